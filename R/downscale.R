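#' GIDS interpolation configuration
#'
#' @param n_neighbors Number of nearest coarse cells used per target cell;
#'   must be at least 4 (one more than the three predictors) for the local
#'   regression to be solvable. Default 8 balances locality against
#'   regression stability.
#' @param singular_fallback What to do when a neighbourhood's design matrix
#'   is rank-deficient (e.g. constant elevation): `"idw"` (default) falls
#'   back to gradient-free inverse-distance-squared weighting with a warning,
#'   `"error"` aborts.
#' @return A list of class `gids_config`.
#' @export
gids_config <- function(n_neighbors = 8, singular_fallback = c("idw", "error")) {
  singular_fallback <- match.arg(singular_fallback)
  if (n_neighbors < 4) stop("n_neighbors must be >= 4", call. = FALSE)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 singular_fallback = singular_fallback),
            class = "gids_config")
}

#' Gradient-plus-inverse-distance-squared (GIDS) interpolation
#'
#' Downscales a monthly climatology from a coarse grid to a finer terrain.
#' For each target cell, a multiple regression of each monthly variable on
#' easting, northing and elevation is fitted over the `n_neighbors` nearest
#' coarse cell centres; the prediction combines the neighbours'
#' gradient-adjusted values with inverse-squared-distance weights:
#' \deqn{\hat Z = \frac{\sum_i (Z_i + (X-X_i)C_x + (Y-Y_i)C_y + (E-E_i)C_e)/d_i^2}
#'                     {\sum_i 1/d_i^2}}
#' A target centre coinciding with a coarse centre returns that coarse value
#' unchanged. Any field affine in (X, Y, E) is reproduced exactly.
#' Precipitation is floored at 0; temperature is not floored. The procedure
#' is fully deterministic.
#'
#' @param coarse_clim A [clim_normal()] on the coarse grid.
#' @param coarse_terrain Terrain (with `cell`, `x`, `y`, `elevation`) on the
#'   coarse grid, e.g. from [make_terrain()]; only cells present in
#'   `coarse_clim` are used.
#' @param fine_terrain Terrain on the target grid.
#' @param cfg A [gids_config()].
#' @return A [clim_normal()] on the fine grid.
#' @export
gids_interpolate <- function(coarse_clim, coarse_terrain, fine_terrain,
                             cfg = gids_config()) {
  stopifnot(inherits(coarse_clim, "clim_normal"), inherits(cfg, "gids_config"))
  src <- dplyr::inner_join(
    tibble::as_tibble(coarse_clim),
    coarse_terrain[c("cell", "elevation")], by = "cell"
  )
  if (nrow(src) < cfg$n_neighbors) {
    stop("fewer coarse cells than n_neighbors", call. = FALSE)
  }
  bands <- clim_value_cols()
  zmat <- as.matrix(src[bands])
  sx <- src$x; sy <- src$y; se <- src$elevation
  k <- cfg$n_neighbors
  n_fine <- nrow(fine_terrain)
  pred <- matrix(NA_real_, n_fine, length(bands), dimnames = list(NULL, bands))
  n_singular <- 0L

  for (i in seq_len(n_fine)) {
    dx <- sx - fine_terrain$x[i]
    dy <- sy - fine_terrain$y[i]
    d2 <- dx * dx + dy * dy
    nb <- order(d2)[seq_len(k)]
    if (d2[nb[1]] == 0) {        # target coincides with a coarse centre
      pred[i, ] <- zmat[nb[1], ]
      next
    }
    X <- cbind(1, sx[nb], sy[nb], se[nb])
    qrX <- qr(X)
    w <- 1 / d2[nb]
    zi <- zmat[nb, , drop = FALSE]
    if (qrX$rank < 4L) {
      if (cfg$singular_fallback == "error") {
        stop("singular GIDS neighbourhood at fine cell ", fine_terrain$cell[i],
             call. = FALSE)
      }
      n_singular <- n_singular + 1L
      pred[i, ] <- colSums(w * zi) / sum(w)
      next
    }
    beta <- qr.coef(qrX, zi)     # 4 x 36; rows: intercept, Cx, Cy, Ce
    delta <- cbind(fine_terrain$x[i] - sx[nb],
                   fine_terrain$y[i] - sy[nb],
                   fine_terrain$elevation[i] - se[nb])
    adj <- zi + delta %*% beta[2:4, , drop = FALSE]
    pred[i, ] <- colSums(w * adj) / sum(w)
  }
  if (n_singular > 0) {
    warning(n_singular, " target cell(s) used gradient-free inverse-distance ",
            "fallback (singular neighbourhood)", call. = FALSE)
  }
  prcp_cols <- grepl("^prcp_", bands)
  pred[, prcp_cols] <- pmax(pred[, prcp_cols], 0)
  data <- dplyr::bind_cols(
    fine_terrain[c("cell", "row", "col", "x", "y")],
    tibble::as_tibble(pred)
  )
  clim_normal(data, clim_geometry(fine_terrain),
              period = clim_period(coarse_clim), check = "mask")
}

#' Bias-correct a modeled climatology against a reference
#'
#' Fits, per cell and per variable (tmin, tmax, prcp), the linear transform
#' `z -> mu_ref + (z - mu_mod) * sd_ref / sd_mod` with moments taken over the
#' twelve monthly normals, so that the corrected annual cycle matches the
#' reference mean and standard deviation exactly. Where `sd_mod` is 0 only
#' the mean shift applies. Corrected precipitation is floored at 0. The
#' fitted transform is returned so it can be applied unchanged to a future
#' climatology from the same model ([apply_bias_transform()]). Correcting an
#' already-corrected historical climatology is a no-op.
#'
#' @param modeled,reference [clim_normal()] objects on the same geometry.
#' @return List of class `bias_correction`: `corrected` (a [clim_normal()])
#'   and `transform` (tibble `cell, var, mu_mod, sd_mod, mu_ref, sd_ref`).
#' @export
bias_correct <- function(modeled, reference) {
  stop_if_geometry_mismatch(clim_geometry(modeled), clim_geometry(reference),
                            "modeled and reference climatologies")
  common <- intersect(modeled$cell, reference$cell)
  mod <- tibble::as_tibble(modeled)[match(common, modeled$cell), ]
  ref <- tibble::as_tibble(reference)[match(common, reference$cell), ]
  transform <- purrr::map(c("tmin", "tmax", "prcp"), function(v) {
    zm <- as.matrix(mod[month_cols(v)])
    zr <- as.matrix(ref[month_cols(v)])
    tibble::tibble(
      cell = common, var = v,
      mu_mod = rowMeans(zm), sd_mod = apply(zm, 1, stats::sd),
      mu_ref = rowMeans(zr), sd_ref = apply(zr, 1, stats::sd)
    )
  }) |> purrr::list_rbind()
  corrected <- apply_bias_transform(
    clim_normal(mod, clim_geometry(modeled), period = clim_period(modeled)),
    transform
  )
  structure(list(corrected = corrected, transform = transform),
            class = "bias_correction")
}

#' Apply a stored bias-correction transform to a climatology
#'
#' @param clim A [clim_normal()] (e.g. a future projection from the model the
#'   transform was fitted on).
#' @param transform The `transform` tibble from [bias_correct()].
#' @return The corrected [clim_normal()].
#' @export
apply_bias_transform <- function(clim, transform) {
  data <- tibble::as_tibble(clim)
  for (v in c("tmin", "tmax", "prcp")) {
    tr <- transform[transform$var == v, ]
    ix <- match(data$cell, tr$cell)
    if (anyNA(ix)) stop("transform missing cells present in the climatology",
                        call. = FALSE)
    scale <- ifelse(tr$sd_mod[ix] > 0, tr$sd_ref[ix] / tr$sd_mod[ix], 1)
    for (m in 1:12) {
      colname <- sprintf("%s_%02d", v, m)
      z <- data[[colname]]
      z <- tr$mu_ref[ix] + (z - tr$mu_mod[ix]) * scale
      if (v == "prcp") z <- pmax(z, 0)
      data[[colname]] <- z
    }
  }
  clim_normal(data, clim_geometry(clim), period = clim_period(clim),
              check = "mask")
}

#' Three-step GIDS downscaling with bias correction
#'
#' Mirrors the production downscaling chain: GIDS from the coarse model grid
#' to the intermediate reference grid, bias correction of the result against
#' the reference climatology, then GIDS from the intermediate grid to the
#' fine terrain. When a `future` climatology is supplied it is interpolated
#' to the intermediate grid, corrected with the transform fitted on the
#' historical pair, and downscaled to the fine grid.
#'
#' @param coarse_clim Historical model climatology on the coarse grid.
#' @param coarse_terrain Terrain of the coarse grid.
#' @param reference_mid Reference climatology on the intermediate grid.
#' @param mid_terrain Terrain of the intermediate grid.
#' @param fine_terrain Terrain of the target grid.
#' @param cfg A [gids_config()].
#' @param future Optional future model climatology on the coarse grid.
#' @return List of class `downscale_result`: `historical` (fine-grid
#'   [clim_normal()]), `future` (fine-grid [clim_normal()] or `NULL`),
#'   `transform` (the bias transform), and `log` (character vector of step
#'   descriptions).
#' @export
downscale_pipeline <- function(coarse_clim, coarse_terrain, reference_mid,
                               mid_terrain, fine_terrain, cfg = gids_config(),
                               future = NULL) {
  log <- character()
  step1 <- gids_interpolate(coarse_clim, coarse_terrain, mid_terrain, cfg)
  log <- c(log, sprintf("GIDS %s -> %s (k=%d)",
                        format(clim_geometry(coarse_clim)),
                        format(clim_geometry(mid_terrain)), cfg$n_neighbors))
  bc <- bias_correct(step1, reference_mid)
  log <- c(log, "bias correction against reference (mean/SD moment matching)")
  step3 <- gids_interpolate(bc$corrected, mid_terrain, fine_terrain, cfg)
  log <- c(log, sprintf("GIDS %s -> %s (k=%d)",
                        format(clim_geometry(mid_terrain)),
                        format(clim_geometry(fine_terrain)), cfg$n_neighbors))
  fut_fine <- NULL
  if (!is.null(future)) {
    fut_mid <- gids_interpolate(future, coarse_terrain, mid_terrain, cfg)
    fut_mid <- apply_bias_transform(fut_mid, bc$transform)
    fut_fine <- gids_interpolate(fut_mid, mid_terrain, fine_terrain, cfg)
    log <- c(log, "future: GIDS -> bias transform -> GIDS")
  }
  structure(list(historical = step3, future = fut_fine,
                 transform = bc$transform, log = log),
            class = "downscale_result")
}
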