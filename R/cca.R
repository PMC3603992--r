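#' Canonical correspondence analysis of vegetation vs. bioclimatic indices
#'
#' Constrained ordination relating a plots-by-species percent-cover matrix to
#' environmental variables. The algorithm is the standard weighted
#' eigenanalysis: plot and species weights come from the matrix totals; the
#' chi-square-standardised residual matrix
#' \eqn{\bar Q_{ij} = (p_{ij} - r_i c_j)/\sqrt{r_i c_j}} is projected, by
#' weighted least squares, onto the (row-weight standardised) environment
#' matrix; the singular value decomposition of the projection yields the
#' canonical axes, with eigenvalues the squared singular values. Each axis is
#' sign-normalised so that its largest-magnitude species score is positive.
#'
#' @param abundance Tibble/data frame whose first column (`plot_col`)
#'   identifies the plots (e.g. isobioclimate codes) and whose remaining
#'   numeric columns are species abundances (non-negative). Columns
#'   `n_cells`/`area_km2` from [patch_abundance()] are dropped automatically.
#'   All-zero rows and columns are dropped with a warning.
#' @param environment Tibble with the same plot id column and one numeric
#'   column per environmental variable (here typically `Io`, `Ic`, `Itc`).
#'   Variables are standardised internally to row-weighted zero mean and unit
#'   variance; collinear variables are dropped with a warning.
#' @param plot_col Name of the shared plot id column.
#' @return Object of class `bioclim_cca` with elements `eigenvalues`
#'   (length \eqn{\le} number of environment variables, non-increasing, in
#'   `[0, 1)`), `total_inertia`, `coefficients` (canonical coefficients on
#'   the standardised variables), `coefficients_raw` (per original unit),
#'   `species_scores`, `site_scores_wa` (weighted-average form),
#'   `site_scores_lc` (linear-combination form), `env_correlations`
#'   (weighted variable-axis correlations), `row_weights`, `col_weights`.
#' @seealso [generics::tidy()], [generics::glance()], [autoplot.bioclim_cca()]
#' @export
cca_bioclim <- function(abundance, environment, plot_col = "code") {
  ab <- tibble::as_tibble(abundance)
  env <- tibble::as_tibble(environment)
  stopifnot(plot_col %in% names(ab), plot_col %in% names(env))
  ab <- ab[!(names(ab) %in% c("n_cells", "area_km2")) ]
  env <- dplyr::semi_join(env, ab, by = plot_col)
  ab <- ab[match(env[[plot_col]], ab[[plot_col]]), , drop = FALSE]

  Y <- as.matrix(ab[setdiff(names(ab), plot_col)])
  storage.mode(Y) <- "double"
  if (any(Y < 0, na.rm = TRUE)) stop("abundances must be non-negative", call. = FALSE)
  plots <- as.character(env[[plot_col]])
  rownames(Y) <- plots

  keep_r <- rowSums(Y) > 0
  keep_c <- colSums(Y) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping ", sum(!keep_r), " empty plot(s) and ",
            sum(!keep_c), " absent species", call. = FALSE)
    Y <- Y[keep_r, keep_c, drop = FALSE]
    env <- env[keep_r, , drop = FALSE]
    plots <- plots[keep_r]
  }
  if (nrow(Y) < 2 || ncol(Y) < 2) {
    stop("need at least 2 plots and 2 species", call. = FALSE)
  }

  E <- as.matrix(env[setdiff(names(env), plot_col)])
  storage.mode(E) <- "double"

  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P)                      # plot weights
  c_w <- colSums(P)                    # species weights
  Qbar <- (P - outer(r, c_w)) / sqrt(outer(r, c_w))
  total_inertia <- sum(Qbar^2)

  # row-weighted standardisation of the environment
  mu <- colSums(E * r)
  Ec <- sweep(E, 2, mu)
  sdw <- sqrt(colSums(Ec^2 * r))
  zero_var <- sdw <= .Machine$double.eps * 1e3
  if (any(zero_var)) {
    warning("dropping constant environment variable(s): ",
            paste(colnames(E)[zero_var], collapse = ", "), call. = FALSE)
    Ec <- Ec[, !zero_var, drop = FALSE]
    sdw <- sdw[!zero_var]
  }
  Es <- sweep(Ec, 2, sdw, "/")
  Xw <- Es * sqrt(r)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping collinear environment variable(s): ",
            paste(colnames(Xw)[-keep], collapse = ", "), call. = FALSE)
    Es <- Es[, keep, drop = FALSE]
    sdw <- sdw[keep]
    Xw <- Xw[, keep, drop = FALSE]
    qrX <- qr(Xw)
  }

  B <- qr.coef(qrX, Qbar)              # q x species: WLS projection
  Yhat <- Xw %*% B
  sv <- svd(Yhat)
  n_axes <- min(ncol(Xw), sum(sv$d > 1e-10))
  n_axes <- max(n_axes, 1L)
  U <- sv$u[, seq_len(n_axes), drop = FALSE]
  V <- sv$v[, seq_len(n_axes), drop = FALSE]
  d <- sv$d[seq_len(n_axes)]
  eig <- d^2

  species <- sweep(V, 1, sqrt(c_w), "/")          # chi-square metric scores
  sites_wa <- sweep(Qbar %*% V, 1, sqrt(r), "/")
  sites_lc <- sweep(U %*% diag(d, n_axes), 1, sqrt(r), "/")
  coefs <- B %*% V                                 # on standardised variables

  # deterministic orientation: largest-|score| species positive on each axis
  for (a in seq_len(n_axes)) {
    top <- which.max(abs(species[, a]))
    if (species[top, a] < 0) {
      species[, a] <- -species[, a]
      sites_wa[, a] <- -sites_wa[, a]
      sites_lc[, a] <- -sites_lc[, a]
      coefs[, a] <- -coefs[, a]
    }
  }

  wcor <- function(xv, yv) {
    mx <- sum(r * xv); my <- sum(r * yv)
    cxy <- sum(r * (xv - mx) * (yv - my))
    cxy / sqrt(sum(r * (xv - mx)^2) * sum(r * (yv - my)^2))
  }
  env_cor <- matrix(NA_real_, ncol(Es), n_axes,
                    dimnames = list(colnames(Es), paste0("CCA", seq_len(n_axes))))
  for (j in seq_len(ncol(Es))) {
    for (a in seq_len(n_axes)) env_cor[j, a] <- wcor(Es[, j], sites_lc[, a])
  }

  axis_names <- paste0("CCA", seq_len(n_axes))
  dimnames(species) <- list(colnames(Y), axis_names)
  dimnames(sites_wa) <- list(plots, axis_names)
  dimnames(sites_lc) <- list(plots, axis_names)
  dimnames(coefs) <- list(colnames(Es), axis_names)

  structure(list(
    eigenvalues = stats::setNames(eig, axis_names),
    total_inertia = total_inertia,
    coefficients = coefs,
    coefficients_raw = coefs / sdw,
    species_scores = species,
    site_scores_wa = sites_wa,
    site_scores_lc = sites_lc,
    env_correlations = env_cor,
    row_weights = stats::setNames(r, plots),
    col_weights = stats::setNames(c_w, colnames(Y))
  ), class = "bioclim_cca")
}

#' @export
print.bioclim_cca <- function(x, ...) {
  cat("<bioclim_cca> constrained correspondence analysis\n")
  cat(sprintf("  total inertia %.4f, constrained %.4f (%.1f%%)\n",
              x$total_inertia, sum(x$eigenvalues),
              100 * sum(x$eigenvalues) / x$total_inertia))
  cat("  eigenvalues:", paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted CCA
#'
#' @param x A `bioclim_cca` object.
#' @param matrix Which component to return: `"eigenvalues"`,
#'   `"coefficients"` (standardised), `"species"`, or `"sites"`
#'   (weighted-average scores).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bioclim_cca <- function(x, matrix = c("eigenvalues", "coefficients",
                                           "species", "sites"), ...) {
  matrix <- match.arg(matrix)
  as_long <- function(m, id) {
    tibble::as_tibble(m, rownames = id) |>
      tidyr::pivot_longer(-dplyr::all_of(id), names_to = "axis",
                          values_to = "score")
  }
  switch(matrix,
    eigenvalues = tibble::tibble(
      axis = names(x$eigenvalues),
      eigenvalue = as.numeric(x$eigenvalues),
      proportion = as.numeric(x$eigenvalues) / x$total_inertia
    ),
    coefficients = as_long(x$coefficients, "variable"),
    species = as_long(x$species_scores, "species"),
    sites = as_long(x$site_scores_wa, "plot")
  )
}

#' One-row summary of a fitted CCA
#'
#' @param x A `bioclim_cca` object.
#' @param ... Unused.
#' @return Tibble with total and constrained inertia, the constrained
#'   proportion, and axis/plot/species counts.
#' @export
glance.bioclim_cca <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = sum(x$eigenvalues),
    prop_constrained = sum(x$eigenvalues) / x$total_inertia,
    n_axes = length(x$eigenvalues),
    n_plots = length(x$row_weights),
    n_species = length(x$col_weights)
  )
}
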