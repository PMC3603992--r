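# Shared fixtures: all built in code, no files on disk.

# climatology from explicit per-month values; tmean is a 12-vector (recycled
# across cells) or an n x 12 matrix, same for prcp
clim_from_monthly <- function(tmean, prcp, geometry = grid_geometry(2, 2, 270),
                              diurnal = 10, period = "fixture") {
  cells <- grid_cells(geometry)
  n <- nrow(cells)
  tm <- if (is.matrix(tmean)) tmean else matrix(tmean, n, 12, byrow = TRUE)
  pr <- if (is.matrix(prcp)) prcp else matrix(prcp, n, 12, byrow = TRUE)
  data <- cells
  for (m in 1:12) {
    data[[sprintf("tmin_%02d", m)]] <- tm[, m] - diurnal / 2
    data[[sprintf("tmax_%02d", m)]] <- tm[, m] + diurnal / 2
    data[[sprintf("prcp_%02d", m)]] <- pr[, m]
  }
  clim_normal(data, geometry, period = period)
}

# cosine seasonal cycle peaking in July
seasonal_cycle <- function(mean_t = 13, range_t = 10) {
  mean_t + range_t / 2 * cos(2 * pi * (1:12 - 7) / 12)
}

# fake classified map with given codes laid over a geometry
iso_from_codes <- function(codes, geometry = NULL) {
  if (is.null(geometry)) {
    side <- ceiling(sqrt(length(codes)))
    geometry <- grid_geometry(side, side, 270)
  }
  cells <- grid_cells(geometry)[seq_along(codes), ]
  parts <- decode_code(codes)
  out <- dplyr::bind_cols(cells, parts)
  out$code <- as.integer(codes)
  out$mediterranean <- TRUE
  structure(out, geometry = geometry, class = class(tibble::tibble()))
}

# pool of valid isobioclimate codes to sample from
valid_codes <- function() {
  grid <- expand.grid(io = 5:15, ic = 1:7, tmo = 1:7)
  compose_code(grid$io, grid$ic, grid$tmo)
}

default_tables <- function() {
  list(
    continentality = category_table("continentality"),
    ombrotype = category_table("ombrotype"),
    thermotype = category_table("thermotype")
  )
}

# independent linear-scan classifier: half-open intervals (prev upper, upper],
# clamped to the extreme categories outside the table span
scan_classify <- function(v, table) {
  uppers <- table$upper
  n <- length(uppers)
  out <- rep(NA_integer_, length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    if (!is.finite(x)) next
    if (x <= uppers[1]) { out[i] <- table$numeric[1]; next }
    if (x > uppers[n]) { out[i] <- table$numeric[n]; next }
    for (k in 2:n) {
      if (x > uppers[k - 1] && x <= uppers[k]) {
        out[i] <- table$numeric[k]
        break
      }
    }
  }
  as.integer(out)
}
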