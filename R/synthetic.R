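#' Generate a smooth synthetic terrain
#'
#' Produces a reproducible pseudo-random elevation surface as a finite sum of
#' randomly oriented cosine waves (smooth by construction, bounded by
#' `relief_amplitude`), plus the distance of every cell centre from the west
#' grid edge, which stands in for distance to the coastline.
#'
#' @param geometry A [grid_geometry()].
#' @param relief_amplitude Half-range of the elevation field in metres;
#'   elevations lie in `[-relief_amplitude, relief_amplitude]`. `0` yields a
#'   flat terrain.
#' @param n_waves Number of cosine components (more gives rougher terrain).
#' @param wavelength_range Range of component wavelengths in metres; defaults
#'   to 0.2-1 times the grid extent.
#' @param seed Integer seed; identical seeds give identical terrain.
#' @return Tibble `cell,row,col,x,y,elevation,coast_km` with the geometry
#'   attached as attribute `geometry`.
#' @examples
#' tr <- make_terrain(grid_geometry(20, 20, 1000), relief_amplitude = 800, seed = 1)
#' range(tr$elevation)
#' @export
make_terrain <- function(geometry, relief_amplitude = 1000, n_waves = 8,
                         wavelength_range = NULL, seed = 1) {
  stopifnot(inherits(geometry, "grid_geometry"), relief_amplitude >= 0)
  cells <- grid_cells(geometry)
  extent <- max(geometry$n_rows, geometry$n_cols) * geometry$cell_size
  if (is.null(wavelength_range)) wavelength_range <- c(0.2, 1) * extent
  elev <- rep(0, nrow(cells))
  if (relief_amplitude > 0 && n_waves > 0) {
    set.seed(seed)
    theta <- stats::runif(n_waves, 0, 2 * pi)
    lambda <- stats::runif(n_waves, wavelength_range[1], wavelength_range[2])
    phase <- stats::runif(n_waves, 0, 2 * pi)
    amp <- stats::runif(n_waves, 0.3, 1)
    for (k in seq_len(n_waves)) {
      proj <- cells$x * cos(theta[k]) + cells$y * sin(theta[k])
      elev <- elev + amp[k] * cos(2 * pi * proj / lambda[k] + phase[k])
    }
    # normalise so the field exactly spans [-amplitude, amplitude]
    elev <- elev - mean(range(elev))
    elev <- elev / max(abs(elev)) * relief_amplitude
  }
  out <- dplyr::mutate(cells,
    elevation = elev,
    coast_km = (.data$x - geometry$origin[1]) / 1000
  )
  structure(out, geometry = geometry,
            class = c("terrain_model", class(tibble::tibble())))
}

#' Parameters for the synthetic climate generator
#'
#' Defines the structural knobs of [make_climatology()]: a coastal sea-level
#' seasonal cycle whose annual range grows saturating with distance from the
#' coast (continentality gradient), an elevational lapse, a fixed diurnal
#' range, winter-concentrated precipitation with an orographic term, and
#' optional independent Gaussian noise. Defaults describe a Mediterranean
#' coastal-range setting: a maritime-buffered coast, strong inland
#' amplification of the seasonal cycle, and wet winters.
#'
#' @param sea_level_tmean 12 monthly mean temperatures (deg C) at the coast at
#'   sea level. The default is a cosine cycle peaking in July (mean 13, range
#'   8 deg C).
#' @param annual_range_inland Asymptotic July-January range (deg C) far inland.
#' @param coastal_damping_scale e-folding distance (km) of the coastal damping
#'   of the annual range; `0` switches damping off (fully inland everywhere).
#' @param lapse_rate Temperature decrease per km of elevation (deg C/km).
#' @param diurnal_range Fixed tmax - tmin gap (deg C); tmin/tmax are
#'   tmean -/+ half this value.
#' @param precip_base Annual precipitation at elevation 0 (mm/yr).
#' @param orographic_factor Additional annual precipitation per km of
#'   elevation (mm/yr/km); negative elevations dry accordingly, with monthly
#'   totals floored at 0.
#' @param wet_season_fraction Fraction of annual precipitation falling in the
#'   four winter months (Nov-Feb); the rest is spread over the other eight.
#' @param noise_sd_temp,noise_sd_prcp SDs of independent per-cell, per-month
#'   Gaussian noise (deg C, mm). `0` keeps the generator exactly closed-form.
#' @param hemisphere `"north"` (July warmest) or `"south"` (cycle shifted six
#'   months, January warmest).
#' @return A list of class `synthetic_climate_params`.
#' @export
synthetic_climate_params <- function(sea_level_tmean = 13 + 4 * cos(2 * pi * (1:12 - 7) / 12),
                                     annual_range_inland = 20,
                                     coastal_damping_scale = 25,
                                     lapse_rate = 6.5,
                                     diurnal_range = 10,
                                     precip_base = 700,
                                     orographic_factor = 800,
                                     wet_season_fraction = 0.9,
                                     noise_sd_temp = 0,
                                     noise_sd_prcp = 0,
                                     hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(length(sea_level_tmean) == 12,
            lapse_rate >= 0, diurnal_range >= 0,
            wet_season_fraction >= 0, wet_season_fraction <= 1,
            noise_sd_temp >= 0, noise_sd_prcp >= 0,
            coastal_damping_scale >= 0, precip_base >= 0)
  structure(
    list(
      sea_level_tmean = sea_level_tmean,
      annual_range_inland = annual_range_inland,
      coastal_damping_scale = coastal_damping_scale,
      lapse_rate = lapse_rate,
      diurnal_range = diurnal_range,
      precip_base = precip_base,
      orographic_factor = orographic_factor,
      wet_season_fraction = wet_season_fraction,
      noise_sd_temp = noise_sd_temp,
      noise_sd_prcp = noise_sd_prcp,
      hemisphere = hemisphere
    ),
    class = "synthetic_climate_params"
  )
}

# monthly precipitation weights: wet_season_fraction split over Nov-Feb
precip_weights <- function(wet_season_fraction, hemisphere = "north") {
  winter <- if (hemisphere == "north") c(11, 12, 1, 2) else c(5, 6, 7, 8)
  w <- rep((1 - wet_season_fraction) / 8, 12)
  w[winter] <- wet_season_fraction / 4
  w
}

#' Generate a synthetic monthly climatology over a terrain
#'
#' Monthly mean temperature is the sea-level seasonal cycle with its annual
#' amplitude amplified away from the coast (saturating at
#' `annual_range_inland` with e-folding `coastal_damping_scale`), lowered by
#' `lapse_rate` per km of elevation; tmin/tmax bracket it by half the diurnal
#' range. Annual precipitation is `precip_base + orographic_factor *
#' elevation/1000`, distributed by the wet-season weights and floored at 0.
#' With noise off every downstream bioclimatic index has a closed form in the
#' generator parameters, which the test-suite uses as an oracle.
#'
#' @param terrain A terrain from [make_terrain()].
#' @param params A [synthetic_climate_params()].
#' @param period Period label for the result.
#' @param seed Seed for the Gaussian noise (ignored when both noise SDs are 0).
#' @return A [clim_normal()].
#' @export
make_climatology <- function(terrain, params = synthetic_climate_params(),
                             period = "synthetic-present", seed = 1) {
  stopifnot(inherits(params, "synthetic_climate_params"))
  g <- clim_geometry(terrain)
  n <- nrow(terrain)
  s <- params$sea_level_tmean
  if (params$hemisphere == "south") s <- s[c(7:12, 1:6)]
  anom <- s - mean(s)
  base_range <- diff(range(s))
  # amplification of the seasonal anomaly with distance from the coast
  f <- if (params$coastal_damping_scale <= 0) rep(1, n) else {
    1 - exp(-terrain$coast_km / params$coastal_damping_scale)
  }
  amp <- if (base_range <= 0) rep(1, n) else {
    (base_range + (params$annual_range_inland - base_range) * f) / base_range
  }
  lapse_term <- params$lapse_rate * terrain$elevation / 1000
  p_ann <- pmax(0, params$precip_base +
                  params$orographic_factor * terrain$elevation / 1000)
  w <- precip_weights(params$wet_season_fraction, params$hemisphere)

  noisy <- params$noise_sd_temp > 0 || params$noise_sd_prcp > 0
  if (noisy) set.seed(seed)
  vals <- matrix(NA_real_, n, 36, dimnames = list(NULL, clim_value_cols()))
  for (m in 1:12) {
    tmean <- mean(s) + anom[m] * amp - lapse_term
    if (params$noise_sd_temp > 0) tmean <- tmean + stats::rnorm(n, 0, params$noise_sd_temp)
    pr <- p_ann * w[m]
    if (params$noise_sd_prcp > 0) pr <- pr + stats::rnorm(n, 0, params$noise_sd_prcp)
    vals[, sprintf("tmin_%02d", m)] <- tmean - params$diurnal_range / 2
    vals[, sprintf("tmax_%02d", m)] <- tmean + params$diurnal_range / 2
    vals[, sprintf("prcp_%02d", m)] <- pmax(0, pr)
  }
  data <- dplyr::bind_cols(
    terrain[c("cell", "row", "col", "x", "y")],
    tibble::as_tibble(vals)
  )
  clim_normal(data, g, period = period)
}

#' Apply a synthetic future perturbation to a climatology
#'
#' Warms every month by `delta_t`, widens the seasonal cycle by adding
#' `continentality_boost / 2` to the warmest month and subtracting it from the
#' coldest (so the continentality index rises by exactly
#' `continentality_boost` on noise-free input), and scales precipitation by
#' `precip_scale` (floored at 0).
#'
#' @param clim A [clim_normal()].
#' @param delta_t Uniform warming in deg C.
#' @param precip_scale Multiplicative precipitation change (> 0; < 1 dries).
#' @param continentality_boost Increase of the warm-cold month range in deg C.
#' @param warm_month,cold_month Months receiving the continentality
#'   perturbation (defaults July/January).
#' @param period Period label of the result.
#' @return A [clim_normal()].
#' @export
make_future <- function(clim, delta_t = 3, precip_scale = 0.8,
                        continentality_boost = 2,
                        warm_month = 7L, cold_month = 1L,
                        period = "synthetic-future") {
  stopifnot(inherits(clim, "clim_normal"), precip_scale > 0)
  data <- tibble::as_tibble(clim)
  for (m in 1:12) {
    shift <- delta_t +
      (m == warm_month) * continentality_boost / 2 -
      (m == cold_month) * continentality_boost / 2
    data[[sprintf("tmin_%02d", m)]] <- data[[sprintf("tmin_%02d", m)]] + shift
    data[[sprintf("tmax_%02d", m)]] <- data[[sprintf("tmax_%02d", m)]] + shift
    data[[sprintf("prcp_%02d", m)]] <-
      pmax(0, data[[sprintf("prcp_%02d", m)]] * precip_scale)
  }
  clim_normal(data, clim_geometry(clim), period = period)
}

#' Construct Gaussian niche parameters for synthetic vegetation
#'
#' Spreads `n_types` optima evenly along the observed ombrotype (Io) range so
#' the moisture gradient is the primary structuring axis, with random broad
#' niches on continentality (Ic) and thermicity (Itc).
#'
#' @param indices A bioclimatic index table from [bioclim_indices()] (needs
#'   columns `Io`, `Ic`, `Itc`).
#' @param n_types Number of vegetation types (>= 2).
#' @param labels Optional type labels (default `veg01`, `veg02`, ...).
#' @param seed Seed for the secondary-axis optima.
#' @return Tibble `type, opt_io, tol_io, opt_ic, tol_ic, opt_itc, tol_itc`.
#' @export
make_niches <- function(indices, n_types = 8, labels = NULL, seed = 1) {
  if (n_types < 2) stop("n_types must be >= 2", call. = FALSE)
  set.seed(seed)
  io_rng <- range(indices$Io, na.rm = TRUE)
  ic_rng <- range(indices$Ic, na.rm = TRUE)
  itc_rng <- range(indices$Itc, na.rm = TRUE)
  if (is.null(labels)) labels <- sprintf("veg%02d", seq_len(n_types))
  tibble::tibble(
    type = labels,
    opt_io = seq(io_rng[1], io_rng[2], length.out = n_types),
    tol_io = diff(io_rng) / n_types * 1.2 + 1e-6,
    opt_ic = stats::runif(n_types, ic_rng[1], ic_rng[2]),
    tol_ic = diff(ic_rng) * 2 + 1e-6,
    opt_itc = stats::runif(n_types, itc_rng[1], itc_rng[2]),
    tol_itc = diff(itc_rng) * 2 + 1e-6
  )
}

#' Generate a synthetic vegetation map from bioclimatic indices
#'
#' Each cell is assigned the type with the highest Gaussian (unimodal)
#' suitability over (Io, Ic, Itc) plus independent Gaussian noise, emulating a
#' single-label categorical vegetation raster whose types respond unimodally
#' along the moisture gradient.
#'
#' @param indices Index table from [bioclim_indices()] (columns `cell`, `row`,
#'   `col`, `x`, `y`, `Io`, `Ic`, `Itc`).
#' @param niches Niche table as from [make_niches()].
#' @param noise_sd SD of the suitability noise (`0` = deterministic argmax).
#' @param seed Seed for the noise.
#' @return List with `map` (tibble `cell,row,col,x,y,veg_code`) and `legend`
#'   (tibble `code,label,tag` with every type tagged `natural`).
#' @export
make_vegetation <- function(indices, niches, noise_sd = 0.05, seed = 1) {
  if (nrow(niches) < 2) stop("n_types must be >= 2", call. = FALSE)
  n <- nrow(indices)
  suit <- matrix(NA_real_, n, nrow(niches))
  for (k in seq_len(nrow(niches))) {
    suit[, k] <- exp(-0.5 * (
      ((indices$Io - niches$opt_io[k]) / niches$tol_io[k])^2 +
        ((indices$Ic - niches$opt_ic[k]) / niches$tol_ic[k])^2 +
        ((indices$Itc - niches$opt_itc[k]) / niches$tol_itc[k])^2
    ))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    suit <- suit + matrix(stats::rnorm(length(suit), 0, noise_sd), nrow = n)
  }
  map <- dplyr::mutate(indices[c("cell", "row", "col", "x", "y")],
                       veg_code = max.col(suit, ties.method = "first"))
  legend <- tibble::tibble(
    code = seq_len(nrow(niches)),
    label = niches$type,
    tag = "natural"
  )
  list(map = map, legend = legend)
}
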