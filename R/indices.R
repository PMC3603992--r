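#' Monthly mean temperature grids
#'
#' Monthly mean temperature is the midpoint of the monthly minimum and
#' maximum normals, `(tmin + tmax) / 2`, the standard convention for
#' PRISM-style monthly normals.
#'
#' @param clim A [clim_normal()].
#' @return Tibble `cell` plus `tmean_01`..`tmean_12` (deg C).
#' @export
monthly_mean_temperature <- function(clim) {
  out <- tibble::tibble(cell = clim$cell)
  for (m in 1:12) {
    out[[sprintf("tmean_%02d", m)]] <-
      (clim[[sprintf("tmin_%02d", m)]] + clim[[sprintf("tmax_%02d", m)]]) / 2
  }
  out
}

#' Warmest and coldest months of the seasonal cycle
#'
#' `mode = "fixed"` returns July and January, the consistently warmest and
#' coldest months of the California coastal study setting this workflow is
#' built around. `mode = "data_driven"` takes the argmax/argmin of the
#' domain-mean monthly mean temperature; ties break to the lowest month
#' number (with a message).
#'
#' @param clim A [clim_normal()].
#' @param mode `"fixed"` or `"data_driven"`.
#' @return Named integer vector `c(warm = , cold = )`.
#' @export
extreme_months <- function(clim, mode = c("fixed", "data_driven")) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(c(warm = 7L, cold = 1L))
  tm <- monthly_mean_temperature(clim)
  means <- vapply(1:12, function(m) mean(tm[[sprintf("tmean_%02d", m)]]), numeric(1))
  if (length(unique(round(means, 12))) == 1) {
    message("constant seasonal cycle: extreme-month tie broken to month 1")
  }
  c(warm = which.max(means)[1], cold = which.min(means)[1])
}

#' Continentality index (Ic)
#'
#' Annual temperature range: mean temperature of the warmest month minus mean
#' temperature of the coldest month, in deg C. Negative values indicate a
#' misconfigured month choice and trigger a warning.
#'
#' @param clim A [clim_normal()].
#' @param months Named vector from [extreme_months()].
#' @return Tibble `cell, Ic`.
#' @export
continentality <- function(clim, months = extreme_months(clim)) {
  tm <- monthly_mean_temperature(clim)
  ic <- tm[[sprintf("tmean_%02d", months[["warm"]])]] -
    tm[[sprintf("tmean_%02d", months[["cold"]])]]
  if (any(ic < 0, na.rm = TRUE)) {
    warning("negative continentality in ", sum(ic < 0, na.rm = TRUE),
            " cell(s); check the warm/cold month configuration", call. = FALSE)
  }
  tibble::tibble(cell = clim$cell, Ic = ic)
}

#' Yearly positive precipitation (Pp) and positive temperature index (Tp)
#'
#' Pp sums precipitation over months whose mean temperature exceeds 0 deg C;
#' Tp sums the mean temperatures of those same months, expressed in tenths of
#' a degree (x 10), the scale on which published thermotype thresholds
#' (1200-2650) are stated.
#'
#' @param clim A [clim_normal()].
#' @return Tibble `cell, Pp, Tp`.
#' @export
positive_precip_and_temp <- function(clim) {
  tm <- monthly_mean_temperature(clim)
  pp <- numeric(nrow(clim))
  tsum <- numeric(nrow(clim))
  for (m in 1:12) {
    t_m <- tm[[sprintf("tmean_%02d", m)]]
    pos <- t_m > 0
    pp <- pp + ifelse(pos, clim[[sprintf("prcp_%02d", m)]], 0)
    tsum <- tsum + ifelse(pos, t_m, 0)
  }
  tibble::tibble(cell = clim$cell, Pp = pp, Tp = 10 * tsum)
}

#' Ombrotype index (Io)
#'
#' The aridity ratio `Io = Pp / Tp` with Tp in tenths of a degree, folded as
#' `10 * Pp / Tp` so the result lands on the published ombrotype category
#' scale (equivalently: Pp divided by the unscaled positive-temperature sum).
#' Undefined (NA) where `Tp <= 0`.
#'
#' @param pp,tp Vectors of Pp (mm) and Tp (tenths of deg C), e.g. from
#'   [positive_precip_and_temp()].
#' @return Numeric vector of Io values.
#' @export
ombrotype_index <- function(pp, tp) {
  ifelse(tp > 0, 10 * pp / tp, NA_real_)
}

#' Thermicity (It) and compensated thermicity (Itc)
#'
#' `It = (T + m + M) * 10` where T is the annual mean of the twelve monthly
#' mean temperatures and m/M are the mean minimum/maximum temperatures of the
#' coldest month. Compensation for continentality: no change for `Ic <= 18`,
#' `+5` for `18 < Ic <= 21`, and `+(Ic - 21) + 15` beyond 21 (so Itc is
#' continuous at Ic = 21 and Itc >= It everywhere).
#'
#' @param clim A [clim_normal()].
#' @param ic Continentality vector aligned with `clim` rows.
#' @param cold_month Coldest month (integer 1-12).
#' @return Tibble `cell, T, m, M, It, Itc`.
#' @export
thermicity <- function(clim, ic, cold_month = 1L) {
  tm <- monthly_mean_temperature(clim)
  t_annual <- rowMeans(as.matrix(tm[month_cols("tmean")]))
  m <- clim[[sprintf("tmin_%02d", cold_month)]]
  mm <- clim[[sprintf("tmax_%02d", cold_month)]]
  it <- (t_annual + m + mm) * 10
  comp <- ifelse(ic > 21, (ic - 21) + 15, ifelse(ic > 18, 5, 0))
  tibble::tibble(cell = clim$cell, T = t_annual, m = m, M = mm,
                 It = it, Itc = it + comp)
}

#' Summer ombrothermic indices (Ios2, Ios4)
#'
#' Ratio of summer precipitation to summer positive temperature, on the same
#' scale as Io: `Ios2` over the warmest summer bimonth (default July-August)
#' and `Ios4` over the four-month summer (default May-August). For a uniform
#' year with monthly precipitation p and mean temperature t both reduce to
#' `p / t`. NA where the summer temperature sum is not positive.
#'
#' @param clim A [clim_normal()].
#' @param bimonth Integer months of the summer bimonth.
#' @param quarter Integer months of the extended summer window.
#' @return Tibble `cell, Ios2, Ios4`.
#' @export
summer_ombrothermic <- function(clim, bimonth = c(7L, 8L), quarter = 5:8) {
  tm <- monthly_mean_temperature(clim)
  ratio <- function(months) {
    p <- rowSums(as.matrix(clim[sprintf("prcp_%02d", months)]))
    t <- rowSums(as.matrix(tm[sprintf("tmean_%02d", months)]))
    ifelse(t > 0, p / t, NA_real_)
  }
  tibble::tibble(cell = clim$cell, Ios2 = ratio(bimonth), Ios4 = ratio(quarter))
}

#' All bioclimatic index grids for a climatology
#'
#' Computes the full per-cell index set used by the classification: warmest
#' and coldest month mean temperatures (Tmax, Tmin), annual mean (T), coldest
#' month extremes (m, M), positive precipitation and temperature (Pp, Tp),
#' continentality (Ic), ombrotype (Io), thermicity and compensated thermicity
#' (It, Itc), and the summer ombrothermic indices (Ios2, Ios4). Every value
#' is a deterministic function of the climatology.
#'
#' @param clim A [clim_normal()].
#' @param months Warm/cold months, from [extreme_months()].
#' @param bimonth,quarter Summer month windows for [summer_ombrothermic()].
#' @return Tibble with `cell,row,col,x,y` and the 13 index columns, carrying
#'   the grid geometry and period as attributes.
#' @examples
#' tr <- make_terrain(grid_geometry(8, 8, 1000), 500, seed = 2)
#' idx <- bioclim_indices(make_climatology(tr))
#' dplyr::glimpse(idx)
#' @export
bioclim_indices <- function(clim, months = extreme_months(clim),
                            bimonth = c(7L, 8L), quarter = 5:8) {
  stopifnot(inherits(clim, "clim_normal"))
  tm <- monthly_mean_temperature(clim)
  ic <- continentality(clim, months)
  pt <- positive_precip_and_temp(clim)
  th <- thermicity(clim, ic$Ic, cold_month = months[["cold"]])
  ios <- summer_ombrothermic(clim, bimonth, quarter)
  out <- dplyr::bind_cols(
    tibble::as_tibble(clim)[c("cell", "row", "col", "x", "y")],
    tibble::tibble(
      Tmax = tm[[sprintf("tmean_%02d", months[["warm"]])]],
      Tmin = tm[[sprintf("tmean_%02d", months[["cold"]])]],
      T = th$T, m = th$m, M = th$M,
      Pp = pt$Pp, Tp = pt$Tp,
      Ic = ic$Ic,
      Io = ombrotype_index(pt$Pp, pt$Tp),
      It = th$It, Itc = th$Itc,
      Ios2 = ios$Ios2, Ios4 = ios$Ios4
    )
  )
  structure(out, geometry = clim_geometry(clim), period = clim_period(clim),
            class = class(tibble::tibble()))
}
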