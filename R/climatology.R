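#' @keywords internal
month_cols <- function(var) sprintf("%s_%02d", var, 1:12)

clim_value_cols <- function() c(month_cols("tmin"), month_cols("tmax"), month_cols("prcp"))

#' Monthly climate normal on a grid
#'
#' Bundles a per-cell table of 30-year monthly normals with its grid geometry.
#' The table holds one row per analysed cell (cells absent from the table are
#' treated as nodata/masked) and 36 value columns: `tmin_01`..`tmin_12` and
#' `tmax_01`..`tmax_12` in degrees Celsius, `prcp_01`..`prcp_12` in mm/month.
#'
#' @param data Tibble with columns `cell`, `row`, `col`, `x`, `y` and the 36
#'   monthly value columns.
#' @param geometry The [grid_geometry()] the cells live on.
#' @param period Free-text label for the normal period (e.g. `"1971-2000"`).
#' @param check How to treat cells with `tmax < tmin` in any month:
#'   `"error"` aborts, `"mask"` drops the offending cells with a warning.
#' @return A `clim_normal`: the tibble with `geometry` and `period` attributes.
#' @seealso [make_climatology()], [read_climatology()], [bioclim_indices()]
#' @export
clim_normal <- function(data, geometry, period = "unspecified",
                        check = c("error", "mask")) {
  check <- match.arg(check)
  stopifnot(inherits(geometry, "grid_geometry"))
  data <- tibble::as_tibble(data)
  needed <- c("cell", "row", "col", "x", "y", clim_value_cols())
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("climatology table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$cell) > 0) stop("duplicate cell ids", call. = FALSE)
  if (any(data$cell < 1 | data$cell > geometry$n_rows * geometry$n_cols)) {
    stop("cell ids outside the grid", call. = FALSE)
  }
  tmin <- as.matrix(data[month_cols("tmin")])
  tmax <- as.matrix(data[month_cols("tmax")])
  prcp <- as.matrix(data[month_cols("prcp")])
  if (any(prcp < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  bad <- rowSums(tmax < tmin, na.rm = TRUE) > 0
  if (any(bad)) {
    if (check == "error") {
      stop("inconsistent temperatures: tmax < tmin in ", sum(bad), " cell(s)",
           call. = FALSE)
    }
    warning("inconsistent temperatures: masking ", sum(bad), " cell(s)", call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  structure(data,
    geometry = geometry, period = as.character(period),
    class = c("clim_normal", class(tibble::tibble()))
  )
}

#' Geometry and period accessors for gridded objects
#'
#' @param x A `clim_normal` or any object carrying a `geometry` attribute.
#' @return [clim_geometry()] the [grid_geometry()]; [clim_period()] the period
#'   label.
#' @export
clim_geometry <- function(x) {
  g <- attr(x, "geometry", exact = TRUE)
  if (is.null(g)) stop("object has no grid geometry attached", call. = FALSE)
  g
}

#' @rdname clim_geometry
#' @export
clim_period <- function(x) {
  p <- attr(x, "period", exact = TRUE)
  if (is.null(p)) "unspecified" else p
}

#' @export
print.clim_normal <- function(x, ...) {
  g <- clim_geometry(x)
  cat(sprintf(
    "<clim_normal> period %s, %d/%d cells on %s grid\n",
    clim_period(x), nrow(x), g$n_rows * g$n_cols, format(g)
  ))
  NextMethod()
}

# reassemble a clim_normal after transforming its value columns
rebuild_clim <- function(data, template, period = clim_period(template)) {
  clim_normal(data, clim_geometry(template), period = period)
}
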