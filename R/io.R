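#' @keywords internal
#' @name asc-io
#' @noRd
NULL

# ESRI ASCII grid writer. `values` is a full-grid vector in row-major order
# (top row first); NA becomes the nodata value. Plain text so rasters remain
# diffable and portable to any GIS.
asc_write <- function(values, geometry, path, nodata = -9999, digits = 15) {
  stopifnot(length(values) == geometry$n_rows * geometry$n_cols)
  yll <- geometry$origin[2] - geometry$n_rows * geometry$cell_size
  header <- c(
    sprintf("ncols %d", geometry$n_cols),
    sprintf("nrows %d", geometry$n_rows),
    sprintf("xllcorner %.10f", geometry$origin[1]),
    sprintf("yllcorner %.10f", yll),
    sprintf("cellsize %.10f", geometry$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  values[!is.finite(values)] <- nodata
  m <- matrix(values, nrow = geometry$n_rows, ncol = geometry$n_cols, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

asc_read <- function(path, crs_label = "unspecified") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("grid body has wrong length in ", path, call. = FALSE)
  }
  vals[vals == nodata] <- NA_real_
  geometry <- grid_geometry(
    hdr$nrows, hdr$ncols, hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    crs_label = crs_label
  )
  list(geometry = geometry, values = vals)
}

# expand per-cell values to a full-grid vector (NA where cell absent)
full_grid_vector <- function(cells, values, geometry) {
  out <- rep(NA_real_, geometry$n_rows * geometry$n_cols)
  out[cells] <- values
  out
}

#' Write a monthly climatology as ESRI ASCII rasters
#'
#' Writes one plain-text `.asc` raster per band (36 files named
#' `tmin_01.asc` .. `prcp_12.asc`) plus a `metadata.csv` sidecar carrying the
#' period label and CRS label. Cells absent from the table are written as
#' nodata, so the analysis mask round-trips.
#'
#' @param clim A [clim_normal()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_climatology()]
#' @export
write_climatology <- function(clim, dir) {
  stopifnot(inherits(clim, "clim_normal"))
  g <- clim_geometry(clim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (band in clim_value_cols()) {
    asc_write(full_grid_vector(clim$cell, clim[[band]], g),
              g, file.path(dir, paste0(band, ".asc")))
  }
  utils::write.csv(
    data.frame(key = c("period", "crs_label"),
               value = c(clim_period(clim), g$crs_label)),
    file.path(dir, "metadata.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Read a monthly climatology from ESRI ASCII rasters
#'
#' Reads the 36 co-registered `.asc` bands written by [write_climatology()].
#' All bands must share one geometry; cells that are nodata in any band are
#' masked (dropped from the table).
#'
#' @param dir Directory containing `tmin_01.asc` .. `prcp_12.asc` and
#'   optionally `metadata.csv`.
#' @param check Passed to [clim_normal()]: strictness for `tmax < tmin` cells
#'   (`"mask"` warns and drops; `"error"` aborts).
#' @return A [clim_normal()].
#' @export
read_climatology <- function(dir, check = c("mask", "error")) {
  check <- match.arg(check)
  meta_path <- file.path(dir, "metadata.csv")
  period <- "unspecified"
  crs_label <- "unspecified"
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    period <- meta$value[meta$key == "period"][1]
    crs_label <- meta$value[meta$key == "crs_label"][1]
  }
  bands <- clim_value_cols()
  first <- asc_read(file.path(dir, paste0(bands[1], ".asc")), crs_label)
  g <- first$geometry
  vals <- matrix(NA_real_, nrow = g$n_rows * g$n_cols, ncol = length(bands),
                 dimnames = list(NULL, bands))
  vals[, 1] <- first$values
  for (j in 2:length(bands)) {
    b <- asc_read(file.path(dir, paste0(bands[j], ".asc")), crs_label)
    if (!same_geometry(b$geometry, g)) {
      stop("grid mismatch: band ", bands[j], " differs from ", bands[1],
           call. = FALSE)
    }
    vals[, j] <- b$values
  }
  keep <- rowSums(is.na(vals)) == 0
  cells <- grid_cells(g)[keep, , drop = FALSE]
  data <- dplyr::bind_cols(cells, tibble::as_tibble(vals[keep, , drop = FALSE]))
  clim_normal(data, g, period = period, check = check)
}

#' Write a categorical (integer-coded) map with its legend
#'
#' Writes a single-band integer `.asc` raster and a `<path>_legend.csv`
#' sidecar with columns `code,label`. Every code present in the map must
#' appear in the legend.
#'
#' @param map Tibble with columns `cell` and the code column.
#' @param geometry The [grid_geometry()] of the map.
#' @param legend Tibble/data frame with columns `code` and `label`.
#' @param path Output path for the raster (conventionally ending in `.asc`).
#' @param code_col Name of the integer code column in `map`.
#' @return `path`, invisibly.
#' @export
write_categorical <- function(map, geometry, legend, path, code_col = "code") {
  codes <- map[[code_col]]
  missing <- setdiff(unique(codes[!is.na(codes)]), legend$code)
  if (length(missing) > 0) {
    stop("codes missing from legend: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  asc_write(full_grid_vector(map$cell, as.numeric(codes), geometry), geometry,
            path, digits = 12)
  legend_path <- sub("\\.asc$", "", path)
  utils::write.csv(legend[c("code", "label")],
                   paste0(legend_path, "_legend.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a categorical map written by [write_categorical()]
#'
#' @param path Path to the `.asc` raster.
#' @return List with `map` (tibble `cell,row,col,x,y,code`), `geometry`, and
#'   `legend` (tibble, or `NULL` when no sidecar is found).
#' @export
read_categorical <- function(path) {
  r <- asc_read(path)
  keep <- !is.na(r$values)
  map <- grid_cells(r$geometry)[keep, , drop = FALSE]
  map$code <- as.integer(round(r$values[keep]))
  legend_path <- paste0(sub("\\.asc$", "", path), "_legend.csv")
  legend <- if (file.exists(legend_path)) {
    tibble::as_tibble(utils::read.csv(legend_path, stringsAsFactors = FALSE))
  }
  list(map = map, geometry = r$geometry, legend = legend)
}
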