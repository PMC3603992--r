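#' Load a bioclimatic category table
#'
#' The three category tables (continentality, ombrotype, thermotype) ship as
#' CSV data under `inst/extdata/` so variants (e.g. an extra hyperarid
#' ombrotype row) can be dropped in without code changes. Each row carries an
#' alpha code, a strictly increasing numeric code, a label, and printed
#' two-decimal bounds; the thermotype table adds the positive-temperature
#' (`tp_*`) thresholds used under high continentality or low thermicity.
#'
#' The printed bounds (e.g. `4.01-8`) are two-decimal renderings of a
#' continuous partition; classification therefore uses half-open intervals
#' `(previous upper, upper]`, so a value of exactly 4 falls in the lower
#' category and 4.005 in the upper.
#'
#' @param index `"continentality"`, `"ombrotype"` or `"thermotype"`.
#' @param path Optional path to a replacement CSV with the same columns.
#' @return A tibble of class `category_table` (attribute `index_name`).
#' @export
category_table <- function(index = c("continentality", "ombrotype", "thermotype"),
                           path = NULL) {
  index <- match.arg(index)
  if (is.null(path)) {
    path <- system.file("extdata", paste0(index, "_categories.csv"),
                        package = "isoclim", mustWork = TRUE)
  }
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("alpha", "numeric", "label", "lower", "upper") %in% names(tbl)))
  if (is.unsorted(tbl$lower) || any(diff(tbl$numeric) <= 0)) {
    stop("category table rows must be ordered with increasing bounds and codes",
         call. = FALSE)
  }
  structure(tbl, index_name = index,
            class = c("category_table", class(tbl)))
}

#' Look up the numeric code of a named category
#'
#' Matches the category label (or alpha code) case-insensitively.
#'
#' @param table A [category_table()].
#' @param name Category label (e.g. `"Lower humid"`) or alpha code.
#' @return Integer numeric code.
#' @export
category_code <- function(table, name) {
  hit <- tolower(table$label) == tolower(name) | tolower(table$alpha) == tolower(name)
  if (sum(hit) != 1) stop("category not found: ", name, call. = FALSE)
  as.integer(table$numeric[hit])
}

#' Classify index values against a category table
#'
#' Assigns each finite value the unique category whose half-open interval
#' `(previous upper, upper]` contains it. Values outside the table's overall
#' range are handled per `out_of_range`: `"extend"` clamps to the first/last
#' category (the attribute `"flagged"` records which inputs were clamped),
#' `"flag"` returns NA for them. NaN/NA inputs always return NA.
#'
#' @param v Numeric vector of index values.
#' @param table A [category_table()]. For the thermotype Tp column use
#'   `tp_bounds(table)`.
#' @param out_of_range `"extend"` or `"flag"`.
#' @return Integer vector of numeric category codes, with a logical
#'   `"flagged"` attribute marking out-of-range inputs.
#' @examples
#' t3 <- category_table("continentality")
#' classify_value(c(4, 4.5, 15), t3)  # 1, 2, 5
#' @export
classify_value <- function(v, table, out_of_range = c("extend", "flag")) {
  out_of_range <- match.arg(out_of_range)
  uppers <- table$upper
  idx <- findInterval(v, uppers, left.open = TRUE) + 1L
  flagged <- !is.na(v) & (v < table$lower[1] | v > uppers[length(uppers)])
  if (out_of_range == "extend") {
    idx <- pmin(pmax(idx, 1L), nrow(table))
  } else {
    idx[flagged] <- NA_integer_
  }
  idx[!is.finite(v)] <- NA_integer_
  codes <- as.integer(table$numeric)[idx]
  attr(codes, "flagged") <- flagged
  codes
}

#' Thermotype table re-expressed on its Tp thresholds
#'
#' @param table The thermotype [category_table()].
#' @return A `category_table` whose `lower`/`upper` are the Tp bounds.
#' @export
tp_bounds <- function(table) {
  stopifnot(all(c("tp_lower", "tp_upper") %in% names(table)))
  out <- table
  out$lower <- table$tp_lower
  out$upper <- table$tp_upper
  out
}

#' Classify the thermotype with the positive-temperature fallback
#'
#' Cells are classified on the compensated thermicity index Itc against the
#' It/Itc thresholds, except where continentality is high or thermicity is
#' low - by default `Ic > 21 | Itc < 120` - in which case the positive
#' temperature index Tp is classified against the Tp thresholds instead.
#' The continentality comparator is configurable (`">"` or `">="`, both in
#' circulation for this rule).
#'
#' @param it,itc,ic,tp Aligned numeric vectors of It, Itc, Ic and Tp.
#' @param table The thermotype [category_table()].
#' @param tp_trigger_cmp `">"` (default) or `">="` for the Ic trigger.
#' @param out_of_range Passed to [classify_value()].
#' @return Integer vector of thermotype codes with attribute `"used_tp"`
#'   (logical, which cells took the Tp route).
#' @export
classify_thermotype <- function(it, itc, ic, tp,
                                table = category_table("thermotype"),
                                tp_trigger_cmp = c(">", ">="),
                                out_of_range = c("extend", "flag")) {
  tp_trigger_cmp <- match.arg(tp_trigger_cmp)
  out_of_range <- match.arg(out_of_range)
  high_ic <- if (tp_trigger_cmp == ">") ic > 21 else ic >= 21
  use_tp <- high_ic | itc < 120
  use_tp[is.na(use_tp)] <- FALSE
  code_itc <- classify_value(itc, table, out_of_range)
  code_tp <- classify_value(tp, tp_bounds(table), out_of_range)
  out <- ifelse(use_tp, code_tp, code_itc)
  attr(out, "used_tp") <- use_tp
  out
}

#' Mediterranean macrobioclimate test
#'
#' The Mediterranean macrobioclimate is diagnosed by summer drought: a summer
#' ombrothermic index strictly below 2. The default applies the rule to the
#' four-month index Ios4; `rule = "ios2"` applies it to the bimonthly Ios2.
#'
#' @param ios2,ios4 Summer ombrothermic index vectors.
#' @param rule `"ios4"` (default) or `"ios2"`.
#' @param threshold Drought threshold (default 2; strict `<`).
#' @return Logical vector (TRUE = Mediterranean).
#' @export
mediterranean_test <- function(ios2, ios4, rule = c("ios4", "ios2"), threshold = 2) {
  rule <- match.arg(rule)
  v <- if (rule == "ios4") ios4 else ios2
  v < threshold
}

#' Compose and decode isobioclimate codes
#'
#' An isobioclimate code packs the three numeric category codes as
#' `io * 100 + ic * 10 + tmo` (e.g. lower humid 12, euoceanic 5, upper
#' mesomediterranean 2 gives 1252). Continentality and thermotype codes must
#' be single digits (1-7); ombrotype codes span 5-15 and occupy the leading
#' digits, so decoding is exact.
#'
#' @param io_cat,ic_cat,tmo_cat Integer category code vectors.
#' @return [compose_code()]: integer code vector. [decode_code()]: tibble
#'   `io_cat, ic_cat, tmo_cat`.
#' @examples
#' compose_code(12, 5, 2)  # 1252
#' decode_code(1163)
#' @export
compose_code <- function(io_cat, ic_cat, tmo_cat) {
  ok <- function(x, lo, hi) is.na(x) | (x >= lo & x <= hi & x == round(x))
  if (!all(ok(io_cat, 5, 15)) || !all(ok(ic_cat, 1, 7)) || !all(ok(tmo_cat, 1, 7))) {
    stop("category code out of range (io 5-15, ic 1-7, tmo 1-7)", call. = FALSE)
  }
  as.integer(io_cat * 100L + ic_cat * 10L + tmo_cat)
}

#' @rdname compose_code
#' @param code Integer isobioclimate code vector.
#' @export
decode_code <- function(code) {
  io <- code %/% 100L
  ic <- (code %/% 10L) %% 10L
  tmo <- code %% 10L
  bad <- !is.na(code) & (io < 5 | io > 15 | ic < 1 | ic > 7 | tmo < 1 | tmo > 7)
  if (any(bad)) {
    stop("undecodable isobioclimate code(s): ",
         paste(utils::head(unique(code[bad]), 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(io_cat = as.integer(io), ic_cat = as.integer(ic),
                 tmo_cat = as.integer(tmo))
}

#' Classify a climatology into isobioclimates
#'
#' Runs the full chain: bioclimatic indices, per-index classification against
#' the packaged category tables, the Mediterranean macrobioclimate test, and
#' isobioclimate code composition.
#'
#' @param clim A [clim_normal()], or an index table already produced by
#'   [bioclim_indices()].
#' @param tables Named list of the three [category_table()]s
#'   (`continentality`, `ombrotype`, `thermotype`).
#' @param out_of_range,tp_trigger_cmp,med_rule Conventions passed through to
#'   [classify_value()], [classify_thermotype()] and [mediterranean_test()].
#' @param months Passed to [bioclim_indices()] when `clim` is a climatology.
#' @return Tibble `cell,row,col,x,y,io_cat,ic_cat,tmo_cat,code,mediterranean`
#'   with the grid geometry and period attached as attributes.
#' @examples
#' tr <- make_terrain(grid_geometry(8, 8, 1000), 500, seed = 2)
#' iso <- classify_grid(make_climatology(tr))
#' isobioclimate_summary(iso)
#' @export
classify_grid <- function(clim,
                          tables = list(
                            continentality = category_table("continentality"),
                            ombrotype = category_table("ombrotype"),
                            thermotype = category_table("thermotype")
                          ),
                          out_of_range = c("extend", "flag"),
                          tp_trigger_cmp = c(">", ">="),
                          med_rule = c("ios4", "ios2"),
                          months = NULL) {
  out_of_range <- match.arg(out_of_range)
  idx <- if (inherits(clim, "clim_normal")) {
    if (is.null(months)) months <- extreme_months(clim)
    bioclim_indices(clim, months = months)
  } else {
    clim
  }
  io_cat <- classify_value(idx$Io, tables$ombrotype, out_of_range)
  ic_cat <- classify_value(idx$Ic, tables$continentality, out_of_range)
  tmo_cat <- classify_thermotype(idx$It, idx$Itc, idx$Ic, idx$Tp,
                                 tables$thermotype, tp_trigger_cmp, out_of_range)
  out <- dplyr::mutate(
    idx[c("cell", "row", "col", "x", "y")],
    io_cat = as.integer(io_cat),
    ic_cat = as.integer(ic_cat),
    tmo_cat = as.integer(tmo_cat),
    code = compose_code(.data$io_cat, .data$ic_cat, .data$tmo_cat),
    mediterranean = mediterranean_test(idx$Ios2, idx$Ios4, med_rule)
  )
  structure(out,
            geometry = attr(idx, "geometry", exact = TRUE),
            period = attr(idx, "period", exact = TRUE),
            class = class(tibble::tibble()))
}

#' Summarise an isobioclimate map
#'
#' Unique codes with cell counts and areas; the area of a code is its cell
#' count times the geometry-derived cell area.
#'
#' @param iso A classified map from [classify_grid()].
#' @param geometry Grid geometry; defaults to the one attached to `iso`.
#' @return Tibble `code, io_cat, ic_cat, tmo_cat, n_cells, area_km2`, sorted
#'   by decreasing area.
#' @export
isobioclimate_summary <- function(iso, geometry = clim_geometry(iso)) {
  area <- cell_area_km2(geometry)
  iso |>
    dplyr::filter(!is.na(.data$code)) |>
    dplyr::count(.data$code, .data$io_cat, .data$ic_cat, .data$tmo_cat,
                 name = "n_cells") |>
    dplyr::mutate(area_km2 = .data$n_cells * area) |>
    dplyr::arrange(dplyr::desc(.data$area_km2))
}
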