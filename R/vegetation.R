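#' Filter a vegetation legend by removal tags
#'
#' Applies the three standard removal criteria for climate-vegetation
#' ordination: anthropogenic types whose distribution climate does not
#' control (urban, agriculture), types driven by local hydrology (riparian,
#' wetland), and unclassified/unknown types. Types are selected by a `tag`
#' column; untagged types are retained with a warning.
#'
#' @param legend Tibble with columns `code`, `label`, `tag` (tags from
#'   `c("natural", "anthropogenic", "hydrologic", "unknown")`).
#' @param remove_tags Character vector of tags to drop.
#' @return The retained rows of `legend`.
#' @examples
#' legend <- synthetic_frap_legend()
#' nrow(filter_vegetation(legend))  # 23
#' @export
filter_vegetation <- function(legend,
                              remove_tags = c("anthropogenic", "hydrologic",
                                              "unknown")) {
  stopifnot(all(c("code", "label", "tag") %in% names(legend)))
  untagged <- is.na(legend$tag) | legend$tag == ""
  if (any(untagged)) {
    warning(sum(untagged), " untagged vegetation type(s) retained", call. = FALSE)
  }
  retained <- legend[untagged | !(legend$tag %in% remove_tags), , drop = FALSE]
  if (nrow(retained) == 0) {
    stop("all vegetation types removed; ordination impossible", call. = FALSE)
  }
  retained
}

#' Synthetic stand-in for a state vegetation-map legend
#'
#' A 42-type legend emulating the structure of a statewide multi-source
#' vegetation layer clipped to a coastal-California study area: 23 natural
#' upland types (the classic coastal-range woodland/chaparral/conifer
#' palette) plus 19 types tagged for removal under the three criteria of
#' [filter_vegetation()]. This is a synthetic fixture, not the real dataset.
#'
#' @return Tibble `code, label, tag`.
#' @export
synthetic_frap_legend <- function() {
  path <- system.file("extdata", "frap_legend_synthetic.csv",
                      package = "isoclim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Percent-cover abundance matrix per isobioclimate
#'
#' Treats every isobioclimate (the set of all cells sharing a code, not
#' necessarily contiguous) as one plot. The entry for (code, type) is 100
#' times the number of the code's cells carrying that vegetation type divided
#' by the code's total cell count - so rows sum to 100 minus the share of
#' types excluded by filtering.
#'
#' @param iso Classified map from [classify_grid()].
#' @param veg_map Vegetation map tibble with columns `cell`, `veg_code`,
#'   co-registered with `iso`.
#' @param legend Retained legend (e.g. from [filter_vegetation()]); only its
#'   types become columns.
#' @param geometry Grid geometry; defaults to the one attached to `iso`.
#' @return Tibble with `code`, `n_cells`, `area_km2`, then one percent-cover
#'   column per retained type label.
#' @export
patch_abundance <- function(iso, veg_map, legend,
                            geometry = clim_geometry(iso)) {
  joined <- dplyr::inner_join(iso[c("cell", "code")],
                              veg_map[c("cell", "veg_code")], by = "cell")
  if (nrow(joined) == 0) stop("no overlapping cells", call. = FALSE)
  totals <- dplyr::count(joined, .data$code, name = "n_total")
  area <- cell_area_km2(geometry)
  cover <- joined |>
    dplyr::filter(.data$veg_code %in% legend$code) |>
    dplyr::count(.data$code, .data$veg_code, name = "n_type") |>
    dplyr::left_join(totals, by = "code") |>
    dplyr::mutate(
      cover = 100 * .data$n_type / .data$n_total,
      label = legend$label[match(.data$veg_code, legend$code)]
    ) |>
    tidyr::pivot_wider(id_cols = "code", names_from = "label",
                       values_from = "cover", values_fill = 0)
  totals |>
    dplyr::mutate(area_km2 = .data$n_total * area) |>
    dplyr::rename(n_cells = "n_total") |>
    dplyr::inner_join(cover, by = "code") |>
    dplyr::arrange(.data$code)
}

#' Compare a current isobioclimate patch with its future analog
#'
#' Given the abundance matrix, lists the vegetation types shared between a
#' patch's current composition and the present-day composition of its
#' projected future analog, the types found only in the current patch
#' (expected local losses), and the types found only in the analog
#' (expansion candidates). The `no_long_distance_dispersal` flag is TRUE
#' exactly when every type of the analog already occurs in the current patch,
#' i.e. the transition can proceed by local rearrangement.
#'
#' @param abundance Output of [patch_abundance()].
#' @param code_now Isobioclimate code of the current patch.
#' @param code_analog Code of the present-day analog of its projected future.
#' @return List of class `analog_report`: `types` (tibble `type,
#'   cover_current, cover_analog, status`), `no_long_distance_dispersal`,
#'   and the two codes.
#' @export
analog_comparison <- function(abundance, code_now, code_analog) {
  for (code in c(code_now, code_analog)) {
    if (!code %in% abundance$code) {
      stop("isobioclimate code ", code, " not present in the abundance matrix",
           call. = FALSE)
    }
  }
  type_cols <- setdiff(names(abundance), c("code", "n_cells", "area_km2"))
  now <- unlist(abundance[abundance$code == code_now, type_cols])
  ana <- unlist(abundance[abundance$code == code_analog, type_cols])
  types <- tibble::tibble(
    type = type_cols,
    cover_current = as.numeric(now),
    cover_analog = as.numeric(ana)
  ) |>
    dplyr::filter(.data$cover_current > 0 | .data$cover_analog > 0) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$cover_current > 0 & .data$cover_analog > 0 ~ "shared",
      .data$cover_current > 0 ~ "current_only",
      TRUE ~ "analog_only"
    )) |>
    dplyr::arrange(dplyr::desc(.data$cover_analog))
  structure(list(
    types = types,
    no_long_distance_dispersal = !any(types$status == "analog_only"),
    code_now = code_now, code_analog = code_analog
  ), class = "analog_report")
}

#' @export
print.analog_report <- function(x, ...) {
  cat(sprintf(
    "<analog_report> %d -> analog %d; local rearrangement sufficient: %s\n",
    x$code_now, x$code_analog, x$no_long_distance_dispersal
  ))
  print(x$types)
  invisible(x)
}
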