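#' Per-index class change between two classified maps
#'
#' Change is counted in categories: the signed difference of numeric category
#' codes per index (future minus baseline), their absolute values, and the
#' total change as the sum of the three absolute differences. A cell that
#' moves from extremely hyperoceanic (1) to barely hyperoceanic (3) has a
#' continentality change of 2.
#'
#' @param iso_a,iso_b Classified maps from [classify_grid()] on the same
#'   geometry and category tables (`a` = baseline, `b` = comparison).
#' @return Tibble `cell,row,col,x,y,d_io,d_ic,d_tmo` (signed),
#'   `abs_io,abs_ic,abs_tmo`, and `total_change`.
#' @export
index_change <- function(iso_a, iso_b) {
  stop_if_geometry_mismatch(clim_geometry(iso_a), clim_geometry(iso_b),
                            "classified maps")
  joined <- dplyr::inner_join(
    iso_a[c("cell", "row", "col", "x", "y", "io_cat", "ic_cat", "tmo_cat")],
    iso_b[c("cell", "io_cat", "ic_cat", "tmo_cat")],
    by = "cell", suffix = c("_a", "_b")
  )
  out <- joined |>
    dplyr::mutate(
      d_io = .data$io_cat_b - .data$io_cat_a,
      d_ic = .data$ic_cat_b - .data$ic_cat_a,
      d_tmo = .data$tmo_cat_b - .data$tmo_cat_a,
      abs_io = abs(.data$d_io),
      abs_ic = abs(.data$d_ic),
      abs_tmo = abs(.data$d_tmo),
      total_change = .data$abs_io + .data$abs_ic + .data$abs_tmo
    ) |>
    dplyr::select(dplyr::all_of(c("cell", "row", "col", "x", "y",
                                  "d_io", "d_ic", "d_tmo",
                                  "abs_io", "abs_ic", "abs_tmo", "total_change")))
  structure(out, geometry = clim_geometry(iso_a), class = class(tibble::tibble()))
}

#' Area-weighted isobioclimate transition matrix
#'
#' Cross-tabulates the baseline and comparison codes cell by cell; each entry
#' is the transition area in km^2 (cell count times the geometry-derived cell
#' area). Returned in tidy long form; row sums over `to` give baseline code
#' areas, column sums over `from` give comparison code areas, and the grand
#' total equals the analysed area.
#'
#' @param iso_a,iso_b Classified maps from [classify_grid()] (same geometry).
#' @param geometry Grid geometry; defaults to the one attached to `iso_a`.
#' @return Tibble `from, to, n_cells, area_km2`.
#' @export
transition_matrix <- function(iso_a, iso_b, geometry = clim_geometry(iso_a)) {
  stop_if_geometry_mismatch(geometry, clim_geometry(iso_b), "classified maps")
  area <- cell_area_km2(geometry)
  dplyr::inner_join(iso_a[c("cell", "code")], iso_b[c("cell", "code")],
                    by = "cell", suffix = c("_from", "_to")) |>
    dplyr::count(from = .data$code_from, to = .data$code_to, name = "n_cells") |>
    dplyr::mutate(area_km2 = .data$n_cells * area)
}

#' Pivot a long transition table to a from-by-to matrix
#'
#' @param transitions Output of [transition_matrix()].
#' @param value `"area_km2"` or `"n_cells"`.
#' @return Numeric matrix with `from` codes as rows and `to` codes as columns.
#' @export
transition_wide <- function(transitions, value = c("area_km2", "n_cells")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    transitions[c("from", "to", value)],
    names_from = "to", values_from = dplyr::all_of(value), values_fill = 0
  ) |> dplyr::arrange(.data$from)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$from
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

#' Novel and disappearing isobioclimates across three climatologies
#'
#' Partitions the union of isobioclimate codes seen in a baseline map and two
#' future projections into seven disjoint categories: shared by all three;
#' baseline plus exactly one projection (two categories); baseline only
#' (disappearing); novel in exactly one projection (two categories); and
#' novel in both projections. The first four categories partition the
#' baseline code set, so their code counts sum to the baseline's unique-code
#' count and their baseline areas sum to the analysed area.
#'
#' @param iso_eo Baseline classified map ([classify_grid()]).
#' @param iso_f1,iso_f2 Two future classified maps on the same geometry.
#' @param geometry Grid geometry; defaults to the baseline's.
#' @param labels Length-3 period labels used in messages/plots.
#' @return List of class `novelty_partition`: `table` (tibble `category,
#'   n_codes, area_eo, area_f1, area_f2`), `codes` (named list of the seven
#'   code sets), and `cell_status` (per-cell tibble with the baseline-map
#'   continuity class and the per-projection novelty class).
#' @export
novelty_partition <- function(iso_eo, iso_f1, iso_f2,
                              geometry = clim_geometry(iso_eo),
                              labels = c("eo", "f1", "f2")) {
  stop_if_geometry_mismatch(geometry, clim_geometry(iso_f1), "classified maps")
  stop_if_geometry_mismatch(geometry, clim_geometry(iso_f2), "classified maps")
  eo <- unique(stats::na.omit(iso_eo$code))
  f1 <- unique(stats::na.omit(iso_f1$code))
  f2 <- unique(stats::na.omit(iso_f2$code))
  sets <- list(
    shared_all = intersect(intersect(eo, f1), f2),
    eo_and_f1_only = setdiff(intersect(eo, f1), f2),
    eo_and_f2_only = setdiff(intersect(eo, f2), f1),
    eo_only = setdiff(eo, union(f1, f2)),
    novel_f1_only = setdiff(f1, union(eo, f2)),
    novel_f2_only = setdiff(f2, union(eo, f1)),
    novel_both = setdiff(intersect(f1, f2), eo)
  )
  area <- cell_area_km2(geometry)
  area_in <- function(iso, codes) sum(iso$code %in% codes, na.rm = TRUE) * area
  table <- tibble::tibble(
    category = names(sets),
    n_codes = unname(vapply(sets, length, integer(1))),
    area_eo = unname(vapply(sets, function(s) area_in(iso_eo, s), numeric(1))),
    area_f1 = unname(vapply(sets, function(s) area_in(iso_f1, s), numeric(1))),
    area_f2 = unname(vapply(sets, function(s) area_in(iso_f2, s), numeric(1)))
  )
  member <- function(codes, sets_keep) {
    codes %in% unlist(sets_keep, use.names = FALSE)
  }
  cell_status <- iso_eo[c("cell", "row", "col", "x", "y", "code")] |>
    dplyr::mutate(
      continuity = dplyr::case_when(
        member(.data$code, sets["shared_all"]) ~ "continues_both",
        member(.data$code, sets["eo_and_f1_only"]) ~ "continues_f1_only",
        member(.data$code, sets["eo_and_f2_only"]) ~ "continues_f2_only",
        TRUE ~ "disappears"
      )
    )
  structure(list(table = table, codes = sets, cell_status = cell_status,
                 labels = labels, area_km2 = area),
            class = "novelty_partition")
}

#' @export
print.novelty_partition <- function(x, ...) {
  cat("<novelty_partition> periods:", paste(x$labels, collapse = ", "), "\n")
  print(x$table)
  invisible(x)
}

#' Climate-space table for one or more classified maps
#'
#' Decodes every unique isobioclimate code into its (ombrotype,
#' continentality, thermotype) coordinate in the 3-D climate cube and
#' accumulates the area each code occupies in each period. Total area per
#' period equals the analysed area.
#'
#' @param maps Named list of classified maps ([classify_grid()]), one per
#'   period; all on the same geometry.
#' @return Tibble `period, code, io_cat, ic_cat, tmo_cat, n_cells, area_km2`.
#' @export
climate_space <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- paste0("period", seq_along(maps))
  }
  g <- clim_geometry(maps[[1]])
  for (m in maps) stop_if_geometry_mismatch(g, clim_geometry(m), "classified maps")
  purrr::imap(maps, function(iso, nm) {
    isobioclimate_summary(iso, g) |> dplyr::mutate(period = nm, .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::select(dplyr::all_of(c("period", "code", "io_cat", "ic_cat",
                                  "tmo_cat", "n_cells", "area_km2")))
}
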