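#' Published isobioclimate-overlap accounting
#'
#' `published_overlap_counts()` loads the packaged six-row overlap table
#' (counts and per-period areas, in km^2, of isobioclimates shared between a
#' baseline climatology and two future projections) in the same shape
#' [novelty_partition()] produces. The published rendering of such tables
#' customarily omits the novel-in-both-projections row;
#' `complete_overlap_table()` reconstructs it by set-algebra from the
#' per-period unique-code totals and the total analysed area, since each
#' period's four categories must sum to that period's totals.
#'
#' @return `published_overlap_counts()`: tibble `category, n_codes, area_eo,
#'   area_f1, area_f2` (NA where a category does not exist in a period).
#' @export
published_overlap_counts <- function() {
  path <- system.file("extdata", "published_overlap_counts.csv",
                      package = "isoclim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname published_overlap_counts
#' @param tbl A six-row overlap table (as from `published_overlap_counts()`).
#' @param n_unique Named per-period unique-isobioclimate totals
#'   `c(eo=, f1=, f2=)`.
#' @param area_total Total analysed area per period in km^2.
#' @return `complete_overlap_table()`: `tbl` with the inferred `novel_both`
#'   row appended.
#' @export
complete_overlap_table <- function(tbl, n_unique, area_total) {
  need <- c("shared_all", "eo_and_f1_only", "eo_and_f2_only", "eo_only",
            "novel_f1_only", "novel_f2_only")
  stopifnot(setequal(tbl$category, need))
  g <- function(cat, col) {
    v <- tbl[[col]][tbl$category == cat]
    if (is.na(v)) 0 else v
  }
  in_f1 <- c("shared_all", "eo_and_f1_only", "novel_f1_only")
  in_f2 <- c("shared_all", "eo_and_f2_only", "novel_f2_only")
  n_both_f1 <- n_unique[["f1"]] - sum(vapply(in_f1, g, numeric(1), col = "n_codes"))
  n_both_f2 <- n_unique[["f2"]] - sum(vapply(in_f2, g, numeric(1), col = "n_codes"))
  if (n_both_f1 != n_both_f2) {
    stop("inconsistent per-period totals: the implied novel-in-both count ",
         "differs between projections (", n_both_f1, " vs ", n_both_f2, ")",
         call. = FALSE)
  }
  novel_both <- tibble::tibble(
    category = "novel_both",
    n_codes = as.integer(n_both_f1),
    area_eo = NA_real_,
    area_f1 = area_total - sum(vapply(in_f1, g, numeric(1), col = "area_f1")),
    area_f2 = area_total - sum(vapply(in_f2, g, numeric(1), col = "area_f2"))
  )
  dplyr::bind_rows(tbl, novel_both)
}
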