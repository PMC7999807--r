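#' IUCN threat categories and severity ranking
#'
#' The package works with the six IUCN Red List codes CR (Critically
#' Endangered), EN (Endangered), VU (Vulnerable), NT (Near Threatened),
#' LC (Least Concern) and DD (Data Deficient). The five data-sufficient
#' categories form a total severity order CR > EN > VU > NT > LC; DD carries
#' rank 0 and is never compared by severity.
#'
#' @return `threat_categories()` returns the category codes in decreasing
#'   severity; `category_rank()` maps codes to integer severity ranks
#'   (CR = 5 ... LC = 1, DD = 0); `rank_to_category()` is its inverse for
#'   ranks 1..5.
#' @param category character vector of category codes.
#' @param rank integer vector of severity ranks in 0..5.
#' @examples
#' category_rank(c("CR", "LC", "DD"))
#' rank_to_category(5)
#' @export
threat_categories <- function() c("CR", "EN", "VU", "NT", "LC", "DD")

.CATEGORY_RANKS <- c(CR = 5L, EN = 4L, VU = 3L, NT = 2L, LC = 1L, DD = 0L)

#' @rdname threat_categories
#' @export
category_rank <- function(category) {
  bad <- !is.na(category) & !category %in% names(.CATEGORY_RANKS)
  if (any(bad))
    stop("unknown threat category code(s): ",
         paste(unique(category[bad]), collapse = ", "))
  unname(.CATEGORY_RANKS[category])
}

#' @rdname threat_categories
#' @export
rank_to_category <- function(rank) {
  stopifnot(all(is.na(rank) | (rank >= 0 & rank <= 5)))
  out <- rep(NA_character_, length(rank))
  ok <- !is.na(rank)
  out[ok] <- names(.CATEGORY_RANKS)[match(rank[ok], .CATEGORY_RANKS)]
  out
}

#' Threshold tables for Criteria A and B
#'
#' `criterion_b_thresholds()` returns the standard IUCN Criterion B range
#' thresholds: sub-criterion B1 on extent of occurrence (EOO, km2), B2 on
#' area of occupancy (AOO, km2), both combined with the number of locations.
#' `criterion_a_thresholds()` returns the Criterion A2 population-reduction
#' cutoffs (percent). Both carry an NT "buffer" band for ranges or reductions
#' that miss the VU cutoffs by up to 50 percent; the buffer is a convention of
#' this package (the IUCN criteria define no numeric NT rule) and can be
#' disabled with `nt_buffer = FALSE`, in which case non-triggering taxa are LC.
#'
#' The tables are plain lists so that alternative thresholds can be supplied
#' to [assess_criterion_b()] and [assess_criterion_a()] without touching any
#' logic.
#'
#' @param nt_buffer logical; include the NT buffer band (default `TRUE`).
#' @return a named list of numeric thresholds.
#' @examples
#' criterion_b_thresholds()
#' @export
criterion_b_thresholds <- function(nt_buffer = TRUE) {
  list(
    eoo_km2  = c(CR = 100,  EN = 5000, VU = 20000),
    aoo_km2  = c(CR = 10,   EN = 500,  VU = 2000),
    locations = c(CR = 1L,  EN = 5L,   VU = 10L),
    nt_buffer = isTRUE(nt_buffer),
    nt_eoo_km2 = 30000, nt_aoo_km2 = 3000, nt_locations = 15L
  )
}

#' @rdname criterion_b_thresholds
#' @export
criterion_a_thresholds <- function(nt_buffer = TRUE) {
  list(reduction_pct = c(CR = 80, EN = 50, VU = 30),
       nt_buffer = isTRUE(nt_buffer), nt_reduction_pct = 20)
}
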