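#' Combine Criterion A and B categories per taxon
#'
#' `combine_categories()` is the maximum-severity join on the category
#' lattice: a taxon rated CR by at least one criterion is CR overall, and so
#' on down the severity order. DD on one side yields the other side's
#' category (flagged by the caller's columns); DD on both sides stays DD.
#'
#' `combine_assessments()` merges the Criterion A and B tables by taxon and
#' adds the combined category and the binary `threatened` flag
#' (CR, EN or VU).
#'
#' @param a,b character vectors of category codes.
#' @param assess_a data frame from [criterion_a_batch()] (`taxon`,
#'   `category_A`, ...).
#' @param assess_b data frame from [assess_criterion_b()] (`taxon`,
#'   `category_B`, ...).
#' @return `combine_categories()`: character vector;
#'   `combine_assessments()`: data frame with `taxon`, `category_A`,
#'   `category_B`, `category_combined`, `threatened`.
#' @examples
#' combine_categories("EN", "CR")  # "CR"
#' @export
combine_categories <- function(a, b) {
  stopifnot(length(a) == length(b))
  ra <- category_rank(a); rb <- category_rank(b)
  out <- character(length(a))
  both_dd <- a == "DD" & b == "DD"
  out[both_dd] <- "DD"
  only_a <- b == "DD" & !both_dd
  out[only_a] <- a[only_a]
  only_b <- a == "DD" & !both_dd
  out[only_b] <- b[only_b]
  rest <- !(both_dd | only_a | only_b)
  out[rest] <- rank_to_category(pmax(ra[rest], rb[rest]))
  out
}

#' @rdname combine_categories
#' @export
combine_assessments <- function(assess_a, assess_b) {
  m <- merge(assess_a[c("taxon", "category_A")],
             assess_b[c("taxon", "category_B")], by = "taxon")
  if (nrow(m) == 0) stop("no taxa shared between the two criteria tables")
  m$category_combined <- combine_categories(m$category_A, m$category_B)
  m$threatened <- m$category_combined %in% c("CR", "EN", "VU")
  m[order(m$taxon), , drop = FALSE]
}

#' Validate assessments against a reference table
#'
#' Aggregates categories into threatened (CR, EN, VU) versus not threatened
#' (LC, NT), builds the 2 x 2 confusion matrix against a reference
#' assessment with threatened as the positive class, and reports accuracy
#' (overall agreement) and sensitivity (true positive rate), plus
#' specificity and balanced accuracy as clearly labelled extras. Taxa absent
#' from either table are excluded and counted; predicted or reference DD
#' rows are excluded, as data-deficient taxa cannot enter the binary
#' comparison.
#'
#' @param predicted data frame with `taxon` and `category_combined` (or a
#'   `category` column named via `category_col`).
#' @param reference data frame with `taxon` and `category`.
#' @param category_col column of `predicted` holding the category.
#' @return list with counts `TP`, `FP`, `TN`, `FN`, `n_reference`,
#'   `n_unmatched`, `n_dd_excluded`, and metrics `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy` (sensitivity is `NA` when the
#'   reference holds no threatened taxa).
#' @export
validate_assessments <- function(predicted, reference,
                                 category_col = "category_combined") {
  stopifnot(category_col %in% names(predicted),
            all(c("taxon", "category") %in% names(reference)))
  m <- merge(predicted[c("taxon", category_col)], reference,
             by = "taxon")
  n_unmatched <- nrow(reference) - nrow(m)
  if (nrow(m) == 0) stop("no taxa shared between predictions and reference")
  dd <- m[[category_col]] == "DD" | m$category == "DD"
  n_dd <- sum(dd)
  m <- m[!dd, , drop = FALSE]
  if (nrow(m) == 0) stop("all matched taxa are data deficient")
  pred_t <- category_rank(m[[category_col]]) >= 3
  ref_t <- category_rank(m$category) >= 3
  tp <- sum(pred_t & ref_t); fp <- sum(pred_t & !ref_t)
  tn <- sum(!pred_t & !ref_t); fn <- sum(!pred_t & ref_t)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       n_reference = nrow(m), n_unmatched = n_unmatched,
       n_dd_excluded = n_dd,
       accuracy = (tp + tn) / nrow(m),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)))
}

#' Category proportion summaries
#'
#' Proportion of taxa per category: overall, per criterion, and (when a
#' taxonomy table is given) per family and genus. Families or genera with
#' fewer than `min_n` taxa are excluded from the ranked group tables, so
#' that proportions are not driven by tiny denominators.
#'
#' @param assessments combined-assessment data frame
#'   (see [combine_assessments()]).
#' @param taxonomy optional data frame with `taxon`, `family`, `genus`.
#' @param min_n minimum group size for the per-family/genus tables.
#' @return list of data frames: `overall`, `by_criterion`, and, with a
#'   taxonomy, `by_family` and `by_genus`; proportions are percentages
#'   summing to 100 within each table row group.
#' @export
category_summaries <- function(assessments, taxonomy = NULL, min_n = 10) {
  cats <- c("CR", "EN", "VU", "NT", "LC", "DD")
  tab <- function(x) {
    n <- length(x)
    counts <- vapply(cats, function(cc) sum(x == cc), integer(1))
    data.frame(category = cats, n = counts,
               percent = 100 * counts / n, stringsAsFactors = FALSE)
  }
  out <- list(overall = tab(assessments$category_combined))
  by_crit <- rbind(
    cbind(criterion = "A", tab(assessments$category_A)),
    cbind(criterion = "B", tab(assessments$category_B)),
    cbind(criterion = "combined", tab(assessments$category_combined)))
  out$by_criterion <- by_crit
  if (!is.null(taxonomy)) {
    m <- merge(assessments, taxonomy, by = "taxon")
    group_tab <- function(col) {
      groups <- split(m$category_combined, m[[col]])
      groups <- groups[vapply(groups, length, integer(1)) >= min_n]
      if (length(groups) == 0) return(NULL)
      do.call(rbind, lapply(names(groups), function(g)
        cbind(group = g, tab(groups[[g]]))))
    }
    out$by_family <- group_tab("family")
    out$by_genus <- group_tab("genus")
  }
  out
}
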