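#' Fair-proportion evolutionary distinctiveness
#'
#' Apportions each branch of a rooted, time-calibrated phylogeny equally
#' among the tips descending from it: the ED of a tip is the sum, over the
#' branches on its root-to-tip path, of branch length divided by the number
#' of tips below that branch. Summed over all tips, fair-proportion ED
#' returns exactly the total branch length of the tree (its phylogenetic
#' diversity) — the defining conservation property. Polytomies are handled
#' as given; no arbitrary resolution is applied.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths (Myr).
#' @return named numeric vector of ED values (Myr), one per tip.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
#' fair_proportion_ed(tree)  # A = B = 1.5, C = 2
#' @export
fair_proportion_ed <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least two tips")
  if (sum(tree$edge.length) == 0)
    warning("tree has zero total branch length; all ED values are 0")
  nnode <- ntip + tree$Nnode
  # tips below every node, by post-order accumulation
  ndesc <- integer(nnode)
  ndesc[seq_len(ntip)] <- 1L
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    ndesc[post$edge[k, 1]] <- ndesc[post$edge[k, 1]] + ndesc[post$edge[k, 2]]
  }
  # accumulate the per-tip share root-down (cladewise order visits every
  # edge after its parent edge)
  share <- numeric(nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    share[child] <- share[parent] + pre$edge.length[k] / ndesc[child]
  }
  stats::setNames(share[seq_len(ntip)], tree$tip.label)
}

.GE_WEIGHTS <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L)

#' EDGE score
#'
#' Evolutionarily Distinct and Globally Endangered score
#' `EDGE = ln(1 + ED) + GE * ln 2`, where GE weights the IUCN category
#' (LC = 0, NT = 1, VU = 2, EN = 3, CR = 4): each one-category increase in
#' threat doubles the modelled extinction risk, adding exactly `ln 2` to the
#' score. Natural logarithms throughout. DD taxa have no GE weight and get
#' `NA`.
#'
#' @param ed numeric ED values (Myr, non-negative).
#' @param category character category codes, recycled against `ed`.
#' @return numeric EDGE scores (`NA` for DD or missing categories).
#' @examples
#' edge_score(1, "CR")  # 5 * ln 2
#' @export
edge_score <- function(ed, category) {
  stopifnot(all(is.na(ed) | ed >= 0))
  ge <- .GE_WEIGHTS[category]
  unname(log1p(ed) + ge * log(2))
}

#' Per-taxon EDGE table
#'
#' Joins ED values from the phylogeny with assessed categories. Taxa
#' assessed but absent from the tree are excluded and counted (attribute
#' `"n_missing_from_tree"`); tree tips without an assessment, or assessed
#' DD, get no EDGE score and are excluded from spatial means downstream.
#' The GE weight uses the combined category of the two criteria.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param assessments combined-assessment data frame with `taxon` and
#'   `category_combined`.
#' @return data frame `taxon`, `ed`, `ge`, `edge`, sorted by decreasing
#'   EDGE.
#' @export
edge_scores <- function(tree, assessments) {
  ed <- fair_proportion_ed(tree)
  common <- intersect(names(ed), assessments$taxon)
  n_missing <- sum(!assessments$taxon %in% names(ed))
  cat_map <- stats::setNames(assessments$category_combined,
                             assessments$taxon)
  cats <- cat_map[common]
  out <- data.frame(taxon = common, ed = unname(ed[common]),
                    ge = unname(.GE_WEIGHTS[cats]),
                    edge = edge_score(unname(ed[common]), unname(cats)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$edge, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_from_tree") <- n_missing
  out
}
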