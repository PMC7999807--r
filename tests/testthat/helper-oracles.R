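# Independent oracles used across the suite. Each reimplements a quantity
# by brute force, on a different algorithmic route than the package.

# O(n^3) convex-hull area: a directed pair (i, j) is a hull edge iff every
# other point lies on its left (cross product >= 0); hull vertices are then
# ordered by angle around their centroid and the shoelace formula applied.
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  scale2 <- max(abs(pts))^2
  verts <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
            (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cr >= -1e-12 * scale2)) verts <- c(verts, i, j)
    }
  }
  verts <- unique(verts)
  if (length(verts) < 3) return(0)
  hull <- pts[verts, , drop = FALSE]
  cx <- mean(hull[, 1]); cy <- mean(hull[, 2])
  ord <- order(atan2(hull[, 2] - cy, hull[, 1] - cx))
  hull <- hull[ord, , drop = FALSE]
  x <- hull[, 1]; y <- hull[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# integer-binning oracle: occupied grid cells counted with an explicit loop
# over points and a character key set
oracle_bin_cells <- function(pts, x0, y0, cell_m) {
  keys <- character(0)
  for (k in seq_len(nrow(pts))) {
    i <- floor((pts[k, 1] - x0) / cell_m)
    j <- floor((pts[k, 2] - y0) / cell_m)
    keys <- union(keys, paste(i, j))
  }
  length(keys)
}

# independently coded Criterion B decision table
oracle_b_category <- function(eoo, aoo, loc, nt_buffer = TRUE) {
  eff <- max(eoo, aoo)
  sub <- function(v, t1, t2, t3) {
    if (v < t1 && loc <= 1) return(5)
    if (v < t2 && loc <= 5) return(4)
    if (v < t3 && loc <= 10) return(3)
    0
  }
  r <- max(sub(eff, 100, 5000, 20000), sub(aoo, 10, 500, 2000))
  if (r == 5) return("CR")
  if (r == 4) return("EN")
  if (r == 3) return("VU")
  if (nt_buffer && loc <= 15 && (eff < 30000 || aoo < 3000)) return("NT")
  "LC"
}

# independently coded Criterion A decision table
oracle_a_category <- function(reduction_pct, nt_buffer = TRUE) {
  if (is.na(reduction_pct)) return("DD")
  if (reduction_pct >= 80) "CR"
  else if (reduction_pct >= 50) "EN"
  else if (reduction_pct >= 30) "VU"
  else if (nt_buffer && reduction_pct >= 20) "NT"
  else "LC"
}

# path-walk ED oracle: walks every root-to-tip path with ape::nodepath and
# counts descendant tips per node with phangorn::Descendants
oracle_ed_pathwalk <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ed <- vapply(seq_len(ntip), function(tp) {
    path <- ape::nodepath(tree, root, tp)
    total <- 0
    for (k in seq_len(length(path) - 1)) {
      e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1])
      nd <- length(phangorn::Descendants(tree, path[k + 1], "tips")[[1]])
      total <- total + tree$edge.length[e] / nd
    }
    total
  }, numeric(1))
  stats::setNames(ed, tree$tip.label)
}

# sort-and-slice top-quantile oracle with tie expansion; returns indices
oracle_top_quantile <- function(values, q) {
  k <- ceiling(q * length(values))
  thr <- sort(values, decreasing = TRUE)[k]
  which(values >= thr)
}

# hand-rolled 2x2 tally oracle (positive class = TRUE)
oracle_tally <- function(pred, ref) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] && ref[k]) tp <- tp + 1L
    else if (pred[k] && !ref[k]) fp <- fp + 1L
    else if (!pred[k] && !ref[k]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# a small projection used throughout the unit tests
test_proj <- function(...) projection_spec(24, 38.5, ...)

random_points <- function(n, extent_m = 2e5) {
  cbind(stats::runif(n, -extent_m, extent_m),
        stats::runif(n, -extent_m, extent_m))
}
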