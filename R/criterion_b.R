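#' Range measures for Criterion B
#'
#' `compute_eoo()` returns the extent of occurrence (EOO): the area of the
#' minimum convex polygon around a taxon's projected points, in km2. With
#' fewer than three non-collinear points it returns 0 with attribute
#' `degenerate = TRUE`; the EOO floor (EOO never below AOO) is applied at
#' assessment time, not here.
#'
#' `compute_aoo()` returns the area of occupancy (AOO): the number of
#' distinct occupied AOO grid cells (default 2 x 2 km, the IUCN reference
#' scale) times the cell area, in km2, plus the occupied cell set.
#'
#' `count_locations()` counts IUCN "locations" as distinct occupied coarse
#' grid cells (default 10 x 10 km). This deterministic grid proxy replaces
#' threat-specific location delineation, which needs information occurrence
#' records do not carry.
#'
#' @param points two-column matrix of unique projected points (metres), one
#'   taxon.
#' @param proj a [projection_spec()].
#' @return `compute_eoo()`: numeric km2 with attribute `degenerate`;
#'   `compute_aoo()`: list with `aoo_km2` and integer cell matrix `cells`;
#'   `count_locations()`: positive integer.
#' @examples
#' proj <- projection_spec(24, 38.5)
#' sq <- cbind(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000))
#' compute_eoo(sq)          # 100 km2
#' compute_aoo(sq, proj)$aoo_km2
#' count_locations(sq, proj)
#' @export
compute_eoo <- function(points) {
  if (is.null(nrow(points)) || nrow(points) == 0)
    stop("cannot compute EOO of an empty point set")
  a <- convex_hull_area(points)
  structure(as.numeric(a) / 1e6, degenerate = attr(a, "degenerate"))
}

#' @rdname compute_eoo
#' @export
compute_aoo <- function(points, proj) {
  if (is.null(nrow(points)) || nrow(points) == 0)
    stop("cannot compute AOO of an empty point set")
  cells <- grid_cells(points, proj, proj$aoo_cell_m)
  list(aoo_km2 = nrow(cells) * (proj$aoo_cell_m / 1000)^2, cells = cells)
}

#' @rdname compute_eoo
#' @export
count_locations <- function(points, proj) {
  if (is.null(nrow(points)) || nrow(points) == 0)
    stop("cannot count locations of an empty point set")
  nrow(grid_cells(points, proj, proj$location_cell_m))
}

#' Per-taxon range metrics table
#'
#' Computes EOO, AOO, number of locations and point count for every taxon in
#' a projected point-set list.
#'
#' @param points_list named list of projected point matrices, as returned by
#'   [project_points()].
#' @param proj a [projection_spec()]; defaults to the projection attached to
#'   `points_list`.
#' @return data frame with columns `taxon`, `eoo_km2`, `aoo_km2`,
#'   `n_locations`, `n_points`, `eoo_degenerate`.
#' @export
range_metrics <- function(points_list, proj = attr(points_list, "proj")) {
  stopifnot(inherits(proj, "projection_spec"))
  rows <- lapply(names(points_list), function(tx) {
    pts <- points_list[[tx]]
    eoo <- compute_eoo(pts)
    aoo <- compute_aoo(pts, proj)
    data.frame(taxon = tx, eoo_km2 = as.numeric(eoo),
               aoo_km2 = aoo$aoo_km2,
               n_locations = count_locations(pts, proj),
               n_points = nrow(pts),
               eoo_degenerate = isTRUE(attr(eoo, "degenerate")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# severity rank triggered by one sub-criterion, or 0L
.b_subrank <- function(range_value, range_thresholds, locations,
                       loc_thresholds) {
  if (range_value < range_thresholds[["CR"]] &&
      locations <= loc_thresholds[["CR"]]) return(5L)
  if (range_value < range_thresholds[["EN"]] &&
      locations <= loc_thresholds[["EN"]]) return(4L)
  if (range_value < range_thresholds[["VU"]] &&
      locations <= loc_thresholds[["VU"]]) return(3L)
  0L
}

#' Preliminary Criterion B categorization
#'
#' Assigns each taxon an IUCN Criterion B category from its range metrics.
#' The EOO floor is applied first (`effective_EOO = max(EOO, AOO)`, which
#' also resolves degenerate collinear ranges); sub-criterion B1 then tests
#' the effective EOO and B2 the AOO against the standard thresholds combined
#' with the location counts, and the category is the more severe of the two.
#' Taxa triggering neither fall into NT when they miss the VU cutoffs by at
#' most 50 percent (the configurable buffer of
#' [criterion_b_thresholds()]), else LC.
#'
#' These are preliminary screening assessments: the Criterion B condition of
#' continuing decline/fragmentation is assumed satisfied, as in automated
#' ConR-style assessments, and no full Red List assessment is implied.
#'
#' @param metrics data frame from [range_metrics()] (needs `eoo_km2`,
#'   `aoo_km2`, `n_locations`).
#' @param thresholds threshold table from [criterion_b_thresholds()].
#' @return `metrics` with added columns `effective_eoo_km2`, `category_B`
#'   and `subcriteria_B` (comma-separated subset of "B1","B2", empty unless
#'   threatened).
#' @export
assess_criterion_b <- function(metrics, thresholds = criterion_b_thresholds()) {
  stopifnot(all(c("eoo_km2", "aoo_km2", "n_locations") %in% names(metrics)))
  if (any(metrics$n_locations <= 0))
    stop("non-positive location counts in metrics")
  n <- nrow(metrics)
  category <- character(n); sub <- character(n)
  eff <- pmax(metrics$eoo_km2, metrics$aoo_km2)
  for (k in seq_len(n)) {
    loc <- metrics$n_locations[k]
    r1 <- .b_subrank(eff[k], thresholds$eoo_km2, loc, thresholds$locations)
    r2 <- .b_subrank(metrics$aoo_km2[k], thresholds$aoo_km2, loc,
                     thresholds$locations)
    r <- max(r1, r2)
    if (r >= 3L) {
      category[k] <- rank_to_category(r)
      sub[k] <- paste(c("B1", "B2")[c(r1 == r, r2 == r)], collapse = ",")
    } else if (isTRUE(thresholds$nt_buffer) &&
               (eff[k] < thresholds$nt_eoo_km2 ||
                metrics$aoo_km2[k] < thresholds$nt_aoo_km2) &&
               loc <= thresholds$nt_locations) {
      category[k] <- "NT"; sub[k] <- ""
    } else {
      category[k] <- "LC"; sub[k] <- ""
    }
  }
  metrics$effective_eoo_km2 <- eff
  metrics$category_B <- category
  metrics$subcriteria_B <- sub
  metrics
}
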