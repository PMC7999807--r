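#' Grid taxa onto the mapping grid
#'
#' Assigns each taxon to every map cell (default 5 x 5 km) holding at least
#' one of its points: presence, not abundance.
#'
#' @param points_list named list of projected point matrices.
#' @param proj a [projection_spec()].
#' @return a list with `cells` (data frame `i`, `j`, `x_min`, `y_min`) and
#'   `taxa` (list of character vectors, one per cell row).
#' @export
rasterize_taxa <- function(points_list, proj = attr(points_list, "proj")) {
  stopifnot(inherits(proj, "projection_spec"))
  s <- proj$map_cell_m
  per_taxon <- lapply(points_list, grid_cells, proj = proj, cell_m = s)
  keys <- unlist(lapply(names(per_taxon), function(tx) {
    ij <- per_taxon[[tx]]
    paste(ij[, 1], ij[, 2], sep = ":")
  }), use.names = FALSE)
  taxa <- rep(names(per_taxon),
              vapply(per_taxon, nrow, integer(1)))
  cellmap <- split(taxa, keys)
  ij <- do.call(rbind, strsplit(names(cellmap), ":", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  ord <- order(i, j)
  cells <- data.frame(i = i[ord], j = j[ord],
                      x_min = proj$x0 + i[ord] * s,
                      y_min = proj$y0 + j[ord] * s)
  list(cells = cells, taxa = unname(cellmap[ord]))
}

#' Per-cell richness and EDGE surfaces
#'
#' Builds the 5-km grid surfaces: per occupied cell, the number of endemic
#' taxa present (`n_endemic`), of threatened taxa (`n_threatened`, CR/EN/VU
#' by the combined category), of CR taxa (`n_cr`), and the arithmetic mean
#' EDGE score over the scored taxa present (`mean_edge`, `NA` where no
#' scored taxon occurs). Taxa without an assessment count toward `n_endemic`
#' only.
#'
#' @param cellmap result of [rasterize_taxa()].
#' @param assessments combined-assessment data frame.
#' @param edge_table optional data frame from [edge_scores()].
#' @return data frame (class `grid_surface`): `i`, `j`, `x_min`, `y_min`,
#'   `n_endemic`, `n_threatened`, `n_cr`, `mean_edge`.
#' @export
build_surfaces <- function(cellmap, assessments, edge_table = NULL) {
  cat_map <- stats::setNames(assessments$category_combined,
                             assessments$taxon)
  edge_map <- if (!is.null(edge_table))
    stats::setNames(edge_table$edge, edge_table$taxon) else numeric(0)
  n <- nrow(cellmap$cells)
  n_end <- integer(n); n_thr <- integer(n); n_cr <- integer(n)
  mean_edge <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    taxa <- cellmap$taxa[[k]]
    n_end[k] <- length(taxa)
    cats <- cat_map[taxa]
    n_thr[k] <- sum(cats %in% c("CR", "EN", "VU"))
    n_cr[k] <- sum(cats == "CR", na.rm = TRUE)
    ev <- edge_map[taxa]
    ev <- ev[!is.na(ev)]
    if (length(ev) > 0) mean_edge[k] <- mean(ev)
  }
  out <- cbind(cellmap$cells,
               data.frame(n_endemic = n_end, n_threatened = n_thr,
                          n_cr = n_cr, mean_edge = mean_edge))
  class(out) <- c("grid_surface", "data.frame")
  out
}

.HOTSPOT_METRICS <- c(GR = "n_endemic", CR_END = "n_cr", EDGE = "mean_edge")

#' L1 (top-1%) hotspot extraction
#'
#' Selects the cells with the highest values of a surface metric: the L1
#' hotspots are the top `quantile` fraction (default 1 percent) of eligible
#' cells. The threshold is the k-th largest metric value with
#' `k = ceiling(quantile * n_eligible)`, and every cell at or above it is a
#' member, so ties at the threshold can push the set slightly past 1
#' percent. Eligible cells are the occupied cells of the surface (cells with
#' no endemic taxon are never counted; for the EDGE metric, cells with no
#' scored taxon are also ineligible). `eligible = "all"` instead takes the
#' quantile over a stated total number of grid cells, counting the
#' unoccupied remainder as zeros.
#'
#' @param surface a [build_surfaces()] data frame.
#' @param metric `"GR"` (endemic richness), `"CR_END"` (CR richness) or
#'   `"EDGE"` (mean EDGE).
#' @param quantile top fraction to extract (default `0.01`).
#' @param eligible `"occupied"` (default) or `"all"`.
#' @param n_cells_total total cell count for `eligible = "all"`.
#' @return list (class `hotspot_set`): `metric`, `threshold`,
#'   `n_eligible`, `cells` (subset of surface rows), `quantile`.
#' @export
l1_hotspots <- function(surface, metric = c("GR", "CR_END", "EDGE"),
                        quantile = 0.01,
                        eligible = c("occupied", "all"),
                        n_cells_total = NULL) {
  metric <- match.arg(metric)
  eligible <- match.arg(eligible)
  col <- .HOTSPOT_METRICS[[metric]]
  vals <- surface[[col]]
  keep <- !is.na(vals)
  vals <- vals[keep]
  if (length(vals) == 0) stop("no eligible cells for metric ", metric)
  n_elig <- if (eligible == "all") {
    if (is.null(n_cells_total)) stop("n_cells_total required for 'all'")
    if (n_cells_total < length(vals))
      stop("n_cells_total smaller than the number of occupied cells")
    n_cells_total
  } else length(vals)
  k <- ceiling(quantile * n_elig)
  sorted <- sort(vals, decreasing = TRUE)
  if (k > length(sorted)) k <- length(sorted)  # top slice is all occupied
  threshold <- sorted[k]
  if (min(vals) == max(vals))
    warning("all eligible cells share one metric value; ",
            "every cell is a hotspot")
  members <- which(keep)[vals >= threshold]
  structure(list(metric = metric, threshold = threshold,
                 n_eligible = n_elig, quantile = quantile,
                 cells = surface[members, , drop = FALSE]),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("L1 hotspots (", x$metric, "): ", nrow(x$cells), " of ",
      x$n_eligible, " eligible cells at threshold ",
      signif(x$threshold, 6), "\n", sep = "")
  invisible(x)
}

#' Protected-area overlap of hotspot cells
#'
#' Flags each hotspot cell as inside the protected-area network iff the
#' full square cell geometrically intersects at least one PA polygon
#' (default), or iff the cell centroid falls in a PA
#' (`mode = "centroid"`). Reports the counts and the percentage of hotspot
#' cells outside the network — the PA gap.
#'
#' @param hotspots a [l1_hotspots()] result.
#' @param pas list of PA polygons (two-column vertex matrices, projected
#'   metres).
#' @param proj a [projection_spec()] (for the map cell size).
#' @param mode `"intersect"` (default) or `"centroid"`.
#' @return list: `n_hotspots`, `n_inside`, `n_outside`, `pct_inside`,
#'   `pct_outside`, `mode`, and `cells` with an `inside_pa` flag.
#' @export
pa_overlap <- function(hotspots, pas, proj, mode = c("intersect", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hotspots, "hotspot_set"),
            inherits(proj, "projection_spec"))
  cells <- hotspots$cells
  s <- proj$map_cell_m
  if (length(pas) == 0) {
    warning("empty protected-area set; all hotspot cells are outside")
    inside <- rep(FALSE, nrow(cells))
  } else {
    inside <- vapply(seq_len(nrow(cells)), function(k) {
      xmin <- cells$x_min[k]; ymin <- cells$y_min[k]
      if (mode == "centroid") {
        any(vapply(pas, function(p)
          point_in_polygon(xmin + s / 2, ymin + s / 2, p), logical(1)))
      } else {
        any(vapply(pas, function(p)
          rect_intersects_polygon(xmin, ymin, xmin + s, ymin + s, p),
          logical(1)))
      }
    }, logical(1))
  }
  cells$inside_pa <- inside
  n <- nrow(cells)
  list(n_hotspots = n, n_inside = sum(inside), n_outside = sum(!inside),
       pct_inside = 100 * sum(inside) / n,
       pct_outside = 100 * sum(!inside) / n,
       mode = mode, cells = cells)
}

#' Export hotspot cells as GeoJSON polygons
#'
#' Writes each hotspot cell as a square polygon feature. Cell corners are
#' inverse-projected to WGS84 degrees.
#'
#' @param hotspots a [l1_hotspots()] result.
#' @param proj the [projection_spec()] used to build the surface.
#' @param path output file path.
#' @export
write_hotspots_geojson <- function(hotspots, proj, path) {
  cells <- hotspots$cells
  s <- proj$map_cell_m
  polys <- lapply(seq_len(nrow(cells)), function(k) {
    xmin <- cells$x_min[k]; ymin <- cells$y_min[k]
    corners <- rbind(c(xmin, ymin), c(xmin + s, ymin),
                     c(xmin + s, ymin + s), c(xmin, ymin + s))
    unproject_xy(corners[, 1], corners[, 2], proj)
  })
  props <- data.frame(metric = hotspots$metric, i = cells$i, j = cells$j,
                      value = cells[[.HOTSPOT_METRICS[[hotspots$metric]]]])
  write_geojson_polygons(polys, path, properties = props)
}
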