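#' Land-cover layers
#'
#' Criterion A infers potential population reduction from the overlap of a
#' taxon's occupied cells with land-cover classes of moderate-to-high human
#' influence (in the CORINE nomenclature: level-1 artificial and level-2
#' agricultural classes, excluding olive groves, code 223, and the mixed
#' agricultural/natural classes 243 and 244, which behave as semi-natural
#' habitat). Two layer forms are supported:
#'
#' * `landcover_raster()` — a categorical raster: integer class codes on a
#'   regular grid, queried by pixel;
#' * `landcover_polygons()` — class-labelled polygons, queried by
#'   point-in-polygon.
#'
#' @param x0,y0 raster origin (lower-left corner), metres.
#' @param res_m pixel size, metres.
#' @param codes integer matrix of class codes, `codes[row, col]` with column
#'   = x index (west to east) and row = y index (south to north).
#' @param threat_classes integer vector of class codes counted as threats.
#' @param polygons list of two-column vertex matrices (projected metres).
#' @param class_codes integer vector, one class code per polygon.
#' @return an object of class `landcover_raster` or `landcover_polygons`.
#' @export
landcover_raster <- function(x0, y0, res_m, codes, threat_classes) {
  stopifnot(is.matrix(codes), res_m > 0)
  structure(list(x0 = x0, y0 = y0, res_m = res_m, codes = codes,
                 nrow = nrow(codes), ncol = ncol(codes),
                 threat_classes = as.integer(threat_classes)),
            class = c("landcover_raster", "landcover"))
}

#' @rdname landcover_raster
#' @export
landcover_polygons <- function(polygons, class_codes, threat_classes) {
  stopifnot(length(polygons) == length(class_codes))
  structure(list(polygons = polygons, class_codes = as.integer(class_codes),
                 threat_classes = as.integer(threat_classes)),
            class = c("landcover_polygons", "landcover"))
}

#' Land-cover class at query points
#'
#' @param lc a land-cover layer.
#' @param x,y projected coordinates, metres.
#' @return integer class codes; `NA` where the layer has no data (outside
#'   the raster extent, or outside every polygon).
#' @export
landcover_class_at <- function(lc, x, y) {
  UseMethod("landcover_class_at")
}

#' @export
landcover_class_at.landcover_raster <- function(lc, x, y) {
  ci <- floor((x - lc$x0) / lc$res_m) + 1
  ri <- floor((y - lc$y0) / lc$res_m) + 1
  ok <- ci >= 1 & ci <= lc$ncol & ri >= 1 & ri <= lc$nrow
  out <- rep(NA_integer_, length(x))
  out[ok] <- lc$codes[cbind(ri[ok], ci[ok])]
  out
}

#' @export
landcover_class_at.landcover_polygons <- function(lc, x, y) {
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(lc$polygons)) {
    undecided <- is.na(out)
    if (!any(undecided)) break
    hit <- point_in_polygon(x[undecided], y[undecided], lc$polygons[[k]])
    out[undecided][hit] <- lc$class_codes[k]
  }
  out
}

#' Classify occupied cells as threatened habitat or not
#'
#' Flags each occupied AOO cell against the land-cover layer. For a raster
#' layer the rule is a pixel-count majority: the cell is `"threatened"` iff
#' strictly more of its known pixels (pixel centres falling inside the cell)
#' belong to threat classes than not; ties go to `"natural"`. For a polygon
#' layer the class at the cell centroid decides. Cells with no land-cover
#' data are `"unknown"`.
#'
#' @param cells integer matrix of occupied cell indices (`i`,`j`) from
#'   [compute_aoo()].
#' @param proj a [projection_spec()].
#' @param lc a land-cover layer.
#' @return character vector (one of `"threatened"`, `"natural"`,
#'   `"unknown"`) per cell, with the decision mode in attribute `"mode"`.
#' @export
classify_cells <- function(cells, proj, lc) {
  stopifnot(inherits(proj, "projection_spec"), inherits(lc, "landcover"))
  s <- proj$aoo_cell_m
  status <- character(nrow(cells))
  if (inherits(lc, "landcover_raster")) {
    mode <- "raster-majority"
    for (k in seq_len(nrow(cells))) {
      xmin <- proj$x0 + cells[k, 1] * s
      ymin <- proj$y0 + cells[k, 2] * s
      # pixel centres inside the half-open cell
      cx0 <- lc$x0 + (floor((xmin - lc$x0) / lc$res_m) + 0.5) * lc$res_m
      cxs <- seq(cx0, by = lc$res_m, length.out = ceiling(s / lc$res_m) + 1)
      cxs <- cxs[cxs >= xmin & cxs < xmin + s]
      cy0 <- lc$y0 + (floor((ymin - lc$y0) / lc$res_m) + 0.5) * lc$res_m
      cys <- seq(cy0, by = lc$res_m, length.out = ceiling(s / lc$res_m) + 1)
      cys <- cys[cys >= ymin & cys < ymin + s]
      if (length(cxs) == 0 || length(cys) == 0) {
        # cell smaller than a pixel: fall back to the centroid pixel
        cl <- landcover_class_at(lc, xmin + s / 2, ymin + s / 2)
      } else {
        g <- expand.grid(x = cxs, y = cys)
        cl <- landcover_class_at(lc, g$x, g$y)
      }
      known <- cl[!is.na(cl)]
      if (length(known) == 0) {
        status[k] <- "unknown"
      } else {
        nthreat <- sum(known %in% lc$threat_classes)
        status[k] <- if (nthreat > length(known) - nthreat) "threatened"
                     else "natural"
      }
    }
  } else {
    mode <- "polygon-centroid"
    cx <- proj$x0 + (cells[, 1] + 0.5) * s
    cy <- proj$y0 + (cells[, 2] + 0.5) * s
    cl <- landcover_class_at(lc, cx, cy)
    status <- ifelse(is.na(cl), "unknown",
                     ifelse(cl %in% lc$threat_classes, "threatened",
                            "natural"))
  }
  structure(status, mode = mode)
}

#' Criterion A categorization from habitat-threat flags
#'
#' The potential population reduction of a taxon is taken as the percentage
#' of its occupied cells (with known land cover) lying in threatened
#' habitat — a static habitat-quality proxy for the taxon's potential
#' decrease in AOO. Categories follow the Criterion A2 reduction cutoffs:
#' CR at 80 percent and above, EN at 50, VU at 30, with an NT buffer at 20
#' (configurable, see [criterion_a_thresholds()]). Cells of unknown class
#' are excluded from the denominator; a taxon whose cells are all unknown
#' is Data Deficient (DD) under this criterion.
#'
#' @param flags character vector of per-cell statuses from
#'   [classify_cells()] (or per-occurrence statuses in occurrence mode).
#' @param thresholds threshold table from [criterion_a_thresholds()].
#' @return list with `n_cells`, `n_known`, `n_threatened`, `n_unknown`,
#'   `threatened_fraction`, `reduction_pct` and `category`.
#' @export
assess_criterion_a <- function(flags, thresholds = criterion_a_thresholds()) {
  if (length(flags) == 0) stop("no occupied cells to assess")
  n_threat <- sum(flags == "threatened")
  n_unknown <- sum(flags == "unknown")
  n_known <- length(flags) - n_unknown
  if (n_known == 0) {
    return(list(n_cells = length(flags), n_known = 0L,
                n_threatened = 0L, n_unknown = n_unknown,
                threatened_fraction = NA_real_, reduction_pct = NA_real_,
                category = "DD"))
  }
  frac <- n_threat / n_known
  red <- 100 * frac
  th <- thresholds$reduction_pct
  category <- if (red >= th[["CR"]]) "CR"
    else if (red >= th[["EN"]]) "EN"
    else if (red >= th[["VU"]]) "VU"
    else if (isTRUE(thresholds$nt_buffer) &&
             red >= thresholds$nt_reduction_pct) "NT"
    else "LC"
  list(n_cells = length(flags), n_known = as.integer(n_known),
       n_threatened = as.integer(n_threat),
       n_unknown = as.integer(n_unknown),
       threatened_fraction = frac, reduction_pct = red, category = category)
}

#' Batch Criterion A assessment over taxa
#'
#' Runs [classify_cells()] and [assess_criterion_a()] for every taxon. The
#' default unit of analysis is the occupied 2-km AOO cell, matching the
#' potential-decrease-in-AOO reading of the criterion;
#' `unit = "occurrence"` instead classifies each unique occurrence point by
#' the class at that point, for sensitivity analysis.
#'
#' @param points_list named list of projected point matrices.
#' @param proj a [projection_spec()].
#' @param lc a land-cover layer.
#' @param thresholds table from [criterion_a_thresholds()].
#' @param unit `"cell"` (default) or `"occurrence"`.
#' @return data frame with one row per taxon: `taxon`, `n_cells`,
#'   `n_threatened`, `n_unknown`, `reduction_pct`, `category_A`.
#' @export
criterion_a_batch <- function(points_list, proj, lc,
                              thresholds = criterion_a_thresholds(),
                              unit = c("cell", "occurrence")) {
  unit <- match.arg(unit)
  rows <- lapply(names(points_list), function(tx) {
    pts <- points_list[[tx]]
    flags <- if (unit == "cell") {
      classify_cells(compute_aoo(pts, proj)$cells, proj, lc)
    } else {
      cl <- landcover_class_at(lc, pts[, 1], pts[, 2])
      ifelse(is.na(cl), "unknown",
             ifelse(cl %in% lc$threat_classes, "threatened", "natural"))
    }
    a <- assess_criterion_a(flags, thresholds)
    data.frame(taxon = tx, n_cells = a$n_cells,
               n_threatened = a$n_threatened, n_unknown = a$n_unknown,
               reduction_pct = a$reduction_pct, category_A = a$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  out
}
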