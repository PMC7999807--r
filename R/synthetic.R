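#' Synthetic study scenario
#'
#' Defines a seeded, fully reproducible stand-in for a national endemic
#' flora study: clustered per-taxon occurrence ranges whose Criterion B
#' category is fixed by construction, a categorical land-cover mosaic with a
#' tunable threat fraction, an ultrametric pure-birth phylogeny over the
#' taxa, and a protected-area network of non-overlapping rectangles covering
#' a tunable fraction of the domain. Default values sketch a
#' Mediterranean-country setting: a 500 x 400 km domain, a land-cover mosaic
#' with 30 percent human-influence classes, and protected areas covering 28
#' percent of the territory. The generator reproduces the *structure* of
#' such data, not the spatial statistics of any real flora.
#'
#' Category designs work through the location grid (10-km cells): a CR taxon
#' is one tight cluster (1.2 km radius disc) inside a single location cell;
#' EN, VU, NT and LC taxa spread 2-4, 7-10, 11-15 and 16-24 such clusters
#' over windows sized so the convex hull stays under the relevant EOO
#' cutoff. One integer seed drives every generator through a documented
#' stream-splitting scheme (five sub-seeds drawn once from the master seed:
#' occurrences, land cover, phylogeny, protected areas, reference subset).
#'
#' @param n_taxa number of taxa.
#' @param seed master integer seed.
#' @param domain_km domain width and height, km.
#' @param center projection/domain centre, degrees (`lon`, `lat`).
#' @param category_mix named proportions of designed Criterion B categories
#'   (CR, EN, VU, NT, LC); normalised to sum 1.
#' @param points_per_cluster occurrence points per cluster.
#' @param threat_fraction fraction of land-cover pixels in threat classes.
#' @param lc_res_m land-cover pixel size, metres.
#' @param pa_cover target fraction of the domain under protected areas.
#' @param pa_block_km protected-area rectangle size, km.
#' @param root_age phylogeny root age, Myr.
#' @param ref_fraction fraction of taxa included in the reference table.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_taxa = 200, seed = 1,
                               domain_km = c(width = 500, height = 400),
                               center = c(lon = 24, lat = 38.5),
                               category_mix = c(CR = 0.20, EN = 0.20,
                                                VU = 0.20, NT = 0.15,
                                                LC = 0.25),
                               points_per_cluster = 8,
                               threat_fraction = 0.30, lc_res_m = 1000,
                               pa_cover = 0.28, pa_block_km = 20,
                               root_age = 100, ref_fraction = 1) {
  stopifnot(n_taxa >= 2, length(domain_km) == 2, all(domain_km > 0),
            threat_fraction >= 0, threat_fraction <= 1,
            pa_cover >= 0, pa_cover <= 1,
            ref_fraction > 0, ref_fraction <= 1, root_age > 0,
            all(names(category_mix) %in% c("CR", "EN", "VU", "NT", "LC")))
  if (any(domain_km %% 20 != 0))
    stop("domain dimensions must be multiples of 20 km so the location ",
         "and block grids tile the domain")
  category_mix <- category_mix / sum(category_mix)
  # one master seed, four documented sub-streams
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  structure(list(n_taxa = n_taxa, seed = seed, sub_seeds = sub_seeds,
                 domain_km = unname(domain_km), center = unname(center),
                 category_mix = category_mix,
                 points_per_cluster = points_per_cluster,
                 threat_fraction = threat_fraction, lc_res_m = lc_res_m,
                 pa_cover = pa_cover, pa_block_km = pa_block_km,
                 root_age = root_age, ref_fraction = ref_fraction),
            class = "synthetic_scenario")
}

#' @rdname synthetic_scenario
#' @param scenario a `synthetic_scenario`.
#' @return `scenario_projection()` returns the equal-area
#'   [projection_spec()] centred on the scenario domain, origin at the
#'   domain centre.
#' @export
scenario_projection <- function(scenario) {
  projection_spec(scenario$center[1], scenario$center[2])
}

# designed location-cluster counts and window sizes (location cells) that
# pin the Criterion B category by construction:
#   CR: 1 cluster in 1 cell -> 1 location, hull < 5 km2 < 100
#   EN: 2-4 clusters in a 6x6-cell window -> hull < 3600 < 5000, loc <= 5
#   VU: 7-10 clusters in a 12x10 window -> hull < 12000 < 20000, loc 7-10
#   NT: 11-15 clusters in a 16x14 window -> hull < 22400 < 30000, loc <= 15
#   LC: 16-24 clusters domain-wide -> loc > 15
.DESIGNS <- list(
  CR = list(n_loc = 1:1,   window = c(1, 1)),
  EN = list(n_loc = 2:4,   window = c(6, 6)),
  VU = list(n_loc = 7:10,  window = c(12, 10)),
  NT = list(n_loc = 11:15, window = c(16, 14)),
  LC = list(n_loc = 16:24, window = NULL))

.CLUSTER_RADIUS_M <- 1200

#' Generate designed occurrence records
#'
#' Draws clustered per-taxon occurrences whose Criterion B category is
#' fixed by construction (see [synthetic_scenario()]), as isotropic discs
#' of points around the centres of designed location cells, and returns the
#' records in WGS84 degrees together with the design ground truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `occurrences` (data frame `taxon`, `lon`, `lat`) and
#'   `truth` (data frame `taxon`, `category_design`, `n_locations_design`).
#' @export
generate_occurrences <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$sub_seeds[1])
  proj <- scenario_projection(scenario)
  loc_m <- proj$location_cell_m
  nw <- as.integer(scenario$domain_km[1] * 1000 / loc_m)
  nh <- as.integer(scenario$domain_km[2] * 1000 / loc_m)
  # location-cell index ranges for the centred domain
  i_min <- -nw %/% 2L; j_min <- -nh %/% 2L
  counts <- round(scenario$category_mix * scenario$n_taxa)
  while (sum(counts) != scenario$n_taxa) {
    k <- which.max(counts)
    counts[k] <- counts[k] + sign(scenario$n_taxa - sum(counts))
  }
  categories <- sample(rep(names(counts), counts))
  taxa <- sprintf("taxon_%03d", seq_len(scenario$n_taxa))
  rows <- vector("list", scenario$n_taxa)
  truth_loc <- integer(scenario$n_taxa)
  for (t in seq_len(scenario$n_taxa)) {
    d <- .DESIGNS[[categories[t]]]
    n_loc <- if (length(d$n_loc) == 1) d$n_loc else sample(d$n_loc, 1)
    truth_loc[t] <- n_loc
    if (is.null(d$window)) {       # domain-wide (LC)
      wi <- nw; wj <- nh; oi <- i_min; oj <- j_min
    } else {
      wi <- min(d$window[1], nw); wj <- min(d$window[2], nh)
      oi <- i_min + sample.int(nw - wi + 1L, 1) - 1L
      oj <- j_min + sample.int(nh - wj + 1L, 1) - 1L
    }
    cell_ids <- sample.int(wi * wj, n_loc) - 1L
    ci <- oi + cell_ids %% wi
    cj <- oj + cell_ids %/% wi
    pts <- do.call(rbind, lapply(seq_len(n_loc), function(k) {
      np <- scenario$points_per_cluster
      r <- .CLUSTER_RADIUS_M * sqrt(stats::runif(np))
      th <- stats::runif(np, 0, 2 * pi)
      cbind((ci[k] + 0.5) * loc_m + r * cos(th),
            (cj[k] + 0.5) * loc_m + r * sin(th))
    }))
    ll <- unproject_xy(pts[, 1], pts[, 2], proj)
    rows[[t]] <- data.frame(taxon = taxa[t], lon = ll[, 1], lat = ll[, 2],
                            stringsAsFactors = FALSE)
  }
  list(occurrences = do.call(rbind, rows),
       truth = data.frame(taxon = taxa, category_design = categories,
                          n_locations_design = truth_loc,
                          stringsAsFactors = FALSE))
}

# land-cover class codes emulating a CORINE-like nomenclature: artificial
# (111, 121) and intensive-agriculture (211, 221) classes are threats;
# olive-grove-analogue 223 and mixed agriculture 243 are agricultural but
# excluded from the threat set; 311/321 are natural.
.LC_THREAT_CODES <- c(111L, 121L, 211L, 221L)
.LC_NATURAL_CODES <- c(311L, 321L, 223L, 243L)

#' Generate a categorical land-cover raster
#'
#' A pixel mosaic over the scenario domain whose realized threat-class
#' fraction equals the target to within one pixel (the threat pixel count
#' is drawn exactly). The non-threat pool includes agricultural classes
#' excluded from the threat set (codes 223 and 243), so the exclusion rule
#' is exercised.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [landcover_raster()].
#' @export
generate_landcover <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$sub_seeds[2])
  w <- scenario$domain_km[1] * 1000; h <- scenario$domain_km[2] * 1000
  ncol <- as.integer(w / scenario$lc_res_m)
  nrow <- as.integer(h / scenario$lc_res_m)
  n <- ncol * nrow
  n_threat <- round(scenario$threat_fraction * n)
  codes <- sample(.LC_NATURAL_CODES, n, replace = TRUE)
  if (n_threat > 0) {
    idx <- sample.int(n, n_threat)
    codes[idx] <- sample(.LC_THREAT_CODES, n_threat, replace = TRUE)
  }
  landcover_raster(x0 = -w / 2, y0 = -h / 2, res_m = scenario$lc_res_m,
                   codes = matrix(codes, nrow = nrow, ncol = ncol),
                   threat_classes = .LC_THREAT_CODES)
}

#' Generate an ultrametric pure-birth phylogeny
#'
#' Simulates a pure-birth (Yule) tree over the given taxa and rescales it so
#' the root age equals `root_age` (default from the scenario, 100 Myr). Tip
#' labels are a random permutation of the taxon ids.
#'
#' @param taxa character vector of taxon ids (tips).
#' @param seed integer seed (scenario sub-stream 3 when called from
#'   [generate_inputs()]).
#' @param root_age root age in Myr.
#' @return an ultrametric [ape::phylo] tree.
#' @export
generate_tree <- function(taxa, seed, root_age = 100) {
  stopifnot(length(taxa) >= 2, !anyDuplicated(taxa), root_age > 0)
  set.seed(seed)
  tree <- ape::rphylo(length(taxa), birth = 0.1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * root_age / depth
  tree$tip.label <- sample(taxa)
  tree
}

#' Generate a protected-area network
#'
#' Non-overlapping square protected areas drawn on a coarse block partition
#' of the domain (block size `pa_block_km`), with the realized coverage
#' equal to the target up to half a block.
#'
#' @param scenario a [synthetic_scenario()].
#' @return named list of rectangle polygons (two-column vertex matrices,
#'   projected metres); empty when `pa_cover = 0`.
#' @export
generate_pas <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$sub_seeds[4])
  b <- scenario$pa_block_km * 1000
  w <- scenario$domain_km[1] * 1000; h <- scenario$domain_km[2] * 1000
  nbx <- as.integer(w / b); nby <- as.integer(h / b)
  n_blocks <- round(scenario$pa_cover * nbx * nby)
  if (n_blocks == 0) return(stats::setNames(list(), character(0)))
  picked <- sample.int(nbx * nby, n_blocks) - 1L
  polys <- lapply(picked, function(p) {
    bx <- -w / 2 + (p %% nbx) * b
    by <- -h / 2 + (p %/% nbx) * b
    cbind(c(bx, bx + b, bx + b, bx), c(by, by, by + b, by + b))
  })
  names(polys) <- sprintf("PA_%03d", seq_along(polys))
  polys
}

#' Serialize a land-cover raster
#'
#' JSON container for the categorical raster (origin, resolution, flattened
#' class codes, threat-class set), readable by [read_landcover()].
#'
#' @param lc a [landcover_raster()].
#' @param path file path.
#' @export
write_landcover <- function(lc, path) {
  stopifnot(inherits(lc, "landcover_raster"))
  jsonlite::write_json(
    list(x0 = lc$x0, y0 = lc$y0, res_m = lc$res_m,
         nrow = lc$nrow, ncol = lc$ncol,
         threat_classes = lc$threat_classes,
         codes = as.integer(lc$codes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landcover
#' @export
read_landcover <- function(path) {
  if (!file.exists(path)) stop("land-cover file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landcover_raster(x$x0, x$y0, x$res_m,
                   matrix(as.integer(x$codes), nrow = x$nrow,
                          ncol = x$ncol),
                   as.integer(x$threat_classes))
}

#' Write all scenario inputs to disk
#'
#' Materialises a scenario as the exact file formats the pipeline reads:
#' `occurrences.csv`, `landcover.json`, `tree.nwk`, `pas.geojson` (WGS84
#' degrees), `reference.csv` (designed categories for a `ref_fraction`
#' subset of taxa) and `truth.csv`, plus `scenario.json` echoing the
#' configuration.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return named list of the file paths, invisibly; the ground-truth table
#'   is attached as attribute `"truth"`.
#' @export
generate_inputs <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proj <- scenario_projection(scenario)
  occ <- generate_occurrences(scenario)
  lc <- generate_landcover(scenario)
  tree <- generate_tree(occ$truth$taxon, scenario$sub_seeds[3],
                        scenario$root_age)
  pas <- generate_pas(scenario)
  paths <- list(occurrences = file.path(dir, "occurrences.csv"),
                landcover = file.path(dir, "landcover.json"),
                tree = file.path(dir, "tree.nwk"),
                pas = file.path(dir, "pas.geojson"),
                reference = file.path(dir, "reference.csv"),
                truth = file.path(dir, "truth.csv"),
                scenario = file.path(dir, "scenario.json"))
  write_occurrences(occ$occurrences, paths$occurrences)
  write_landcover(lc, paths$landcover)
  ape::write.tree(tree, paths$tree)
  pas_ll <- lapply(pas, function(p) unproject_xy(p[, 1], p[, 2], proj))
  write_geojson_polygons(pas_ll, paths$pas)
  set.seed(scenario$sub_seeds[5])  # reference-subsample stream
  ref_idx <- sort(sample.int(nrow(occ$truth),
                             max(1, round(scenario$ref_fraction *
                                            nrow(occ$truth)))))
  utils::write.csv(data.frame(taxon = occ$truth$taxon[ref_idx],
                              category = occ$truth$category_design[ref_idx]),
                   paths$reference, row.names = FALSE)
  utils::write.csv(occ$truth, paths$truth, row.names = FALSE)
  cfg <- unclass(scenario)
  jsonlite::write_json(cfg, paths$scenario, auto_unbox = TRUE, digits = NA)
  attr(paths, "truth") <- occ$truth
  invisible(paths)
}
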