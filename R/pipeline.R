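.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the assessment pipeline end-to-end
#'
#' Orchestrates the whole workflow into a run directory: read (or generate)
#' inputs, compute Criterion B range metrics and categories, Criterion A
#' land-cover categories, combine the criteria, score EDGE on the
#' phylogeny, build the 5-km grid surfaces, extract L1 hotspots per metric,
#' measure protected-area overlap, and validate against a reference table.
#' Stages communicate only through serialized files in the run directory,
#' so any stage's output can be re-read and examined in isolation, and a
#' run is a pure function of (inputs, configuration, seed). A
#' `manifest.json` records the configuration, package version and MD5
#' checksums of every output.
#'
#' Missing optional inputs degrade gracefully: without a tree the EDGE
#' stage (and EDGE hotspots) is skipped with a warning; without land cover
#' every taxon is DD under Criterion A; without protected areas or a
#' reference table the overlap or validation stage is skipped.
#'
#' @param out_dir run directory (created; reused if it exists).
#' @param scenario optional [synthetic_scenario()]; its inputs are written
#'   under `out_dir/inputs` and then read back like any external data.
#' @param inputs named list of file paths (`occurrences`, and optionally
#'   `landcover`, `tree`, `pas`, `reference`); ignored when a scenario is
#'   given.
#' @param proj a [projection_spec()]; default: the scenario projection, or
#'   an equal-area projection centred on the occurrence centroid.
#' @param thresholds_a,thresholds_b threshold tables
#'   (see [criterion_a_thresholds()], [criterion_b_thresholds()]).
#' @param hotspot_quantile top fraction for L1 hotspots (default 0.01).
#' @param hotspot_eligible `"occupied"` (default) or `"all"` (see
#'   [l1_hotspots()]).
#' @param criterion_a_unit `"cell"` or `"occurrence"`
#'   (see [criterion_a_batch()]).
#' @param pa_mode `"intersect"` or `"centroid"` (see [pa_overlap()]).
#' @return invisibly, a list with the in-memory results (`assessments`,
#'   `edge_scores`, `surface`, `hotspots`, `pa_overlap`, `validation`,
#'   `manifest`, `files`).
#' @export
run_pipeline <- function(out_dir, scenario = NULL, inputs = NULL,
                         proj = NULL,
                         thresholds_a = criterion_a_thresholds(),
                         thresholds_b = criterion_b_thresholds(),
                         hotspot_quantile = 0.01,
                         hotspot_eligible = c("occupied", "all"),
                         criterion_a_unit = c("cell", "occurrence"),
                         pa_mode = c("intersect", "centroid")) {
  hotspot_eligible <- match.arg(hotspot_eligible)
  criterion_a_unit <- match.arg(criterion_a_unit)
  pa_mode <- match.arg(pa_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(scenario)) {
    inputs <- .stage("simulate",
                     generate_inputs(scenario, file.path(out_dir, "inputs")))
    if (is.null(proj)) proj <- scenario_projection(scenario)
  }
  if (is.null(inputs$occurrences))
    stop("either a scenario or an 'occurrences' input path is required")

  occ <- .stage("read_occurrences", read_occurrences(inputs$occurrences))
  pts <- .stage("project", project_points(occ, proj))
  proj <- attr(pts, "proj")

  assess_b <- .stage("criterion_b",
                     assess_criterion_b(range_metrics(pts, proj),
                                        thresholds_b))

  if (!is.null(inputs$landcover)) {
    lc <- .stage("read_landcover", read_landcover(inputs$landcover))
    assess_a <- .stage("criterion_a",
                       criterion_a_batch(pts, proj, lc, thresholds_a,
                                         unit = criterion_a_unit))
  } else {
    warning("no land-cover input; Criterion A set to DD for all taxa")
    assess_a <- data.frame(taxon = names(pts), n_cells = NA_integer_,
                           n_threatened = NA_integer_,
                           n_unknown = NA_integer_,
                           reduction_pct = NA_real_, category_A = "DD",
                           stringsAsFactors = FALSE)
  }

  combined <- .stage("combine", combine_assessments(assess_a, assess_b))
  full <- merge(merge(assess_b, assess_a[c("taxon", "n_threatened",
                                           "reduction_pct", "category_A")],
                      by = "taxon"),
                combined[c("taxon", "category_combined", "threatened")],
                by = "taxon")
  files <- list(assessments = file.path(out_dir, "assessments.csv"))
  write_assessments(full, files$assessments)

  es <- NULL
  if (!is.null(inputs$tree)) {
    tree <- .stage("read_tree", read_tree(inputs$tree))
    es <- .stage("edge", edge_scores(tree, combined))
    files$edge_scores <- file.path(out_dir, "edge_scores.csv")
    utils::write.csv(es, files$edge_scores, row.names = FALSE)
  } else {
    warning("no tree input; EDGE stage skipped")
  }

  cellmap <- .stage("grid", rasterize_taxa(pts, proj))
  surface <- .stage("surfaces", build_surfaces(cellmap, combined, es))
  files$surfaces <- file.path(out_dir, "surfaces.csv")
  write_surface(surface, files$surfaces)

  metrics <- c("GR", "CR_END", if (!is.null(es)) "EDGE")
  hotspots <- lapply(stats::setNames(metrics, metrics), function(m)
    .stage(paste0("hotspots_", m),
           l1_hotspots(surface, m, quantile = hotspot_quantile,
                       eligible = hotspot_eligible,
                       n_cells_total = attr(surface, "n_cells_total"))))
  for (m in metrics) {
    files[[paste0("hotspots_", m)]] <-
      file.path(out_dir, paste0("hotspots_", m, ".geojson"))
    write_hotspots_geojson(hotspots[[m]], proj, files[[paste0("hotspots_", m)]])
  }

  overlap <- NULL
  if (!is.null(inputs$pas)) {
    pas_ll <- .stage("read_pas", read_geojson_polygons(inputs$pas))
    pas <- lapply(pas_ll, function(p) project_xy(p[, 1], p[, 2], proj))
    overlap <- lapply(hotspots, function(hs)
      .stage("pa_overlap", pa_overlap(hs, pas, proj, mode = pa_mode)))
    files$pa_overlap <- file.path(out_dir, "pa_overlap.json")
    jsonlite::write_json(
      lapply(overlap, function(o)
        o[c("n_hotspots", "n_inside", "n_outside",
            "pct_inside", "pct_outside", "mode")]),
      files$pa_overlap, auto_unbox = TRUE, digits = 8)
  }

  validation <- NULL
  if (!is.null(inputs$reference)) {
    reference <- utils::read.csv(inputs$reference, stringsAsFactors = FALSE)
    validation <- .stage("validate",
                         validate_assessments(combined, reference))
    files$validation <- file.path(out_dir, "validation.json")
    jsonlite::write_json(validation, files$validation, auto_unbox = TRUE,
                         digits = 8)
  }

  manifest <- list(
    package = "endemicrisk",
    version = tryCatch(as.character(utils::packageVersion("endemicrisk")),
                       error = function(e) NA_character_),
    scenario = if (!is.null(scenario)) unclass(scenario),
    inputs = lapply(inputs, function(p) basename(as.character(p))),
    projection = unclass(proj),
    thresholds_a = thresholds_a, thresholds_b = thresholds_b,
    hotspot_quantile = hotspot_quantile,
    hotspot_eligible = hotspot_eligible,
    criterion_a_unit = criterion_a_unit, pa_mode = pa_mode,
    checksums = lapply(files, function(f) unname(tools::md5sum(f))))
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(assessments = full, combined = combined,
                 edge_scores = es, surface = surface, hotspots = hotspots,
                 pa_overlap = overlap, validation = validation,
                 manifest = manifest, files = files, proj = proj))
}
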