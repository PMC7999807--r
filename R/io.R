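#' Read occurrence records from delimited text
#'
#' Reads a CSV/TSV table of georeferenced records, maps the configured
#' columns, validates coordinates (longitude in \[-180, 180\], latitude in
#' \[-90, 90\], non-empty taxon id) and drops invalid rows. The reader does
#' not deduplicate: duplicate records are legitimate input and are collapsed
#' downstream by [project_points()].
#'
#' @param path file path.
#' @param taxon_col,lon_col,lat_col column names in the file.
#' @param sep field separator (default `","`).
#' @return a data frame with columns `taxon`, `lon`, `lat` and attribute
#'   `"rejected"` (number of dropped rows). Zero valid rows is an error.
#' @export
read_occurrences <- function(path, taxon_col = "taxon", lon_col = "lon",
                             lat_col = "lat", sep = ",") {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  occ <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  missing_cols <- setdiff(c(taxon_col, lon_col, lat_col), names(occ))
  if (length(missing_cols) > 0)
    stop("occurrence file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(taxon = as.character(occ[[taxon_col]]),
                    lon = suppressWarnings(as.numeric(occ[[lon_col]])),
                    lat = suppressWarnings(as.numeric(occ[[lat_col]])),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$lon) & !is.na(out$lat) &
    out$lon >= -180 & out$lon <= 180 & out$lat >= -90 & out$lat <= 90 &
    !is.na(out$taxon) & nzchar(out$taxon)
  rejected <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no valid occurrence records in ", path,
         " (", rejected, " rejected)")
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write occurrence records
#' @param occurrences data frame with `taxon`, `lon`, `lat`.
#' @param path file path.
#' @rdname read_occurrences
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(occurrences[c("taxon", "lon", "lat")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and validate a time-calibrated phylogeny
#'
#' Newick parsing is delegated to [ape::read.tree()]; this wrapper enforces
#' the contract the EDGE stage relies on: a rooted tree, branch lengths
#' present and non-negative, unique tip labels.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("malformed Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree an [ape::phylo] object.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Read and write simple polygon sets as GeoJSON
#'
#' Minimal GeoJSON support for the polygon interfaces (protected areas in,
#' hotspot cells out): a FeatureCollection of single-ring Polygon features.
#' Coordinates are written as given; protected-area files are expected in
#' WGS84 degrees and projected by the caller.
#'
#' @param path file path.
#' @param polygons a list of two-column coordinate matrices (rings, not
#'   closed), optionally named.
#' @param properties optional data frame of per-feature properties.
#' @return `read_geojson_polygons()` returns a named list of open-ring
#'   coordinate matrices with attribute `"properties"`.
#' @export
read_geojson_polygons <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection in ", path)
  polys <- list(); props <- list()
  for (f in gj$features) {
    geom <- f$geometry
    if (is.null(geom) || geom$type != "Polygon")
      stop("only Polygon features are supported (found ",
           if (is.null(geom)) "null" else geom$type, ")")
    ring <- do.call(rbind, lapply(geom$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex GeoJSON requires
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    polys[[length(polys) + 1]] <- ring
    props[[length(polys)]] <- if (is.null(f$properties)) list()
                              else f$properties
  }
  nm <- vapply(props, function(p) {
    if (!is.null(p$name)) as.character(p$name) else NA_character_
  }, character(1))
  if (!anyNA(nm)) names(polys) <- nm
  attr(polys, "properties") <- props
  polys
}

#' @rdname read_geojson_polygons
#' @export
write_geojson_polygons <- function(polygons, path, properties = NULL) {
  features <- lapply(seq_along(polygons), function(k) {
    ring <- polygons[[k]]
    ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
    coords <- lapply(seq_len(nrow(ring)),
                     function(i) c(ring[i, 1], ring[i, 2]))
    prop <- if (!is.null(properties)) as.list(properties[k, , drop = FALSE])
            else if (!is.null(names(polygons)))
              list(name = names(polygons)[k])
            else stats::setNames(list(), character(0))
    list(type = "Feature", properties = prop,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  invisible(path)
}

#' Read and write per-taxon assessment tables
#'
#' CSV with one row per taxon: `taxon`, `category_A`, `category_B`,
#' `category_combined`, `threatened` (see [combine_assessments()]).
#'
#' @param assessments a combined-assessment data frame.
#' @param path file path.
#' @export
write_assessments <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assessments
#' @export
read_assessments <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write grid surfaces
#'
#' CSV with one row per occupied map cell: indices `i`, `j`, lower-left
#' corner `x_min`, `y_min` (metres), richness counts and mean EDGE
#' (see [build_surfaces()]).
#'
#' @param surface a grid-surface data frame.
#' @param path file path.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(surface, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
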