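# Authalic Earth radius (m): the sphere with the same surface area as the
# WGS84 ellipsoid. Using it in a spherical azimuthal equal-area projection
# keeps projected areas within a small fraction of a percent of ellipsoidal
# areas at national extents.
.R_AUTHALIC <- 6371007.1810

#' Analysis projection and grid specification
#'
#' All range geometry (EOO, AOO, locations, mapping grids) is computed on a
#' Lambert azimuthal equal-area projection so that areas come out in km2.
#' The occurrence data name no CRS, so the projection centre is configurable
#' and defaults to the occurrence centroid (see [project_points()]). Grid
#' cells are half-open intervals `[x0 + i*s, x0 + (i+1)*s)` so that cell
#' membership is unambiguous.
#'
#' @param lon0,lat0 projection centre, degrees WGS84.
#' @param x0,y0 grid origin in projected metres (default the projection
#'   origin).
#' @param aoo_cell_m AOO grid cell size in metres (IUCN standard 2000 m).
#' @param location_cell_m grid cell size used to count locations (10000 m).
#' @param map_cell_m mapping grid cell size (5000 m, the 5 x 5 km grid).
#' @return an object of class `projection_spec`.
#' @seealso [project_xy()], [grid_cells()]
#' @examples
#' proj <- projection_spec(24, 38.5)
#' project_xy(24, 38.5, proj)  # projection centre maps to (0, 0)
#' @export
projection_spec <- function(lon0, lat0, x0 = 0, y0 = 0,
                            aoo_cell_m = 2000, location_cell_m = 10000,
                            map_cell_m = 5000) {
  stopifnot(is.numeric(lon0), is.numeric(lat0), length(lon0) == 1,
            length(lat0) == 1, lon0 >= -180, lon0 <= 180,
            lat0 >= -90, lat0 <= 90,
            aoo_cell_m > 0, location_cell_m > 0, map_cell_m > 0)
  structure(list(lon0 = lon0, lat0 = lat0, x0 = x0, y0 = y0,
                 aoo_cell_m = aoo_cell_m, location_cell_m = location_cell_m,
                 map_cell_m = map_cell_m),
            class = "projection_spec")
}

#' @export
print.projection_spec <- function(x, ...) {
  cat("Lambert azimuthal equal-area projection\n",
      "  centre: ", x$lon0, "E ", x$lat0, "N;  grid origin: (",
      x$x0, ", ", x$y0, ") m\n",
      "  cells: AOO ", x$aoo_cell_m / 1000, " km, locations ",
      x$location_cell_m / 1000, " km, map ", x$map_cell_m / 1000, " km\n",
      sep = "")
  invisible(x)
}

#' Forward and inverse equal-area projection
#'
#' Spherical Lambert azimuthal equal-area formulas on the authalic sphere.
#' `project_xy()` maps WGS84 degrees to projected metres; `unproject_xy()`
#' inverts it.
#'
#' @param lon,lat coordinates in degrees.
#' @param x,y projected coordinates in metres.
#' @param proj a [projection_spec()].
#' @return a two-column matrix (`x`,`y` in metres, or `lon`,`lat` in degrees).
#' @export
project_xy <- function(lon, lat, proj) {
  stopifnot(inherits(proj, "projection_spec"))
  lam <- (lon - proj$lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- proj$lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  # antipode of the projection centre is the only singular point
  denom[denom < 1e-12] <- 1e-12
  k <- sqrt(2 / denom)
  x <- .R_AUTHALIC * k * cos(phi) * sin(lam)
  y <- .R_AUTHALIC * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  cbind(x = x, y = y)
}

#' @rdname project_xy
#' @export
unproject_xy <- function(x, y, proj) {
  stopifnot(inherits(proj, "projection_spec"))
  phi0 <- proj$lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * .R_AUTHALIC)))
  lat <- ifelse(rho < 1e-9, proj$lat0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho) *
                  180 / pi)
  lon <- ifelse(rho < 1e-9, proj$lon0,
                proj$lon0 + atan2(x * sin(cc),
                                  rho * cos(phi0) * cos(cc) -
                                    y * sin(phi0) * sin(cc)) * 180 / pi)
  cbind(lon = lon, lat = lat)
}

#' Project occurrence records to per-taxon point sets
#'
#' Projects occurrence records onto the analysis projection and removes
#' exact duplicate points per taxon. EOO and AOO are defined on occupied
#' space, not record counts, so exact duplicates carry no information;
#' near-duplicates are kept.
#'
#' @param occurrences a data frame with columns `taxon`, `lon`, `lat`
#'   (as returned by [read_occurrences()]).
#' @param proj a [projection_spec()], or `NULL` to centre the default
#'   equal-area projection on the centroid of all occurrences.
#' @return a named list with one two-column matrix (`x`, `y` in metres) of
#'   unique projected points per taxon, with the projection used attached as
#'   attribute `"proj"`.
#' @export
project_points <- function(occurrences, proj = NULL) {
  stopifnot(is.data.frame(occurrences),
            all(c("taxon", "lon", "lat") %in% names(occurrences)))
  if (nrow(occurrences) == 0) stop("no occurrence records to project")
  if (is.null(proj))
    proj <- projection_spec(mean(occurrences$lon), mean(occurrences$lat))
  xy <- project_xy(occurrences$lon, occurrences$lat, proj)
  pts <- lapply(split(seq_len(nrow(occurrences)), occurrences$taxon),
                function(i) unique(xy[i, , drop = FALSE]))
  attr(pts, "proj") <- proj
  pts
}

#' Assign projected points to half-open grid cells
#'
#' @param points a two-column matrix of projected coordinates in metres.
#' @param proj a [projection_spec()] supplying the grid origin.
#' @param cell_m cell size in metres.
#' @param unique_cells drop duplicate cells (default `TRUE`).
#' @return an integer matrix with columns `i`, `j` (cell indices such that
#'   the cell spans `[x0 + i*s, x0 + (i+1)*s)`).
#' @export
grid_cells <- function(points, proj, cell_m, unique_cells = TRUE) {
  stopifnot(inherits(proj, "projection_spec"), cell_m > 0)
  ij <- cbind(i = as.integer(floor((points[, 1] - proj$x0) / cell_m)),
              j = as.integer(floor((points[, 2] - proj$y0) / cell_m)))
  if (unique_cells) ij <- unique(ij)
  ij
}
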