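proj <- test_proj()

make_surface <- function(n, metric_values = NULL) {
  # a synthetic occupied-cell surface with controllable mean_edge values
  data.frame(i = seq_len(n), j = 0L, x_min = seq_len(n) * 5000, y_min = 0,
             n_endemic = pmax(1L, seq_len(n) %% 7L),
             n_threatened = 0L, n_cr = 0L,
             mean_edge = if (is.null(metric_values)) runif(n)
                         else metric_values)
}

test_that("rasterize_taxa records presence per 5-km cell", {
  occ <- data.frame(taxon = rep(c("a", "b"), c(5, 2)),
                    lon = 24 + c(0.001, 0.002, 0.003, 0.004, 0.005,
                                 0.001, 0.3),
                    lat = 38.5 + c(rep(0.001, 5), 0.002, 0.002))
  pts <- project_points(occ, proj)
  cm <- rasterize_taxa(pts, proj)
  # a's 5 points share one cell with one of b's points
  shared <- which(vapply(cm$taxa, function(t) "a" %in% t, logical(1)))
  expect_length(shared, 1)
  expect_setequal(cm$taxa[[shared]], c("a", "b"))
  expect_equal(sum(vapply(cm$taxa, length, integer(1))), 3)
})

test_that("per-cell membership matches a nested-loop oracle", {
  set.seed(31)
  occ <- data.frame(taxon = sample(sprintf("t%02d", 1:12), 150, TRUE),
                    lon = runif(150, 23.8, 24.3),
                    lat = runif(150, 38.3, 38.7))
  pts <- project_points(occ, proj)
  cm <- rasterize_taxa(pts, proj)
  s <- proj$map_cell_m
  for (k in seq_len(nrow(cm$cells))) {
    members <- character(0)
    for (tx in names(pts)) {
      p <- pts[[tx]]
      inside <- p[, 1] >= cm$cells$x_min[k] &
        p[, 1] < cm$cells$x_min[k] + s &
        p[, 2] >= cm$cells$y_min[k] & p[, 2] < cm$cells$y_min[k] + s
      if (any(inside)) members <- c(members, tx)
    }
    expect_setequal(cm$taxa[[k]], members)
  }
})

test_that("surfaces count categories and average EDGE per cell", {
  cm <- list(cells = data.frame(i = 0L, j = 0L, x_min = 0, y_min = 0),
             taxa = list(c("a", "b", "c")))
  assess <- data.frame(taxon = c("a", "b", "c"),
                       category_combined = c("CR", "VU", "LC"))
  es <- data.frame(taxon = c("a", "b"), edge = c(2, 4))
  surf <- build_surfaces(cm, assess, es)
  expect_equal(surf$n_endemic, 3L)
  expect_equal(surf$n_threatened, 2L)
  expect_equal(surf$n_cr, 1L)
  expect_equal(surf$mean_edge, 3)
})

test_that("surface invariants hold on a generated scenario and are
           order-invariant", {
  sc <- synthetic_scenario(n_taxa = 40, seed = 5)
  occ <- generate_occurrences(sc)
  pts <- project_points(occ$occurrences, scenario_projection(sc))
  assess <- data.frame(taxon = occ$truth$taxon,
                       category_combined = occ$truth$category_design)
  surf <- build_surfaces(rasterize_taxa(pts), assess)
  expect_true(all(surf$n_cr <= surf$n_threatened))
  expect_true(all(surf$n_threatened <= surf$n_endemic))
  expect_true(all(surf$n_endemic >= 1))
  # reversing record order changes nothing
  occ_rev <- occ$occurrences[rev(seq_len(nrow(occ$occurrences))), ]
  pts2 <- project_points(occ_rev, scenario_projection(sc))
  surf2 <- build_surfaces(rasterize_taxa(pts2), assess)
  expect_equal(surf2, surf)
})

test_that("L1 hotspots slice the top 1% with inclusive ties", {
  set.seed(41)
  # 200 distinct values -> exactly 2 cells
  surf <- make_surface(200, metric_values = sample(seq(1, 200)))
  hs <- l1_hotspots(surf, "EDGE")
  expect_equal(nrow(hs$cells), 2)
  expect_setequal(hs$cells$mean_edge, c(199, 200))
  # 100 cells, top value shared by 3 -> all 3 selected
  vals <- c(rep(9, 3), runif(97, 0, 5))
  surf2 <- make_surface(100, metric_values = vals)
  hs2 <- l1_hotspots(surf2, "EDGE")
  expect_equal(nrow(hs2$cells), 3)
  expect_true(all(hs2$cells$mean_edge == 9))
})

test_that("hotspot members equal the sort-and-slice oracle", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    vals <- round(runif(n, 0, 10), sample(0:2, 1))  # force some ties
    surf <- make_surface(n, metric_values = vals)
    hs <- l1_hotspots(surf, "EDGE")
    expect_setequal(hs$cells$i, surf$i[oracle_top_quantile(vals, 0.01)])
    expect_gte(nrow(hs$cells), ceiling(0.01 * n))
  }
})

test_that("an all-equal surface degenerates with a warning", {
  surf <- make_surface(50, metric_values = rep(2, 50))
  expect_warning(hs <- l1_hotspots(surf, "EDGE"), "every cell")
  expect_equal(nrow(hs$cells), 50)
})

test_that("quantile over all cells counts unoccupied cells as zeros", {
  surf <- make_surface(100, metric_values = seq(0.01, 1, 0.01))
  hs <- l1_hotspots(surf, "EDGE", eligible = "all", n_cells_total = 1000)
  expect_equal(hs$n_eligible, 1000)
  expect_equal(nrow(hs$cells), 10)  # ceil(0.01 * 1000)
})

test_that("cells with NA metric are ineligible for EDGE hotspots", {
  surf <- make_surface(100, metric_values = c(rep(NA, 50), 1:50))
  hs <- l1_hotspots(surf, "EDGE")
  expect_equal(hs$n_eligible, 50)
  expect_equal(nrow(hs$cells), 1)
  expect_equal(hs$cells$mean_edge, 50)
})

test_that("PA overlap flags cells by geometric intersection", {
  surf <- make_surface(3, metric_values = c(3, 2, 1))
  hs <- l1_hotspots(surf, "EDGE")        # top cell: x_min 5000
  pa_containing <- list(cbind(c(4000, 11000, 11000, 4000),
                              c(-1000, -1000, 6000, 6000)))
  ov <- pa_overlap(hs, pa_containing, proj)
  expect_equal(ov$n_inside, 1)
  expect_equal(ov$pct_outside, 0)
  # a PA that only clips the cell corner still counts as intersecting,
  # but misses the centroid
  pa_corner <- list(cbind(c(9500, 10500, 10500, 9500),
                          c(4500, 4500, 5500, 5500)))
  expect_equal(pa_overlap(hs, pa_corner, proj)$n_inside, 1)
  expect_equal(pa_overlap(hs, pa_corner, proj, mode = "centroid")$n_inside, 0)
})

test_that("percentages inside and outside sum to 100", {
  set.seed(44)
  surf <- make_surface(40, metric_values = runif(40))
  hs <- l1_hotspots(surf, "EDGE")
  hs$cells <- surf  # treat every cell as a hotspot for the arithmetic
  pas <- list(cbind(c(0, 60000, 60000, 0), c(-1000, -1000, 2000, 2000)))
  ov <- pa_overlap(hs, pas, proj)
  expect_equal(ov$pct_inside + ov$pct_outside, 100)
  expect_equal(ov$n_inside + ov$n_outside, ov$n_hotspots)
})

test_that("a 40-cell hotspot set with 11 misses is 27.5% outside", {
  surf <- make_surface(40, metric_values = 1:40)
  hs <- l1_hotspots(surf, "EDGE")
  hs$cells <- surf
  # protect cells 1..29 (x_min 5000..145000); leave 11 outside
  pas <- list(cbind(c(5000, 149000, 149000, 5000),
                    c(0, 0, 5000, 5000)))
  ov <- pa_overlap(hs, pas, proj)
  expect_equal(ov$n_outside, 11)
  expect_equal(ov$pct_outside, 27.5)
})

test_that("empty PA set means 100% outside, with a warning", {
  surf <- make_surface(10, metric_values = 1:10)
  hs <- l1_hotspots(surf, "EDGE")
  expect_warning(ov <- pa_overlap(hs, list(), proj), "empty")
  expect_equal(ov$pct_outside, 100)
})

test_that("intersection flags match an exact interval-overlap oracle on
           random rectangles", {
  set.seed(45)
  s <- proj$map_cell_m
  for (rep in 1:20) {
    surf <- make_surface(30, metric_values = runif(30))
    hs <- l1_hotspots(surf, "EDGE")
    hs$cells <- surf
    rects <- lapply(1:5, function(k) {
      x <- runif(1, 0, 150000); y <- runif(1, -10000, 10000)
      w <- runif(1, 1000, 30000); h <- runif(1, 1000, 30000)
      cbind(c(x, x + w, x + w, x), c(y, y, y + h, y + h))
    })
    ov <- pa_overlap(hs, rects, proj)
    for (k in seq_len(nrow(surf))) {
      expected <- any(vapply(rects, function(r) {
        surf$x_min[k] <= max(r[, 1]) && surf$x_min[k] + s >= min(r[, 1]) &&
          surf$y_min[k] <= max(r[, 2]) && surf$y_min[k] + s >= min(r[, 2])
      }, logical(1)))
      expect_equal(ov$cells$inside_pa[k], expected)
    }
  }
})

test_that("hotspot cells export to GeoJSON squares", {
  surf <- make_surface(5, metric_values = 1:5)
  hs <- l1_hotspots(surf, "EDGE")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_hotspots_geojson(hs, proj, f)
  back <- read_geojson_polygons(f)
  expect_length(back, nrow(hs$cells))
  expect_equal(nrow(back[[1]]), 4)
})
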