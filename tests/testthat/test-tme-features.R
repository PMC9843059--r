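tumor_cells_in_tile <- function(k, offset_x = 0, offset_y = 0) {
  if (k == 0) return(NULL)
  data.frame(x = offset_x + seq(10, 490, length.out = k),
             y = offset_y + rep(250, k), cell_type = "tumor",
             stringsAsFactors = FALSE)
}

test_that("tumor-tile selection flips exactly at the 10-cell threshold", {
  for (k in 0:20) {
    cells <- tumor_cells_in_tile(k)
    m <- if (is.null(cells)) make_map(random_patch(0, 1), 500, 500) else
      make_map(cells, 500, 500)
    roi <- detect_tumor_tiles(m)
    expect_identical(nrow(roi$selected), as.integer(k >= 10), info = k)
  }
})

test_that("tile grid partitions the slide and counts per tile", {
  # 2x2 grid with tumor counts 12, 3, 0, 10 -> tiles 1 and 4 selected
  cells <- rbind(tumor_cells_in_tile(12, 0, 0),
                 tumor_cells_in_tile(3, 500, 0),
                 tumor_cells_in_tile(10, 500, 500))
  m <- make_map(cells, 1000, 1000)
  roi <- detect_tumor_tiles(m)
  expect_equal(roi$selected[, c("tile_row", "tile_col")],
               data.frame(tile_row = c(1L, 2L), tile_col = c(1L, 2L)),
               ignore_attr = TRUE)
  # non-tumor cells never count toward selection
  cells$cell_type <- "stroma"
  expect_identical(nrow(detect_tumor_tiles(make_map(cells, 1000, 1000))$selected),
                   0L)
  # empty map -> empty ROI
  expect_identical(nrow(detect_tumor_tiles(make_map(random_patch(0, 1)))$selected),
                   0L)
})

test_that("tumor/stroma ratio counts cells within selected tiles only", {
  inroi <- rbind(tumor_cells_in_tile(50),
                 data.frame(x = seq(10, 490, length.out = 25), y = 100,
                            cell_type = "stroma"))
  # stroma outside the tumor ROI must not contribute
  outside <- data.frame(x = 600 + seq_len(40), y = 600, cell_type = "stroma")
  m <- make_map(rbind(inroi, outside), 1000, 1000)
  roi <- detect_tumor_tiles(m)
  tsr <- compute_tsr(m, roi)
  expect_equal(as.numeric(tsr), 2.0)
  expect_identical(attr(tsr, "n_stroma"), 25L)
  # no stroma in ROI -> undefined, not an error
  m2 <- make_map(tumor_cells_in_tile(50), 500, 500)
  expect_true(is.na(compute_tsr(m2, detect_tumor_tiles(m2))))
  # empty ROI -> undefined
  m3 <- make_map(random_patch(0, 1))
  expect_true(is.na(compute_tsr(m3, detect_tumor_tiles(m3))))
  # randomized map: ratio matches a direct tally over tile membership
  for (rep in 1:5) {
    mm <- simulate_cell_map(seed = 900 + rep, width_px = 2500,
                            height_px = 2500)
    rr <- detect_tumor_tiles(mm)
    got <- compute_tsr(mm, rr)
    tile_of <- function(v) floor(v / 500) + 1
    sel <- sprintf("%d_%d", rr$selected$tile_row, rr$selected$tile_col)
    ins <- sprintf("%d_%d", tile_of(mm$cells$y), tile_of(mm$cells$x)) %in% sel
    expect_equal(as.numeric(got),
                 sum(ins & mm$cells$cell_type == "tumor") /
                   sum(ins & mm$cells$cell_type == "stroma"))
  }
})

test_that("patch sampling caps, clamps and is deterministic", {
  m <- simulate_cell_map(seed = 5, width_px = 8000, height_px = 8000,
                         n_nests = 12, nest_radius_px = 900)
  roi <- detect_tumor_tiles(m)
  expect_gt(nrow(roi$selected), 100)
  ps <- sample_patches(roi, m, seed = 3)
  expect_length(ps, 100)
  centers <- vapply(ps, function(p) paste(p$tile_row, p$tile_col),
                    character(1))
  expect_false(anyDuplicated(centers) > 0)
  for (p in ps) {
    expect_gte(p$x0, 0)
    expect_lte(p$x0 + p$side_px, m$width_px)
    expect_gte(p$y0, 0)
    expect_lte(p$y0 + p$side_px, m$height_px)
  }
  expect_identical(sample_patches(roi, m, seed = 3), ps)
  expect_false(identical(sample_patches(roi, m, seed = 4), ps))
  # fewer candidate tiles than the cap
  m2 <- simulate_cell_map(seed = 6, width_px = 1500, height_px = 1500,
                          n_nests = 1, nest_radius_px = 400)
  roi2 <- detect_tumor_tiles(m2)
  expect_lte(nrow(roi2$selected), 9)
  expect_length(sample_patches(roi2, m2, seed = 1), nrow(roi2$selected))
  # empty ROI warns and returns no patches
  m3 <- make_map(random_patch(0, 1), 2000, 2000)
  expect_warning(ps3 <- sample_patches(detect_tumor_tiles(m3), m3, seed = 1),
                 "empty tumor ROI")
  expect_length(ps3, 0)
})

test_that("Delaunay graphs match counts forced by geometry", {
  tri <- data.frame(x = c(0, 10, 5), y = c(0, 0, 8), cell_type = "tumor")
  g <- build_delaunay(tri)
  expect_false(g$degenerate)
  expect_identical(nrow(g$edges), 3L)
  # convex non-cocircular quadrilateral: 4 hull edges + 1 diagonal
  quad <- data.frame(x = c(0, 10, 11, 1), y = c(0, 0, 9, 7),
                     cell_type = "stroma")
  expect_identical(nrow(build_delaunay(quad)$edges), 5L)
  # degenerate inputs: too few points, collinear points, duplicated points
  expect_true(build_delaunay(tri[1:2, ])$degenerate)
  coll <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
                     cell_type = "tumor")
  g2 <- build_delaunay(coll)
  expect_true(g2$degenerate)
  expect_identical(nrow(g2$edges), 0L)
  dup <- data.frame(x = c(1, 1, 1), y = c(2, 2, 2), cell_type = "tumor")
  expect_true(build_delaunay(dup)$degenerate)
})

test_that("Delaunay edge sets equal the brute-force empty-circumcircle oracle", {
  for (rep in 1:12) {
    n <- withr::with_seed(rep, sample(10:60, 1))
    patch <- random_patch(n, seed = 1000 + rep)
    g <- build_delaunay(patch)
    oracle <- brute_delaunay_edges(patch$x, patch$y)
    expect_equal(g$edges, oracle, info = rep, ignore_attr = TRUE)
  }
})

test_that("interaction fractions follow the connection-counting definition", {
  # all-tumor patch: everything interacts with tumor
  allt <- random_patch(30, seed = 7)
  allt$cell_type <- "tumor"
  it <- patch_interactions(build_delaunay(allt))
  expect_equal(unname(it["interaction_tumor_tumor"]), 1)
  expect_equal(sum(it), 1)
  # one central tumor cell with 2 stroma + 2 lymphocyte neighbors
  star <- data.frame(x = c(5, 5, 5, 0, 10), y = c(5, 0, 10, 5, 5),
                     cell_type = c("tumor", "stroma", "stroma",
                                   "lymphocyte", "lymphocyte"))
  is <- patch_interactions(build_delaunay(star))
  expect_equal(unname(is["interaction_tumor_stroma"]), 0.5)
  expect_equal(unname(is["interaction_tumor_lymphocyte"]), 0.5)
  expect_equal(unname(is["interaction_tumor_tumor"]), 0)
  # no tumor cell at all -> undefined
  nostro <- random_patch(20, seed = 8)
  nostro$cell_type <- "stroma"
  expect_true(all(is.na(patch_interactions(build_delaunay(nostro)))))
  # mixed patches match the independent edge-enumeration oracle
  for (rep in 1:10) {
    patch <- random_patch(30, seed = 2000 + rep)
    g <- build_delaunay(patch)
    expect_equal(patch_interactions(g),
                 oracle_interactions(g$edges, patch$cell_type), info = rep)
  }
})

test_that("interactions conserve mass and are similarity invariant", {
  for (rep in 1:25) {
    n <- withr::with_seed(3000 + rep, sample(8:120, 1))
    patch <- random_patch(n, seed = 3100 + rep)
    it <- patch_interactions(build_delaunay(patch))
    if (all(is.na(it))) next
    expect_equal(sum(it), 1, tolerance = 1e-9)
    expect_true(all(it >= 0 & it <= 1))
    # translate, rotate, scale
    th <- withr::with_seed(3200 + rep, stats::runif(1, 0, 2 * pi))
    s <- withr::with_seed(3300 + rep, stats::runif(1, 0.5, 3))
    p2 <- patch
    p2$x <- s * (cos(th) * patch$x - sin(th) * patch$y) + 50
    p2$y <- s * (sin(th) * patch$x + cos(th) * patch$y) - 20
    expect_equal(patch_interactions(build_delaunay(p2)), it,
                 tolerance = 1e-12, info = rep)
  }
})

test_that("densities are exact per-type tallies", {
  p <- data.frame(x = seq_len(10), y = seq_len(10),
                  cell_type = c(rep("tumor", 7), rep("stroma", 3)))
  expect_equal(unname(patch_densities(p)), c(7, 3, 0, 0, 0, 0))
  expect_equal(unname(patch_densities(random_patch(0, 1))), rep(0, 6))
  for (rep in 1:5) {
    patch <- random_patch(50, seed = 4000 + rep)
    expect_equal(patch_densities(patch),
                 vapply(stats::setNames(cell_types(),
                                        paste0("density_", cell_types())),
                        function(k) sum(patch$cell_type == k), numeric(1)))
  }
})

test_that("slide features equal a straight-line recomputation over the same patches", {
  m <- simulate_cell_map(seed = 31, width_px = 3000, height_px = 3000)
  sf <- slide_features(m, seed = 77)
  roi <- detect_tumor_tiles(m)
  ps <- sample_patches(roi, m, seed = 77)
  dens <- sapply(ps, patch_densities)
  inter <- sapply(ps, function(p) patch_interactions(build_delaunay(p)))
  expect_equal(as.numeric(sf[paste0("density_", cell_types())]),
               unname(rowMeans(dens)))
  ok <- colSums(is.na(inter)) == 0
  expect_equal(as.numeric(sf[paste0("interaction_tumor_", cell_types())]),
               unname(rowMeans(inter[, ok, drop = FALSE])))
  expect_equal(sf$tsr, as.numeric(compute_tsr(m, roi)))
  expect_identical(sf$n_patches_used, length(ps))
  # determinism: same map + seed reproduces the identical feature vector
  expect_identical(slide_features(m, seed = 77), sf)
  # per-100-patch density convention is a pure rescaling
  sf100 <- slide_features(m, seed = 77, density_per_100 = TRUE)
  expect_equal(as.numeric(sf100[paste0("density_", cell_types())]),
               100 * as.numeric(sf[paste0("density_", cell_types())]))
  # slides without tumor tiles are flagged, mirroring cohort exclusions
  m2 <- make_map(data.frame(x = runif(30) * 900, y = runif(30) * 900,
                            cell_type = "stroma"))
  sf2 <- slide_features(m2, seed = 1)
  expect_identical(sf2$flag, "no_tumor")
  expect_true(is.na(sf2$interaction_tumor_tumor))
})

test_that("patient-level features average slide-level vectors", {
  m <- simulate_cell_map(seed = 41, width_px = 2500, height_px = 2500)
  s1 <- slide_features(m, seed = 1)
  expect_equal(patient_features(s1)$interaction_tumor_stroma,
               s1$interaction_tumor_stroma)
  # multiple slides, multiple patients: mean per feature, by patient
  rows <- list()
  for (i in 1:3) {
    mi <- simulate_cell_map(slide_id = paste0("S", i),
                            patient_id = if (i < 3) "PA" else "PB",
                            seed = 50 + i, width_px = 2500, height_px = 2500)
    rows[[i]] <- slide_features(mi, seed = i)
  }
  sl <- do.call(rbind, rows)
  pf <- patient_features(sl)
  expect_identical(pf$patient_id, c("PA", "PB"))
  for (cc in c(feature_names(), "tsr")) {
    expect_equal(pf[[cc]][1], mean(sl[[cc]][1:2]), info = cc)
    expect_equal(pf[[cc]][2], sl[[cc]][3], info = cc)
  }
  # flagged no-tumor slides are excluded; all-flagged input errors
  flagged <- sl[1, ]
  flagged$flag <- "no_tumor"
  expect_error(patient_features(flagged), "no non-flagged")
})
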