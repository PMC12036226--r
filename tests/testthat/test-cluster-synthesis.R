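test_that("candidate mask is empty on constant cells and nested in the intensity mask", {
  cell <- matrix(1000, 100, 100)
  expect_equal(sum(candidate_mask(cell)), 0)

  pair <- test_pair()
  b <- segment_breast(pair$low_energy)
  site <- select_insertion_site(compute_grid_features(pair$low_energy, b))
  cc <- cemsim:::crop_cell(pair$low_energy, site)
  cm <- candidate_mask(cc)
  imask <- cc > mean(cc) + sd(cc)
  expect_true(all(imask[cm]))          # AND monotonicity
  expect_gt(sum(cm), 0)
  # equals the intersection of the two independently computed masks
  v <- frangi_vesselness(cc)
  fm <- v > quantile(v, 0.95)
  expect_identical(cm, fm & imask)
})

test_that("frangi responds to a bright ridge, not to flat background", {
  m <- matrix(100, 80, 80)
  m[40:41, 10:70] <- 600
  v <- frangi_vesselness(m)
  expect_gt(mean(v[40, 20:60]), 10 * mean(v[10:20, 10:70]))
})

test_that("region morphology: disc, single pixel, elongated bar", {
  disc <- disc_mat(c(21, 21), c(11, 11), 5)
  r <- extract_candidates(disc, spacing_mm = 0.1)
  expect_equal(nrow(r), 1)
  expect_gte(r$circularity, 0.85)
  expect_lte(r$circularity, 1.05)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  r1 <- extract_candidates(single, spacing_mm = 0.1)
  expect_equal(r1$equiv_diameter_mm, 2 * 0.1 * sqrt(1 / pi), tolerance = 1e-9)
  expect_equal(r1$area_px, 1L)

  bar <- matrix(FALSE, 5, 14); bar[3, 3:12] <- TRUE
  rb <- extract_candidates(bar, spacing_mm = 0.1)
  expect_lt(rb$circularity, 0.5)
})

test_that("extraction uses 8-connectivity and deterministic ordering", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE    # diagonal: one 8-connected region
  m[6, 6] <- TRUE
  r <- extract_candidates(m)
  expect_equal(nrow(r), 2)
  expect_equal(r$area_px, c(2L, 1L))
  expect_true(all(diff(order(r$bbox_top, r$bbox_left)) > 0))
})

test_that("class criteria filter by closed circularity and size ranges", {
  regions <- tibble::tibble(
    region_id = 1:4,
    area_px = c(round(pi * 3^2), 3, 18, 38),
    perimeter_px = 1, mean_intensity = 1,
    circularity = c(0.9, 0.2, 0.2, 0.2),
    equiv_diameter_mm = c(0.6, 0.2, 0.3, 0.7),
    centroid_row = 1, centroid_col = 1, bbox_top = 1:4, bbox_left = 1,
    pixels = list(1L, 1L, 1L, 1L))
  ben <- filter_candidates(regions, class_criteria("benign"))
  expect_equal(ben$region_id, 1L)      # 0.6 mm disc kept; 0.2 mm removed
  mal <- filter_candidates(regions, class_criteria("malignant"))
  expect_equal(mal$region_id, c(2L, 3L))  # any circularity; 0.7 mm removed
  # idempotent and order-preserving
  expect_identical(filter_candidates(ben, class_criteria("benign")), ben)
})

test_that("cluster growth hits the target without expansion when possible", {
  # candidates packed into one sub-cell around a contrast peak
  cell <- matrix(1000, 100, 100)
  cell[41:50, 41:50] <- 4000
  mask <- matrix(FALSE, 100, 100)
  ctr <- expand.grid(r = c(42, 45, 48), c = c(42, 45, 48))
  for (i in seq_len(nrow(ctr))) mask[ctr$r[i], ctr$c[i]] <- TRUE
  regions <- extract_candidates(mask, 0.1, cell)
  crit <- class_criteria("benign", size_mm = c(0.05, 1.2), count = c(5L, 9L))
  cl <- grow_cluster(cell, regions, crit, subcell_px = 10, seed = 3)
  expect_s3_class(cl, "cluster_model")
  expect_gte(cl$count, 5)
  expect_lte(cl$count, 9)
  expect_true(all(mask[cl$raster == 1L]))
  # deterministic under the same seed
  cl2 <- grow_cluster(cell, regions, crit, subcell_px = 10, seed = 3)
  expect_identical(cl$raster, cl2$raster)
  expect_identical(cl$target, cl2$target)
})

test_that("insufficient candidates make the view infeasible", {
  cell <- matrix(1000, 100, 100)
  empty <- extract_candidates(matrix(FALSE, 100, 100))
  expect_error(grow_cluster(cell, empty, class_criteria("benign"),
                            subcell_px = 10, seed = 1),
               class = "cemsim_infeasible_cluster")
})

test_that("grown clusters stay inside the cell and within count ranges", {
  sims <- Filter(Negate(is.null), acceptance_sims()[1:20])
  expect_gt(length(sims), 0)
  for (res in sims) {
    cl <- res$cluster
    rng <- class_criteria(cl$class)$count
    expect_gte(cl$count, rng[1])
    expect_lte(cl$count, rng[2])
    expect_true(all(cl$raster %in% c(0L, 1L)))
    expect_equal(sum(cl$raster), sum(lengths(cl$regions$pixels)))
  }
})
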