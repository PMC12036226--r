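make_cluster <- function(seed = 5) {
  cell <- matrix(1000, 60, 60)
  mask <- matrix(FALSE, 60, 60)
  mask[disc_mat(c(60, 60), c(20, 20), 3)] <- TRUE
  mask[disc_mat(c(60, 60), c(35, 40), 2)] <- TRUE
  mask[45, 12] <- TRUE
  regions <- extract_candidates(mask, 0.1, cell)
  crit <- class_criteria("malignant", count = c(1L, 3L))
  grow_cluster(cell, regions, crit, subcell_px = 10, seed = seed)
}

test_that("template contract: background exactly 1, calcifications above 1", {
  cl <- make_cluster()
  tpl <- build_template(cl, amplitude = 0.15)
  sup <- cl$raster == 1L
  expect_true(all(tpl$factors[!sup] == 1))
  expect_true(all(tpl$factors[sup] > 1))
  expect_true(all(is.finite(tpl$factors)))
  expect_lte(max(tpl$factors), 1.15 + 1e-12)
  cl0 <- cl; cl0$raster[] <- 0L
  expect_error(build_template(cl0), "empty")
})

test_that("degradation conserves blurred excess and scales by scatter", {
  cl <- make_cluster()
  tpl <- build_template(cl, amplitude = 0.2)
  # identity degradation
  d0 <- degrade_template(tpl, psf_sigma_px = 0, scatter_fraction = 0)
  expect_identical(d0$factors, tpl$factors)
  # normalized-kernel conservation (before scatter scaling)
  d1 <- degrade_template(tpl, psf_sigma_px = 1.5, scatter_fraction = 0)
  expect_equal(sum(d1$factors - 1), sum(tpl$factors - 1), tolerance = 1e-6)
  # pure scatter scales the peak linearly
  d2 <- degrade_template(tpl, psf_sigma_px = 0, scatter_fraction = 0.3)
  expect_equal(max(d2$factors - 1), 0.7 * max(tpl$factors - 1),
               tolerance = 1e-12)
  # support grows by the blur footprint
  expect_gt(sum(template_support(d1)), sum(template_support(tpl)))
})

test_that("insertion multiplies, preserves non-support pixels, and inverts", {
  img <- gray_image(matrix(as.numeric(sample(500:2000, 3600, TRUE)), 60, 60))
  cl <- make_cluster()
  tpl <- degrade_template(build_template(cl, amplitude = 0.15))
  out <- insert_template(img, tpl)
  sup <- template_support(tpl)
  expect_identical(out$pixels[!sup], img$pixels[!sup])
  expect_true(all(out$pixels >= img$pixels))
  # exact arithmetic and round-trip
  ones <- tpl; ones$factors[] <- 1
  expect_identical(insert_template(img, ones)$pixels, img$pixels)
  one05 <- tpl; one05$factors[] <- 1; one05$factors[10, 10] <- 1.05
  expect_equal(insert_template(gray_image(matrix(1000, 60, 60)),
                               one05)$pixels[10, 10], 1050)
  back <- out$pixels / tpl$factors
  expect_equal(back, img$pixels, tolerance = 1e-12)
  bad <- tpl; bad$factors <- bad$factors[1:30, 1:30]
  expect_error(insert_template(img, bad), "shape")
})

test_that("expand_contour grows outward and contains the input polygon", {
  tri <- cbind(c(10, 30, 20), c(10, 12, 28))
  expect_identical(expand_contour(tri, iterations = 0), tri)
  out1 <- expand_contour(tri, iterations = 1, offset_px = 2)
  expect_equal(nrow(out1), 6)
  shoe <- function(p) abs(cemsim:::shoelace_area(p))
  expect_gt(shoe(out1), shoe(tri))
  # area monotone non-decreasing over iterations
  areas <- sapply(0:4, function(k) shoe(expand_contour(tri, k, 2)))
  expect_true(all(diff(areas) >= 0))
  expect_error(expand_contour(tri[1:2, ], 1), "n >= 3")

  # point-in-polygon containment of sampled hull boundary points
  in_poly <- function(pt, poly) {
    n <- nrow(poly); nxt <- c(2:n, 1)
    if (cemsim:::shoelace_area(poly) < 0) poly <- poly[n:1, ]
    all((poly[nxt, 1] - poly[, 1]) * (pt[2] - poly[, 2]) -
          (poly[nxt, 2] - poly[, 2]) * (pt[1] - poly[, 1]) >= -1e-9)
  }
  withr::with_seed(1, {
    for (rep in 1:20) {
      pts <- cbind(runif(8, 5, 40), runif(8, 5, 40))
      hull <- pts[grDevices::chull(pts), , drop = FALSE]
      if (nrow(hull) < 3) next
      out <- expand_contour(hull, iterations = sample(1:3, 1), offset_px = 2)
      n <- nrow(hull); nxt <- c(2:n, 1)
      for (t in seq(0, 1, by = 0.25)) {
        edge_pts <- hull * (1 - t) + hull[nxt, , drop = FALSE] * t
        for (i in seq_len(n)) expect_true(in_poly(edge_pts[i, ], out))
      }
    }
  })
})

test_that("auto-generated lesion masks cover the calcifications with margin", {
  cl <- make_cluster()
  tpl <- degrade_template(build_template(cl, amplitude = 0.15))
  sup <- template_support(tpl)
  mask <- generate_lesion_mask(sup)
  expect_true(all(mask[sup]))
  expect_equal(attr(mask, "provenance"), "auto_generated")
  # strictly exceeds the undilated hull
  undil <- generate_lesion_mask(sup, dilation_px = 0)
  expect_gt(sum(mask), sum(undil))
  # degenerate supports fall back to a disc dilation
  two <- matrix(FALSE, 30, 30); two[10, 10] <- TRUE; two[12, 10] <- TRUE
  fb <- generate_lesion_mask(two)
  expect_true(all(fb[two]))
  expect_gt(sum(fb), 2)
  expect_error(generate_lesion_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("masks cover degraded template support across seeded simulations", {
  sims <- Filter(Negate(is.null), acceptance_sims()[1:20])
  expect_gt(length(sims), 0)
  for (res in sims) {
    frame_raster <- matrix(0L, nrow(res$mask), ncol(res$mask))
    a <- res$cluster$anchor
    frame_raster[(a$top + 1):(a$top + nrow(res$cluster$raster)),
                 (a$left + 1):(a$left + ncol(res$cluster$raster))] <-
      res$cluster$raster
    expect_true(all(res$mask[frame_raster == 1L]))
  }
})
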