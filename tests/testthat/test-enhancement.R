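test_that("ring construction brackets the 2x and 3x pixel-count targets", {
  lesion <- disc_mat(c(120, 120), c(60, 60), 5.6)  # ~100 px disc
  n <- sum(lesion)
  rings <- build_rings(lesion)
  d <- chebyshev_dist(lesion)
  # oracle: first k where the dilated shell crosses each target
  k1 <- min(which(sapply(1:30, function(k) sum(d <= k & !lesion) >= n)))
  inc1 <- sum(d <= k1 & !lesion) - sum(d <= k1 - 1 & !lesion)
  expect_gte(sum(rings$perilesional), n)
  expect_lt(sum(rings$perilesional), n + inc1 + 1)
  expect_gte(sum(rings$background), n)
  # pairwise disjoint
  expect_equal(sum(rings$lesion & rings$perilesional), 0)
  expect_equal(sum(rings$lesion & rings$background), 0)
  expect_equal(sum(rings$perilesional & rings$background), 0)

  border <- matrix(FALSE, 20, 20); border[1, 5] <- TRUE
  expect_error(build_rings(border), "border")
  huge <- matrix(TRUE, 12, 12); huge[1, ] <- FALSE; huge[, 1] <- FALSE
  huge[12, ] <- FALSE; huge[, 12] <- FALSE
  expect_error(build_rings(huge), "third|small")
})

test_that("rings match brute-force dilation on random lesion shapes", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      frame <- c(90L, 90L)
      m <- matrix(FALSE, frame[1], frame[2])
      nblob <- sample(1:3, 1)
      for (b in seq_len(nblob)) {
        m <- m | disc_mat(frame, c(runif(1, 35, 55), runif(1, 35, 55)),
                          runif(1, 3, 7))
      }
      n <- sum(m)
      rings <- build_rings(m)
      d <- chebyshev_dist(m)
      counts1 <- sapply(1:40, function(k) sum(d <= k & !m))
      k1 <- min(which(counts1 >= n))
      expect_equal(sum(rings$perilesional), counts1[k1])
      counts2 <- sapply(k1:40, function(k) sum(d <= k & !m) - counts1[k1])
      k2 <- (k1:40)[min(which(counts2 >= n))]
      expect_equal(sum(rings$background), sum(d <= k2 & !m) - counts1[k1])
    }
  })
})

test_that("enhancement measurement is the lesion/background mean ratio", {
  frame <- c(80L, 80L)
  lesion <- disc_mat(frame, c(40, 40), 8)
  uni <- gray_image(matrix(500, 80, 80), kind = "recombined")
  rings <- build_rings(lesion)
  expect_equal(measure_enhancement(uni, rings), 1.0)
  px <- matrix(500, 80, 80); px[lesion] <- 530
  expect_equal(measure_enhancement(gray_image(px, kind = "recombined"), rings),
               1.06)
  zero <- gray_image(matrix(0, 80, 80), kind = "recombined")
  expect_error(measure_enhancement(zero, rings), "positive")
})

test_that("fitted distributions are normalized with mode at the data atom", {
  d <- fit_enhancement_distribution(rep(1.03, 5), bandwidth = 0.004)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_equal(d$grid[which.max(d$weights)], 1.03, tolerance = 1e-9)
  expect_error(fit_enhancement_distribution(1.02), "at least 2")
  expect_error(fit_enhancement_distribution(c(1.5, 1.3)), "1.0, 1.2")
})

test_that("KDE weights match direct kernel summation on a bimodal sample", {
  vals <- c(rep(1.01, 6), rep(1.05, 4))
  h <- 0.005
  d <- fit_enhancement_distribution(vals, bandwidth = h, grid_n = 61)
  oracle <- sapply(seq(1.00, 1.06, length.out = 61), function(g)
    sum(exp(-((g - vals) / h)^2 / 2)))
  oracle <- oracle / sum(oracle)
  expect_equal(d$weights, oracle, tolerance = 1e-12)
  # bimodal: local maxima near both atoms
  i1 <- which.min(abs(d$grid - 1.01)); i2 <- which.min(abs(d$grid - 1.05))
  expect_gt(d$weights[i1], d$weights[i1 + 8])
  expect_gt(d$weights[i2], d$weights[i2 - 8])
})

test_that("sampling is bounded, deterministic and matches the fitted CDF", {
  vals <- 1 + 0.06 * stats::rbeta(40, 2, 3)
  d <- fit_enhancement_distribution(vals, subset_key = "benign_CC")
  x <- sample_enhancement(d, n = 10000, seed = 4)
  expect_gte(min(x), 1.00)
  expect_lte(max(x), 1.06)
  expect_identical(x, sample_enhancement(d, n = 10000, seed = 4))
  # KS distance against the discrete fitted CDF
  cdf <- stats::stepfun(d$grid, c(0, cumsum(d$weights)))
  ks <- max(abs(sapply(d$grid, function(g) mean(x <= g) - cdf(g))))
  expect_lt(ks, 0.02)
  # subset routing: different keys draw from different streams
  d2 <- d; d2$subset_key <- "malignant_CC"
  expect_false(identical(sample_enhancement(d2, 10, seed = 4),
                         sample_enhancement(d, 10, seed = 4)))
})

test_that("applied enhancement is e in the deep interior and absent far away", {
  frame <- c(200L, 200L)
  lesion <- disc_mat(frame, c(100, 100), 35)
  img <- gray_image(matrix(1000, 200, 200), kind = "recombined")
  out <- apply_enhancement(img, lesion, 1.05, smooth_sigma = 5)
  expect_equal(out$pixels[100, 100] / 1000, 1.05, tolerance = 1e-4)
  # >= 6 sigma outside the mask: unchanged
  d <- chebyshev_dist(lesion)
  far <- d >= 66   # 35 px radius + 30 px kernel reach + margin
  expect_true(all(abs(out$pixels[far] - 1000) < 1e-6))
  # e = 1 returns the image bit-identically
  expect_identical(apply_enhancement(img, lesion, 1)$pixels, img$pixels)
})

test_that("round-trip error shrinks with lesion size", {
  errs <- sapply(c(20, 35, 50), function(rad) {
    frame <- c(260L, 260L)
    lesion <- disc_mat(frame, c(130, 130), rad)
    img <- gray_image(matrix(2000, 260, 260), kind = "recombined")
    out <- apply_enhancement(img, lesion, 1.05, smooth_sigma = 5)
    abs(measure_enhancement(out, build_rings(lesion)) - 1.05)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})
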