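# Enhancement measurement, per-(class, view) distribution fitting,
# sampling, and smoothed multiplicative enhancement of the recombined
# image.

#' Ring decomposition around a lesion mask
#'
#' The lesion mask is incrementally dilated with 1-pixel 8-connected
#' steps: the first stop is the first iteration at which the dilated area
#' minus the lesion reaches the lesion pixel count (perilesional ring);
#' dilation then continues until a second, equally sized background ring
#' is obtained.  The three regions are pairwise disjoint; ring pixel
#' counts overshoot their target by at most one dilation shell.
#'
#' @param lesion Logical/binary lesion mask.
#' @return A `ring_decomposition`: list of logical matrices `lesion`,
#'   `perilesional`, `background`.
#' @export
build_rings <- function(lesion) {
  stopifnot(is.matrix(lesion))
  lesion <- lesion != 0
  n_lesion <- sum(lesion)
  if (n_lesion == 0L) abort("empty lesion mask")
  if (any(lesion[1, ]) || any(lesion[nrow(lesion), ]) ||
      any(lesion[, 1]) || any(lesion[, ncol(lesion)])) {
    abort("lesion touches the image border; rings undefined")
  }
  if (n_lesion >= length(lesion) / 3) {
    abort("lesion covers a third of the frame or more; rings infeasible")
  }
  dil <- lesion
  repeat {
    dil <- dilate1_box(dil)
    if (sum(dil & !lesion) >= n_lesion) break
    if (all(dil)) abort("frame too small for the perilesional ring")
  }
  ring1 <- dil & !lesion
  repeat {
    dil <- dilate1_box(dil)
    if (sum(dil & !lesion & !ring1) >= n_lesion) break
    if (all(dil)) abort("frame too small for the background ring")
  }
  ring2 <- dil & !lesion & !ring1
  structure(list(lesion = lesion, perilesional = ring1, background = ring2),
            class = "ring_decomposition")
}

#' Measure the enhancement ratio of a lesion
#'
#' `e = meanPV(lesion) / meanPV(background ring)` in the recombined image.
#'
#' @param recombined A [gray_image()] of kind `"recombined"`.
#' @param rings A `ring_decomposition` from [build_rings()].
#' @return Scalar enhancement ratio.
#' @export
measure_enhancement <- function(recombined, rings) {
  stopifnot(inherits(recombined, "gray_image"),
            inherits(rings, "ring_decomposition"))
  if (!identical(dim(recombined$pixels), dim(rings$lesion))) {
    abort("rings and image shapes differ")
  }
  bg <- mean(recombined$pixels[rings$background])
  if (!is.finite(bg) || bg <= 0) abort("background ring mean must be positive")
  mean(recombined$pixels[rings$lesion]) / bg
}

#' Fit the per-(class, view) enhancement distribution
#'
#' Gaussian kernel density of measured enhancement values, evaluated on a
#' uniform grid over [1.00, 1.06] and renormalized so the weighted sum of
#' all grid probabilities equals 1.  Data preparation note: in the
#' intended use the value list is restricted to lesions that a baseline
#' detector missed; the fit itself accepts any value list.
#'
#' @param values Measured enhancement ratios (at least 2, within
#'   [1.0, 1.2]).
#' @param subset_key Label for the (class, view) subset, e.g.
#'   `"benign_CC"`.
#' @param bandwidth Kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]) on `values`.
#' @param grid_n Number of grid points over [1.00, 1.06] (default 121).
#' @return An `enhancement_distribution`: list with `subset_key`, `grid`,
#'   `weights` (summing to 1), `bandwidth`, `n`.
#' @export
fit_enhancement_distribution <- function(values, subset_key = "all",
                                         bandwidth = NULL, grid_n = 121L) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort("need at least 2 enhancement values")
  if (any(values < 1.0) || any(values > 1.2)) {
    abort("enhancement values must lie in [1.0, 1.2]")
  }
  h <- bandwidth %||% stats::bw.nrd0(values)
  if (!is_scalar_num(h) || h <= 0) abort("bandwidth must be positive")
  grid <- seq(1.00, 1.06, length.out = grid_n)
  w <- vapply(grid, function(g) sum(stats::dnorm((g - values) / h)), numeric(1))
  if (sum(w) <= 0) abort("kernel density vanished on the grid")
  w <- w / sum(w)
  structure(list(subset_key = subset_key, grid = grid, weights = w,
                 bandwidth = h, n = length(values)),
            class = "enhancement_distribution")
}

#' @export
print.enhancement_distribution <- function(x, ...) {
  cat(sprintf("<enhancement_distribution> %s: %d values, bw %.4g, %d grid points on [%.2f, %.2f]\n",
              x$subset_key, x$n, x$bandwidth, length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @rdname fit_enhancement_distribution
#' @param x An `enhancement_distribution`.
#' @param ... Unused.
#' @export
tidy.enhancement_distribution <- function(x, ...) {
  tibble::tibble(subset_key = x$subset_key, value = x$grid,
                 probability = x$weights)
}

#' @rdname fit_enhancement_distribution
#' @export
glance.enhancement_distribution <- function(x, ...) {
  cdf <- cumsum(x$weights)
  tibble::tibble(subset_key = x$subset_key, n = x$n, bandwidth = x$bandwidth,
                 mean = sum(x$grid * x$weights),
                 median = x$grid[which(cdf >= 0.5)[1]],
                 mode = x$grid[which.max(x$weights)])
}

#' @rdname fit_enhancement_distribution
#' @param object An `enhancement_distribution`.
#' @export
autoplot.enhancement_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$value, y = .data$probability)) +
    ggplot2::geom_col(width = diff(object$grid[1:2]), fill = "steelblue") +
    ggplot2::labs(x = "enhancement value", y = "probability",
                  title = object$subset_key) +
    ggplot2::theme_minimal()
}

#' Sample enhancement values from a fitted distribution
#'
#' Inverse-CDF sampling on the discrete grid with uniform jitter within
#' each grid bin; draws always lie in [1.00, 1.06].
#'
#' @param dist An `enhancement_distribution`.
#' @param n Number of draws.
#' @param seed Integer seed (fixed seed gives an identical draw sequence).
#' @return Numeric vector of length `n`.
#' @export
sample_enhancement <- function(dist, n = 1L, seed = 1L) {
  stopifnot(inherits(dist, "enhancement_distribution"))
  if (abs(sum(dist$weights) - 1) > 1e-9) {
    abort("distribution weights are not normalized")
  }
  step <- diff(dist$grid[1:2])
  withr::with_seed(derive_seed(seed, paste0("enh_", dist$subset_key)), {
    cdf <- cumsum(dist$weights)
    u <- stats::runif(n)
    idx <- findInterval(u, cdf) + 1L
    idx <- pmin(idx, length(dist$grid))
    jitter <- stats::runif(n, -step / 2, step / 2)
    pmin(pmax(dist$grid[idx] + jitter, min(dist$grid)), max(dist$grid))
  })
}

#' Apply smoothed enhancement to the recombined image
#'
#' Builds a multiplicative template equal to `e` inside the lesion mask
#' and 1.0 elsewhere, smooths it with a Gaussian kernel (default sigma
#' 5.0 px) to obtain a gradual decrease in enhancement toward the lesion
#' edge, and multiplies the recombined image with it at the insertion
#' location.  Pixels beyond the kernel footprint are unchanged; `e = 1`
#' returns the image bit-identically.
#'
#' @param recombined A [gray_image()] of kind `"recombined"`.
#' @param lesion Lesion mask (logical matrix, image shape).
#' @param e Enhancement factor (>= 1).
#' @param smooth_sigma Gaussian sigma in pixels (default 5.0).
#' @return A [gray_image()].
#' @export
apply_enhancement <- function(recombined, lesion, e, smooth_sigma = 5) {
  stopifnot(inherits(recombined, "gray_image"))
  if (!identical(dim(recombined$pixels), dim(lesion))) {
    abort("lesion mask and image shapes differ")
  }
  if (!is_scalar_num(e) || e < 1) abort("`e` must be a scalar >= 1")
  if (smooth_sigma < 0) abort("`smooth_sigma` must be >= 0")
  if (e == 1) return(recombined)
  excess <- matrix(as.numeric(lesion != 0), nrow(lesion)) * (e - 1)
  if (smooth_sigma > 0) {
    k <- gauss_kernel2(smooth_sigma, radius = ceiling(6 * smooth_sigma))
    excess <- conv2_zero(excess, k)
    excess[abs(excess) < 1e-12] <- 0
  }
  out <- recombined
  out$pixels <- recombined$pixels * (1 + excess)
  out
}
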