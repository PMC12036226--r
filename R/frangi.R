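# Frangi vesselness for 2D bright curvilinear structures, from the
# Hessian-of-Gaussian eigenvalue definition.  No installed package provides
# it, and candidate extraction is anchored on it.

gauss_deriv_kernels <- function(sigma) {
  r <- ceiling(3 * sigma) + 1L
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  list(g = g, g1 = g1, g2 = g2)
}

#' Frangi vesselness response for bright ridges
#'
#' Computes the multiscale vesselness of a 2D raster: Hessian of Gaussian
#' at each scale (scale-normalized by sigma^2), eigenvalues ordered by
#' magnitude, blobness ratio suppressed by `beta`, structureness scaled by
#' half the per-scale maximum Frobenius norm, bright-structure convention
#' (response zero where the dominant eigenvalue is positive).  The output
#' is the pixelwise maximum over scales.
#'
#' @param m Numeric matrix.
#' @param scales Gaussian scales (sigma, pixels); default 1--4.
#' @param beta Blobness sensitivity (default 0.5).
#' @return Matrix of vesselness values in [0, 1].
#' @export
frangi_vesselness <- function(m, scales = 1:4, beta = 0.5) {
  stopifnot(is.matrix(m), length(scales) >= 1L)
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    k <- gauss_deriv_kernels(s)
    hxx <- conv2_zero(m, outer(k$g, k$g2)) * s^2   # d2/dx2 (columns)
    hyy <- conv2_zero(m, outer(k$g2, k$g)) * s^2   # d2/dy2 (rows)
    hxy <- conv2_zero(m, outer(k$g1, k$g1)) * s^2
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    mu1 <- (hxx + hyy) / 2 + tmp
    mu2 <- (hxx + hyy) / 2 - tmp
    big <- abs(mu1) >= abs(mu2)          # lambda2: larger magnitude
    l2 <- ifelse(big, mu1, mu2)
    l1 <- ifelse(big, mu2, mu1)
    rb <- abs(l1) / pmax(abs(l2), .Machine$double.eps)
    st <- sqrt(l1^2 + l2^2)
    cs <- max(st) / 2
    if (cs <= 0) next
    v <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-st^2 / (2 * cs^2)))
    v[l2 > 0] <- 0                       # bright structures: lambda2 < 0
    best <- pmax(best, v)
  }
  best
}
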