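# Internal helpers shared across modules.

#' @importFrom rlang abort %||%
#' @importFrom stats dnorm quantile runif rnorm sd setNames
#' @importFrom utils head tail
NULL

# Deterministic per-stage seed derivation: one master seed fans out to
# independent stage streams so a change in one stage's draw count does not
# shift another stage's stream.  Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage_id <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.double(seed)) * 48271 + stage_id * 30269) %% 2147483629)
}

# Normalized 2D Gaussian kernel truncated at `radius` pixels (odd size).
gauss_kernel2 <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Convolve `m` with kernel `k` under zero padding (no circular wrap into the
# frame).  EBImage::filter2 is FFT-based and circular, so the frame is padded
# by the kernel radius first; total mass is conserved to FFT precision.
conv2_zero <- function(m, k) {
  r <- (dim(k)[1] - 1L) %/% 2L
  if (r == 0L) return(m * k[1, 1])
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(0, n + 2L * r, p + 2L * r)
  pad[(r + 1L):(r + n), (r + 1L):(r + p)] <- m
  out <- EBImage::filter2(pad, k, boundary = "circular")
  out[(r + 1L):(r + n), (r + 1L):(r + p)]
}

# 8-connected component labelling of a logical/0-1 matrix.  EBImage::bwlabel
# is 4-connected; candidate extraction requires 8-connectivity.
label8 <- function(mask) {
  mask <- mask != 0
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nb <- c(-1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
  cur <- 0L
  queue <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      rr <- ((v - 1L) %% n) + 1L
      for (d in nb) {
        w <- v + d
        if (w < 1L || w > n * p) next
        wr <- ((w - 1L) %% n) + 1L
        if (abs(wr - rr) > 1L) next  # column wrap guard
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          qt <- qt + 1L
          queue[qt] <- w
        }
      }
    }
  }
  lab
}

# Marching-squares perimeter of a binary region (matrix), via the 0.5
# isocontour of the zero-padded mask.  The mask is lightly smoothed first
# so the contour follows the shape rather than the pixel staircase, which
# would bias the length upward.
ms_perimeter <- function(mask) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  pad <- matrix(0, nrow(mask) + 6L, ncol(mask) + 6L)
  pad[4:(nrow(mask) + 3L), 4:(ncol(mask) + 3L)] <- mask
  pad <- conv2_zero(pad, gauss_kernel2(0.7, 3))
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)), pad,
                                levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1)))
}

# Binary dilation with a disc brush of the given radius (pixels).
dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask != 0)
  side <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  EBImage::dilate(matrix(as.numeric(mask != 0), nrow(mask)), brush) > 0.5
}

# One 8-connected (3x3 box) binary dilation.
dilate1_box <- function(mask) {
  EBImage::dilate(matrix(as.numeric(mask != 0), nrow(mask)),
                  matrix(1, 3, 3)) > 0.5
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
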