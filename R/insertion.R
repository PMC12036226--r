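# Multiplicative template construction, degradation, insertion into the
# low-energy image, and automatic lesion-mask generation (convex hull +
# outward corner smoothing + dilation).

#' Build a multiplicative insertion template from a cluster model
#'
#' Background pixels are exactly 1.0 (the original image is preserved upon
#' multiplication); each calcification pixel gets `1 + amplitude * w`,
#' where `w` is a per-region radial profile from the distance transform,
#' peaking at 1.0 at the region's morphological centre and tapering toward
#' its edge -- under the inverted lookup table of processed mammograms the
#' inserted calcifications therefore appear brighter.
#'
#' @param cluster A `cluster_model` from [grow_cluster()].
#' @param amplitude Peak multiplicative excess at a region centre
#'   (default 0.15).
#' @param frame Optional output shape `c(rows, cols)`; when given, the
#'   cell-resolution template is placed at the cluster's anchor so the
#'   template aligns with the full image.
#' @return An `insertion_template`: list with `factors` (raster of
#'   multiplicative factors) and `anchor`.
#' @export
build_template <- function(cluster, amplitude = 0.15, frame = NULL) {
  stopifnot(inherits(cluster, "cluster_model"))
  if (!is_scalar_num(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be a positive scalar")
  }
  if (sum(cluster$raster) == 0L) abort("empty cluster: no calcification pixels")
  cellf <- matrix(1, nrow(cluster$raster), ncol(cluster$raster))
  nr <- nrow(cluster$raster)
  for (i in seq_len(nrow(cluster$regions))) {
    idx <- cluster$regions$pixels[[i]]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    sub <- matrix(0, diff(range(rows)) + 3L, diff(range(cols)) + 3L)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- 1
    d <- EBImage::distmap(sub)
    w <- d / max(d)
    cellf[idx] <- 1 + amplitude * w[cbind(rows - min(rows) + 2L,
                                          cols - min(cols) + 2L)]
  }
  top <- 0L; left <- 0L
  if (!is.null(cluster$anchor)) {
    top <- cluster$anchor$top; left <- cluster$anchor$left
  }
  if (is.null(frame)) {
    factors <- cellf
  } else {
    factors <- matrix(1, frame[1], frame[2])
    factors[(top + 1L):(top + nrow(cellf)),
            (left + 1L):(left + ncol(cellf))] <- cellf
  }
  structure(list(factors = factors, anchor = c(top = top, left = left)),
            class = "insertion_template")
}

#' Apply degradation (blur and scatter) to an insertion template
#'
#' The multiplicative excess (`factors - 1`) is convolved with a
#' normalized Gaussian point-spread function and scaled by
#' `1 - scatter_fraction`; the template support grows by the blur
#' footprint.  With a normalized kernel the total excess is conserved by
#' the blur (before scatter scaling).
#'
#' @param tpl An `insertion_template`.
#' @param psf_sigma_px PSF sigma in pixels (default 1; 0 = no blur).
#' @param scatter_fraction Fraction of signal lost to scatter, in [0, 1)
#'   (default 0.2).
#' @return A degraded `insertion_template`.
#' @export
degrade_template <- function(tpl, psf_sigma_px = 1, scatter_fraction = 0.2) {
  stopifnot(inherits(tpl, "insertion_template"))
  if (psf_sigma_px < 0) abort("`psf_sigma_px` must be >= 0")
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    abort("`scatter_fraction` must be in [0, 1)")
  }
  excess <- tpl$factors - 1
  if (psf_sigma_px > 0) {
    excess <- conv2_zero(excess, gauss_kernel2(psf_sigma_px))
    excess[abs(excess) < 1e-12] <- 0  # keep the background exactly 1.0
  }
  excess <- excess * (1 - scatter_fraction)
  structure(list(factors = 1 + excess, anchor = tpl$anchor),
            class = "insertion_template")
}

#' Insert a template into an image by multiplication
#'
#' Output is the elementwise product; pixels where the template is exactly
#' 1.0 are bit-identical to the input, inserted pixels are brighter.
#'
#' @param img A [gray_image()].
#' @param tpl An `insertion_template` whose `factors` match the image
#'   shape.
#' @return A [gray_image()] with the cluster inserted.
#' @export
insert_template <- function(img, tpl) {
  stopifnot(inherits(img, "gray_image"), inherits(tpl, "insertion_template"))
  if (!identical(dim(img$pixels), dim(tpl$factors))) {
    abort("template and image shapes differ")
  }
  out <- img
  out$pixels <- img$pixels * tpl$factors
  out
}

#' Template support (pixels differing from 1.0)
#' @param tpl An `insertion_template`.
#' @return Logical matrix.
#' @export
template_support <- function(tpl) tpl$factors != 1

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xi <- c(x[-1], x[1]); yi <- c(y[-1], y[1])
  0.5 * sum(x * yi - xi * y)
}

#' Outward corner-smoothing pass for a convex contour
#'
#' A corner-cutting-style pass that enlarges instead of cutting: each
#' corner contributes two points, displaced outward by `offset_px` along
#' the outward normals of its two adjacent edges.  Every edge of the input
#' is thereby translated outward and every corner replaced by an outward
#' bevel, so the input polygon is contained in the output for any convex
#' input and any positive offset, the area is non-decreasing, and corners
#' smooth over iterations.
#'
#' @param poly Numeric matrix `n x 2` of vertices `(x = col, y = row)` of
#'   a simple convex polygon.
#' @param iterations Number of passes (0 returns the input unchanged).
#' @param offset_px Outward displacement per pass, in pixels.
#' @return Expanded polygon matrix (counter-clockwise).
#' @export
expand_contour <- function(poly, iterations = 2L, offset_px = 2) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L) {
    abort("`poly` must be an n x 2 matrix with n >= 3")
  }
  if (iterations < 0) abort("`iterations` must be >= 0")
  if (shoelace_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  for (it in seq_len(iterations)) {
    n <- nrow(poly)
    nxt <- c(2:n, 1L)
    ex <- poly[nxt, 1] - poly[, 1]
    ey <- poly[nxt, 2] - poly[, 2]
    len <- pmax(sqrt(ex^2 + ey^2), .Machine$double.eps)
    # outward normal of each edge of a CCW polygon
    nx <- ey / len
    ny <- -ex / len
    prev <- c(n, 1:(n - 1L))
    a <- cbind(poly[, 1] + offset_px * nx[prev],
               poly[, 2] + offset_px * ny[prev])
    b <- cbind(poly[, 1] + offset_px * nx,
               poly[, 2] + offset_px * ny)
    out <- matrix(0, 2L * n, 2L)
    out[seq(1L, 2L * n, by = 2L), ] <- a
    out[seq(2L, 2L * n, by = 2L), ] <- b
    poly <- out
  }
  poly
}

# Rasterize a convex CCW polygon: pixels whose centre (col = x, row = y)
# lies inside or on the polygon.
rasterize_convex <- function(poly, frame) {
  if (shoelace_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  rmin <- max(1L, floor(min(poly[, 2])))
  rmax <- min(frame[1], ceiling(max(poly[, 2])))
  cmin <- max(1L, floor(min(poly[, 1])))
  cmax <- min(frame[2], ceiling(max(poly[, 1])))
  mask <- matrix(FALSE, frame[1], frame[2])
  if (rmin > rmax || cmin > cmax) return(mask)
  rs <- rmin:rmax; cs <- cmin:cmax
  yy <- matrix(rs, length(rs), length(cs))
  xx <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  inside <- matrix(TRUE, length(rs), length(cs))
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) {
    cross <- (poly[nxt[i], 1] - poly[i, 1]) * (yy - poly[i, 2]) -
      (poly[nxt[i], 2] - poly[i, 2]) * (xx - poly[i, 1])
    inside <- inside & (cross >= -1e-9)
  }
  mask[rs, cs] <- inside
  mask
}

#' Automatically generate a lesion mask around inserted calcifications
#'
#' Convex hull of all calcification pixels, smoothed outward with
#' [expand_contour()], rasterized, and dilated -- emulating radiologists'
#' habit of including a margin of perilesional tissue.  Degenerate
#' supports (fewer than 3 pixels, or collinear) fall back to a disc
#' dilation of the support.
#'
#' @param support Binary matrix of calcification pixels (a cluster raster
#'   placed in the frame, or [template_support()] of a degraded template).
#' @param expand_iterations,offset_px Passed to [expand_contour()]
#'   (defaults 2 and 2).
#' @param dilation_px Radius of the final disc dilation (default 5).
#' @return Logical matrix of class `lesion_mask` with attribute
#'   `provenance = "auto_generated"`; always a superset of `support`.
#' @export
generate_lesion_mask <- function(support, expand_iterations = 2L,
                                 offset_px = 2, dilation_px = 5) {
  stopifnot(is.matrix(support))
  pts <- which(support != 0)
  if (length(pts) == 0L) abort("empty support: no calcification pixels")
  nr <- nrow(support)
  xy <- cbind(x = ((pts - 1L) %/% nr) + 1L, y = ((pts - 1L) %% nr) + 1L)
  hull_ok <- FALSE
  if (nrow(unique(xy)) >= 3L) {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    if (length(h) >= 3L) {
      poly <- xy[h, , drop = FALSE]
      if (abs(shoelace_area(poly)) > 1e-9) hull_ok <- TRUE
    }
  }
  if (!hull_ok) {
    mask <- dilate_disc(support, max(dilation_px, 1))
  } else {
    poly <- expand_contour(poly, iterations = expand_iterations,
                           offset_px = offset_px)
    mask <- rasterize_convex(poly, dim(support))
    mask <- mask | (support != 0)   # guard against half-pixel raster loss
    if (dilation_px >= 1) mask <- dilate_disc(mask, dilation_px)
  }
  structure(mask, provenance = "auto_generated",
            class = c("lesion_mask", class(mask)))
}
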