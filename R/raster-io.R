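# Image, mask and annotation-table I/O plus breast segmentation and the
# 3-channel CLAHE composition used to prepare CEM images for a detector.

#' Construct a grayscale CEM image
#'
#' The unit all pipeline stages operate on: a 2D nonnegative intensity
#' raster together with its pixel spacing, mammographic view and image kind
#' (low-energy or recombined).  Pixel values are stored as digital numbers
#' (typically integers in 0--65535, the 16-bit range of processed CEM
#' images); nothing below assumes a particular absolute range, only that
#' calcifications and enhancement brighten the image multiplicatively.
#'
#' @param pixels Numeric matrix of finite, nonnegative intensities
#'   (rows = image rows).
#' @param spacing_mm Isotropic pixel pitch in mm (default 0.1 mm, typical
#'   for full-field digital mammography systems).
#' @param view Mammographic view, `"CC"` or `"MLO"`.
#' @param kind `"low_energy"` or `"recombined"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing_mm = 0.1, view = c("CC", "MLO"),
                       kind = c("low_energy", "recombined")) {
  view <- match.arg(view)
  kind <- match.arg(kind)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) abort("image must be at least 1x1")
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("pixels must be finite and nonnegative")
  }
  if (!is_scalar_num(spacing_mm) || spacing_mm <= 0) {
    abort("`spacing_mm` must be a positive scalar")
  }
  structure(list(pixels = pixels, spacing_mm = spacing_mm,
                 view = view, kind = kind),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g mm/px, view %s, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$view, x$kind))
  cat(sprintf("  intensity range [%.0f, %.0f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pair of low-energy and recombined images of one view
#'
#' @param low_energy,recombined [gray_image] objects of matching shape,
#'   spacing and view.
#' @param patient_id Opaque patient identifier.
#' @param laterality `"L"` or `"R"`.
#' @return An object of class `case_pair`.
#' @export
case_pair <- function(low_energy, recombined, patient_id = "anon",
                      laterality = c("L", "R")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(low_energy, "gray_image"),
            inherits(recombined, "gray_image"))
  if (!identical(dim(low_energy$pixels), dim(recombined$pixels))) {
    abort("low-energy and recombined images must have the same shape")
  }
  if (low_energy$spacing_mm != recombined$spacing_mm) {
    abort("pixel spacings must match")
  }
  if (low_energy$view != recombined$view) abort("views must match")
  structure(list(low_energy = low_energy, recombined = recombined,
                 patient_id = patient_id, laterality = laterality),
            class = "case_pair")
}

#' Read a grayscale PNG as a CEM image
#'
#' Accepts 8- or 16-bit grayscale PNGs and preserves the stored bit depth:
#' pixel values are returned as integers on the native scale (0--255 or
#' 0--65535), so a write/read round-trip is bit-exact.
#'
#' @inheritParams gray_image
#' @param path Path to the PNG file.
#' @return A [gray_image].
#' @export
read_image <- function(path, spacing_mm = 0.1, view = c("CC", "MLO"),
                       kind = c("low_energy", "recombined")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L && dim(img)[3] > 1L) {
    abort("expected a grayscale PNG; got a multi-channel image")
  }
  depth <- info$bit.depth %||% 8L
  scale <- 2^depth - 1
  px <- round(matrix(img, nrow(img), ncol(img)) * scale)
  gray_image(px, spacing_mm = spacing_mm, view = view, kind = kind)
}

#' Write a CEM image or binary mask as PNG
#'
#' Images are written as 16-bit grayscale PNG (dynamic range of processed
#' CEM images); masks as 8-bit PNG with values {0, 255}.
#'
#' @param img A [gray_image] with values in 0--65535.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  if (any(img$pixels > 65535)) abort("pixel values exceed the 16-bit range")
  write_png16(img$pixels, path)
}

#' @rdname write_image
#' @param mask Logical or 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(img > 0.5, nrow(img), ncol(img))
}

#' Segment the breast region
#'
#' Otsu threshold, largest connected above-threshold component (preferring
#' components that touch a lateral image border, where the breast enters the
#' field of view), holes filled.
#'
#' @param img A [gray_image].
#' @return Logical matrix of the breast support (`breast_mask`).
#' @export
segment_breast <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  px <- img$pixels / 65535
  thr <- EBImage::otsu(px, range = c(0, 1))
  bw <- px > thr
  if (!any(bw)) abort("no breast found: empty foreground after thresholding")
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(bw)))
  sizes <- tabulate(lab[lab > 0])
  lateral <- unique(c(lab[, 1L], lab[, ncol(lab)]))
  lateral <- lateral[lateral > 0]
  cand <- if (length(lateral)) lateral else seq_along(sizes)
  keep <- cand[which.max(sizes[cand])]
  mask <- lab == keep
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0.5
  structure(mask, class = c("breast_mask", class(mask)))
}

#' Compose the 3-channel detector input image
#'
#' Channel 1 is the CLAHE-filtered low-energy image, channel 2 the original
#' low-energy image (extra weight on the image that best shows
#' calcifications), channel 3 the CLAHE-filtered recombined image.
#'
#' @param pair A [case_pair].
#' @param nx,ny CLAHE tile grid (default 8x8).
#' @param limit CLAHE clip limit (EBImage semantics; default 2).
#' @return Numeric array `rows x cols x 3` on the 0--65535 scale; channel 2
#'   is bit-identical to the input low-energy raster.
#' @export
compose_rgb <- function(pair, nx = 8, ny = 8, limit = 2) {
  stopifnot(inherits(pair, "case_pair"))
  le <- pair$low_energy$pixels
  rc <- pair$recombined$pixels
  clahe01 <- function(m) {
    if (max(m) == min(m)) return(m)  # constant image: nothing to equalize
    out <- EBImage::clahe(m / 65535, nx = nx, ny = ny, limit = limit)
    matrix(as.numeric(out), nrow(m)) * 65535
  }
  out <- array(0, dim = c(nrow(le), ncol(le), 3L))
  out[, , 1L] <- clahe01(le)
  out[, , 2L] <- le
  out[, , 3L] <- clahe01(rc)
  out
}

#' Write / read ROI annotation tables
#'
#' One record per ROI: patient id, view, label, optional score, and a
#' reference to a mask PNG, as delimited text.  The mask files live next to
#' the table.
#'
#' @param rois Tibble with columns `patient_id`, `view`, `label`,
#'   optionally `score`, and `mask` (list column of ROI masks, see
#'   [roi_mask()]).
#' @param path CSV path; masks are written alongside as
#'   `<stem>_roi<k>.png`.
#' @return Path of the table, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  stem <- sub("\\.csv$", "", path)
  tab <- dplyr::mutate(rois, mask_file = sprintf("%s_roi%03d.png", basename(stem),
                                                 dplyr::row_number()))
  purrr::walk2(tab$mask, tab$mask_file, function(m, f) {
    write_mask(roi_mask_matrix(m), file.path(dirname(path), f))
  })
  utils::write.csv(dplyr::select(tab, -"mask"), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @param frame Frame dimension `c(rows, cols)` the masks live in.
#' @export
read_roi_table <- function(path, frame = NULL) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tab$mask <- purrr::map(tab$mask_file, function(f) {
    m <- read_mask(file.path(dirname(path), f))
    roi_mask(m)
  })
  dplyr::select(tab, -"mask_file")
}

#' Read a YAML configuration file into a simulation config
#'
#' @param path YAML file; keys override [simulation_config()] defaults.
#' @return A `simulation_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}
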