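# Candidate calcification extraction inside the selected grid cell,
# class-specific morphology filtering, and iterative cluster growth from
# the highest-contrast sub-cell.

#' Class-specific morphology criteria for calcification candidates
#'
#' Typically benign clusters keep the larger, rounder calcifications
#' (circularity 0.5--1.0, equivalent diameter 0.3--1.2 mm, 10--20 per
#' cluster); typically malignant clusters keep small irregular ones (any
#' circularity, 0.1--0.5 mm, 20--40 per cluster).  All intervals are
#' closed.
#'
#' @param class `"benign"` or `"malignant"`.
#' @param circularity,size_mm,count Optional overrides of the class
#'   default ranges (length-2 numeric).
#' @return A `class_criteria` list.
#' @export
class_criteria <- function(class = c("benign", "malignant"),
                           circularity = NULL, size_mm = NULL, count = NULL) {
  class <- match.arg(class)
  defaults <- switch(class,
    benign = list(circularity = c(0.5, 1.0), size_mm = c(0.3, 1.2),
                  count = c(10L, 20L)),
    malignant = list(circularity = c(0.0, 1.0), size_mm = c(0.1, 0.5),
                     count = c(20L, 40L)))
  out <- list(class = class,
              circularity = circularity %||% defaults$circularity,
              size_mm = size_mm %||% defaults$size_mm,
              count = as.integer(count %||% defaults$count))
  stopifnot(length(out$circularity) == 2L, length(out$size_mm) == 2L,
            length(out$count) == 2L, out$count[1] <= out$count[2])
  structure(out, class = "class_criteria")
}

#' Binary candidate mask of a grid cell
#'
#' Elementwise AND of the binarized Frangi vesselness response (top
#' `1 - frangi_quantile` fraction of within-cell response) and an intensity
#' threshold mask (mean + `thr_k` standard deviations of the cell).
#'
#' @param cell Numeric matrix (one grid cell of the low-energy image).
#' @param frangi_scales,frangi_beta Passed to [frangi_vesselness()].
#' @param frangi_quantile Vesselness binarization quantile (default 0.95).
#' @param thr_k Intensity threshold offset in cell standard deviations.
#' @return Logical matrix; a subset of the intensity-threshold mask.
#' @export
candidate_mask <- function(cell, frangi_scales = 1:4, frangi_beta = 0.5,
                           frangi_quantile = 0.95, thr_k = 1) {
  stopifnot(is.matrix(cell), length(cell) > 0L)
  if (max(cell) == min(cell)) return(matrix(FALSE, nrow(cell), ncol(cell)))
  v <- frangi_vesselness(cell, scales = frangi_scales, beta = frangi_beta)
  fmask <- v > stats::quantile(v, frangi_quantile)
  imask <- cell > mean(cell) + thr_k * stats::sd(cell)
  fmask & imask
}

#' Extract connected candidate regions with morphology measurements
#'
#' 8-connected components of a binary mask with area, marching-squares
#' perimeter, circularity and equivalent diameter.  Circularity
#' `4*pi*A/P^2` is clamped at 1 to absorb the discretization bias of the
#' perimeter estimate for very small regions.  Regions are ordered by the
#' (top, left) corner of their bounding box.
#'
#' @param mask Logical/binary matrix (e.g. from [candidate_mask()]).
#' @param spacing_mm Pixel pitch in mm.
#' @param intensity Optional raster for per-region mean intensity.
#' @return Tibble with one row per region: `region_id`, `area_px`,
#'   `perimeter_px`, `circularity`, `equiv_diameter_mm`, `centroid_row`,
#'   `centroid_col`, `bbox_*`, `mean_intensity`, `pixels` (list of linear
#'   indices into the mask).
#' @export
extract_candidates <- function(mask, spacing_mm = 0.1, intensity = NULL) {
  stopifnot(is.matrix(mask))
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(region_id = integer(), area_px = integer(),
                          perimeter_px = numeric(), circularity = numeric(),
                          equiv_diameter_mm = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          bbox_top = integer(), bbox_left = integer(),
                          mean_intensity = numeric(), pixels = list()))
  }
  nr <- nrow(mask)
  regions <- purrr::map_dfr(seq_len(n), function(i) {
    idx <- which(lab == i)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    sub <- matrix(FALSE, diff(range(rows)) + 1L, diff(range(cols)) + 1L)
    sub[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
    per <- ms_perimeter(sub)
    area <- length(idx)
    circ <- if (per > 0) min(4 * pi * area / per^2, 1) else 1
    tibble::tibble(
      region_id = i, area_px = area, perimeter_px = per,
      circularity = circ,
      equiv_diameter_mm = 2 * spacing_mm * sqrt(area / pi),
      centroid_row = mean(rows), centroid_col = mean(cols),
      bbox_top = min(rows), bbox_left = min(cols),
      mean_intensity = if (is.null(intensity)) NA_real_ else
        mean(intensity[idx]),
      pixels = list(idx))
  })
  regions <- dplyr::arrange(regions, .data$bbox_top, .data$bbox_left)
  regions$region_id <- seq_len(nrow(regions))
  regions
}

#' Filter candidate regions by class criteria
#'
#' Keeps regions whose circularity and equivalent diameter fall inside the
#' closed class ranges.  Idempotent and order-preserving.
#'
#' @param regions Tibble from [extract_candidates()].
#' @param criteria A [class_criteria()].
#' @return The retained rows of `regions`.
#' @export
filter_candidates <- function(regions, criteria) {
  stopifnot(inherits(criteria, "class_criteria"))
  dplyr::filter(regions,
                .data$circularity >= criteria$circularity[1],
                .data$circularity <= criteria$circularity[2],
                .data$equiv_diameter_mm >= criteria$size_mm[1],
                .data$equiv_diameter_mm <= criteria$size_mm[2])
}

# Per-sub-cell contrast map (max - mean) of a cell raster.
subcell_contrast <- function(cell, subcell_px) {
  ns <- nrow(cell) %/% subcell_px
  ms <- ncol(cell) %/% subcell_px
  con <- matrix(0, ns, ms)
  for (i in seq_len(ns)) {
    for (j in seq_len(ms)) {
      sub <- cell[((i - 1L) * subcell_px + 1L):(i * subcell_px),
                  ((j - 1L) * subcell_px + 1L):(j * subcell_px)]
      con[i, j] <- max(sub) - mean(sub)
    }
  }
  con
}

#' Grow a calcification cluster from the highest-contrast sub-cell
#'
#' The cell is divided into `subcell_px` x `subcell_px` sub-cells and the
#' one with the highest contrast (max - mean intensity) seeds the cluster.
#' All filtered candidate regions whose centroid lies in the current search
#' window are incorporated; the window grows by one sub-cell ring per
#' iteration until the target calcification count (drawn uniformly from
#' the class count range) is reached or the cell is exhausted.  If fewer
#' candidates than the class lower count bound are available, the
#' simulation for this view is infeasible and an error of class
#' `"cemsim_infeasible_cluster"` is signalled so the caller can skip the
#' view.
#'
#' @param cell Numeric matrix (the selected grid cell).
#' @param regions Filtered candidate tibble ([filter_candidates()]).
#' @param criteria A [class_criteria()].
#' @param subcell_px Sub-cell side; must divide the cell side (default 10).
#' @param seed Integer seed (target count draw).
#' @param anchor Optional grid-cell row (from [select_insertion_site()])
#'   recording where the cell sits in the full image.
#' @return A `cluster_model`: binary raster at cell resolution (unity
#'   marks calcifications), class, count, target, member regions, anchor.
#' @export
grow_cluster <- function(cell, regions, criteria, subcell_px = 10L,
                         seed = 1L, anchor = NULL) {
  stopifnot(is.matrix(cell), inherits(criteria, "class_criteria"))
  subcell_px <- as.integer(subcell_px)
  if (nrow(cell) %% subcell_px != 0L || ncol(cell) %% subcell_px != 0L) {
    abort("`subcell_px` must divide the cell size")
  }
  target <- withr::with_seed(derive_seed(seed, "cluster_target"),
                             sample(criteria$count[1]:criteria$count[2], 1L))
  if (nrow(regions) < criteria$count[1]) {
    abort(sprintf(
      "infeasible cluster: %d candidate regions < lower bound %d; no simulation for this view",
      nrow(regions), criteria$count[1]),
      class = "cemsim_infeasible_cluster")
  }
  con <- subcell_contrast(cell, subcell_px)
  start <- which(con == max(con), arr.ind = TRUE)[1L, ]
  ns <- nrow(con); ms <- ncol(con)
  r0 <- r1 <- start[["row"]]; c0 <- c1 <- start[["col"]]
  repeat {
    in_win <- regions$centroid_row >= (r0 - 1L) * subcell_px + 1L &
      regions$centroid_row <= r1 * subcell_px &
      regions$centroid_col >= (c0 - 1L) * subcell_px + 1L &
      regions$centroid_col <= c1 * subcell_px
    count <- sum(in_win)
    full <- r0 == 1L && c0 == 1L && r1 == ns && c1 == ms
    if (count >= target || full) break
    r0 <- max(r0 - 1L, 1L); c0 <- max(c0 - 1L, 1L)
    r1 <- min(r1 + 1L, ns); c1 <- min(c1 + 1L, ms)
  }
  members <- regions[in_win, ]
  if (nrow(members) < criteria$count[1]) {
    abort(sprintf(
      "infeasible cluster: only %d reachable calcifications < lower bound %d; no simulation for this view",
      nrow(members), criteria$count[1]),
      class = "cemsim_infeasible_cluster")
  }
  if (nrow(members) > target) {
    # the last sub-cell ring may overshoot the predetermined count: keep
    # the target number of regions closest to the seed sub-cell
    seed_ctr <- c((start[["row"]] - 0.5) * subcell_px,
                  (start[["col"]] - 0.5) * subcell_px)
    d2 <- (members$centroid_row - seed_ctr[1])^2 +
      (members$centroid_col - seed_ctr[2])^2
    members <- members[order(d2, members$region_id)[seq_len(target)], ]
    members <- dplyr::arrange(members, .data$region_id)
  }
  raster <- matrix(0L, nrow(cell), ncol(cell))
  raster[unlist(members$pixels)] <- 1L
  structure(list(raster = raster, class = criteria$class,
                 count = nrow(members), target = target,
                 regions = members, anchor = anchor,
                 subcell_px = subcell_px, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s, %d calcifications (target %d), %d x %d cell\n",
              x$class, x$count, x$target, nrow(x$raster), ncol(x$raster)))
  invisible(x)
}
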