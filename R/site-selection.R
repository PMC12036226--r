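# Texture-guided insertion-site selection: per-cell texture features on a
# non-overlapping grid over the breast, combined by direction-aware rank
# aggregation to find the densest, structurally busiest cell.

#' Default texture feature specification
#'
#' Five per-cell texture features act as proxies for "denser regions with
#' greater structural variety": mean intensity, standard deviation,
#' intensity entropy, mean gradient magnitude and intensity range.  Each
#' has a ranking direction (all `higher_better` by default: denser = higher
#' mean, busier = higher variation) and a weight.  The set is a documented,
#' replaceable default; any tibble with these columns can be substituted.
#'
#' @return Tibble with columns `feature`, `direction`, `weight`.
#' @export
default_feature_specs <- function() {
  tibble::tibble(
    feature = c("mean", "sd", "entropy", "gradient", "range"),
    direction = "higher_better",
    weight = 1
  )
}

cell_entropy <- function(v, bins = 64L) {
  h <- tabulate(pmin(pmax(findInterval(v, seq(0, 65535, length.out = bins + 1L),
                                       all.inside = TRUE), 1L), bins), bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Compute per-cell texture features on a non-overlapping grid
#'
#' The image is tiled with non-overlapping square cells of `cell_px` pixels
#' anchored at the image origin; cells with less than `min_coverage` breast
#' coverage are dropped.
#'
#' @param img A [gray_image()] (low-energy).
#' @param breast Breast mask from [segment_breast()] (logical matrix).
#' @param cell_px Cell side in pixels (default 200).
#' @param min_coverage Minimum fraction of in-breast pixels per cell.
#' @return Tibble of grid cells: `row`, `col` (1-based cell indices),
#'   `top`, `left` (0-based pixel origin, half-open bounds of side
#'   `cell_px`), one column per feature.
#' @export
compute_grid_features <- function(img, breast, cell_px = 200L,
                                  min_coverage = 0.9) {
  stopifnot(inherits(img, "gray_image"))
  cell_px <- as.integer(cell_px)
  if (cell_px < 16L) abort("`cell_px` must be at least 16")
  px <- img$pixels
  if (nrow(px) < cell_px || ncol(px) < cell_px) {
    abort("image smaller than one grid cell")
  }
  if (!identical(dim(breast), dim(px))) abort("breast mask shape mismatch")
  nr <- nrow(px) %/% cell_px
  nc <- ncol(px) %/% cell_px
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  cells <- purrr::pmap_dfr(grid, function(row, col) {
    rs <- (row - 1L) * cell_px + 1L
    cs <- (col - 1L) * cell_px + 1L
    sub <- px[rs:(rs + cell_px - 1L), cs:(cs + cell_px - 1L)]
    cov <- mean(breast[rs:(rs + cell_px - 1L), cs:(cs + cell_px - 1L)])
    if (cov < min_coverage) return(NULL)
    gy <- sub[-1, ] - sub[-nrow(sub), ]
    gx <- sub[, -1] - sub[, -ncol(sub)]
    gm <- mean(c(abs(gy), abs(gx)))
    tibble::tibble(
      row = row, col = col,
      top = rs - 1L, left = cs - 1L, cell_px = cell_px,
      coverage = cov,
      mean = mean(sub), sd = stats::sd(sub),
      entropy = cell_entropy(sub),
      gradient = gm, range = max(sub) - min(sub))
  })
  if (nrow(cells) == 0L) abort("no eligible grid cell inside the breast")
  class(cells) <- c("grid_cells", class(cells))
  cells
}

#' Select the insertion cell by weighted rank aggregation
#'
#' Each feature ranks the cells (direction-aware, average ranks for ties);
#' ranks are combined as a weighted sum and the highest-scoring cell wins.
#' Ties are broken by (row, col) lexicographic order, so selection is
#' invariant to the order of the input rows.
#'
#' @param cells Tibble from [compute_grid_features()].
#' @param specs Feature specification tibble (see
#'   [default_feature_specs()]).
#' @return The winning row of `cells`, with its aggregate `score` added.
#' @export
select_insertion_site <- function(cells, specs = default_feature_specs()) {
  if (is.null(cells) || nrow(cells) == 0L) abort("no cells to rank")
  if (is.null(specs) || nrow(specs) == 0L) abort("no feature specs")
  missing <- setdiff(specs$feature, names(cells))
  if (length(missing)) {
    abort(paste("unknown features:", paste(missing, collapse = ", ")))
  }
  if (any(specs$weight < 0)) abort("feature weights must be nonnegative")
  score <- rep(0, nrow(cells))
  for (i in seq_len(nrow(specs))) {
    v <- cells[[specs$feature[i]]]
    r <- if (identical(specs$direction[i], "lower_better")) {
      rank(-v, ties.method = "average")
    } else {
      rank(v, ties.method = "average")
    }
    score <- score + specs$weight[i] * r
  }
  ord <- order(-score, cells$row, cells$col)
  out <- cells[ord[1L], ]
  out$score <- score[ord[1L]]
  out
}

#' Crop the pixel raster of one grid cell from an image
#' @param img A [gray_image()].
#' @param cell One row of the tibble from [compute_grid_features()].
#' @return Numeric matrix of the cell's pixels.
#' @export
crop_cell <- function(img, cell) {
  px <- img$pixels
  rs <- cell$top + 1L
  cs <- cell$left + 1L
  px[rs:(rs + cell$cell_px - 1L), cs:(cs + cell$cell_px - 1L)]
}
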