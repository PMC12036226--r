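# ROI-level detection/classification evaluation: IoU matching, the
# correct-detection definition, sensitivity/precision, DL-score
# binomialization, ensembling, falsely-detected-ROIs-as-benign ROC-AUC,
# and patient-level bootstrap confidence intervals.

#' Compact ROI mask representation
#'
#' ROI masks are stored as sorted linear pixel indices plus the frame
#' dimension, which keeps toy annotation sets light and makes IoU a set
#' operation.
#'
#' @param m Logical/binary matrix.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(m) {
  stopifnot(is.matrix(m))
  structure(list(idx = which(m != 0), frame = dim(m)), class = "roi_mask")
}

#' @rdname roi_mask
#' @param frame Frame dimension `c(rows, cols)`.
#' @param center Disc centre `c(row, col)`.
#' @param radius Disc radius in pixels.
#' @export
roi_mask_disc <- function(frame, center, radius) {
  rr <- matrix(seq_len(frame[1]), frame[1], frame[2])
  cc <- matrix(seq_len(frame[2]), frame[1], frame[2], byrow = TRUE)
  roi_mask((rr - center[1])^2 + (cc - center[2])^2 <= radius^2)
}

#' @rdname roi_mask
#' @param rm An `roi_mask`.
#' @export
roi_mask_matrix <- function(rm) {
  stopifnot(inherits(rm, "roi_mask"))
  m <- matrix(FALSE, rm$frame[1], rm$frame[2])
  m[rm$idx] <- TRUE
  m
}

#' Intersection over union of two masks
#'
#' @param a,b `roi_mask` objects or logical matrices on the same frame.
#' @return IoU in [0, 1]; 0 when the union is empty.
#' @export
compute_iou <- function(a, b) {
  if (is.matrix(a)) a <- roi_mask(a)
  if (is.matrix(b)) b <- roi_mask(b)
  if (!identical(a$frame, b$frame)) abort("masks live on different frames")
  u <- length(union(a$idx, b$idx))
  if (u == 0L) return(0)
  length(intersect(a$idx, b$idx)) / u
}

#' Collapse a 4-class label to benign/malignant
#'
#' `benign_mass` and `benign_cluster` map to `"benign"`;
#' `malignant_mass` and `malignant_cluster` to `"malignant"`.
#'
#' @param label4 Character vector of 4-class labels.
#' @return Character vector of `"benign"`/`"malignant"`.
#' @export
binarize_label <- function(label4) {
  valid <- c("benign_mass", "benign_cluster", "malignant_mass",
             "malignant_cluster")
  if (!all(label4 %in% valid)) abort("invalid 4-class label")
  ifelse(startsWith(label4, "benign"), "benign", "malignant")
}

#' Map a DL class + prediction score to binomial probabilities
#'
#' For a benign-labelled ROI, `p_ben = 0.5 * pred_score + 0.5` and
#' `p_mal = 1 - p_ben`; for a malignant label the mapping is inverted.
#' The predicted class always ends up with probability >= 0.5, aligning
#' the detector's confidence score with the binomial output of a
#' radiomics classifier.
#'
#' @param label4 4-class label (vectorized).
#' @param pred_score Prediction score in [0, 1] (vectorized).
#' @return Tibble with columns `p_ben`, `p_mal` (rows sum to 1).
#' @export
dl_score_to_binomial <- function(label4, pred_score) {
  if (any(pred_score < 0 | pred_score > 1)) {
    abort("`pred_score` must be in [0, 1]")
  }
  cls <- binarize_label(label4)
  p_pred <- 0.5 * pred_score + 0.5
  tibble::tibble(
    p_ben = ifelse(cls == "benign", p_pred, 1 - p_pred),
    p_mal = ifelse(cls == "benign", 1 - p_pred, p_pred))
}

#' Average two binomial probability pairs (model ensembling)
#'
#' @param dl,hr Tibbles/data frames with columns `p_ben`, `p_mal`, each
#'   row summing to 1.
#' @return Tibble of elementwise means; rows still sum to 1.  The
#'   ensembled class can differ from either input's class when the other
#'   model is confidently opposite.
#' @export
ensemble_probs <- function(dl, hr) {
  chk <- function(p) {
    if (any(abs(p$p_ben + p$p_mal - 1) > 1e-9)) {
      abort("probabilities must sum to 1")
    }
  }
  chk(dl); chk(hr)
  tibble::tibble(p_ben = (dl$p_ben + hr$p_ben) / 2,
                 p_mal = (dl$p_mal + hr$p_mal) / 2)
}

# Exact maximum-total-IoU one-to-one assignment between predictions and
# ground truths, over pairs with IoU > iou_thr.  DP over subsets of GTs;
# deterministic tie-break: larger total IoU, then more matched pairs, then
# lexicographically smallest assignment (by prediction order, preferring
# lower GT indices).  Falls back to greedy IoU-descending matching above
# `exact_max` ground truths (per patient/view counts are tiny in practice).
assign_pairs <- function(iou, iou_thr, exact_max = 16L) {
  m <- nrow(iou); n <- ncol(iou)
  if (m == 0L || n == 0L) return(integer(0))
  iou[iou <= iou_thr] <- NA
  if (n > exact_max) return(assign_greedy(iou))
  best_score <- -1; best_cnt <- -1L; best_asg <- rep(NA_integer_, m)
  recurse <- function(p, used, score, cnt, asg) {
    if (p > m) {
      better <- score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 && cnt > best_cnt)
      if (better) {
        best_score <<- score; best_cnt <<- cnt; best_asg <<- asg
      }
      return(invisible())
    }
    for (g in seq_len(n)) {       # lower GT index explored first
      if (!used[g] && !is.na(iou[p, g])) {
        used[g] <- TRUE
        asg[p] <- g
        recurse(p + 1L, used, score + iou[p, g], cnt + 1L, asg)
        used[g] <- FALSE
      }
    }
    asg[p] <- NA_integer_
    recurse(p + 1L, used, score, cnt, asg)
  }
  recurse(1L, rep(FALSE, n), 0, 0L, rep(NA_integer_, m))
  best_asg
}

assign_greedy <- function(iou) {
  m <- nrow(iou); n <- ncol(iou)
  asg <- rep(NA_integer_, m)
  pairs <- which(!is.na(iou), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(asg)
  ord <- order(-iou[pairs], pairs[, 1], pairs[, 2])
  used_p <- rep(FALSE, m); used_g <- rep(FALSE, n)
  for (k in ord) {
    p <- pairs[k, 1]; g <- pairs[k, 2]
    if (!used_p[p] && !used_g[g]) {
      asg[p] <- g; used_p[p] <- TRUE; used_g[g] <- TRUE
    }
  }
  asg
}

#' Match predicted ROIs to ground-truth ROIs
#'
#' Predictions with `score <= score_thr` are discarded.  Within each
#' (patient, view), surviving predictions are assigned one-to-one to
#' ground truths by the exact maximum-total-IoU assignment over pairs
#' with `IoU > iou_thr`.  A matched pair is a *correct detection* iff the
#' prediction's probability for the ground truth's benign/malignant class
#' exceeds `class_prob_thr`.  Unmatched predictions are falsely detected
#' ROIs.
#'
#' @param preds Tibble with `patient_id`, `view`, `roi_id`, `label4`,
#'   `score`, `mask` and optionally `p_ben`/`p_mal` (otherwise derived
#'   with [dl_score_to_binomial()]).
#' @param gts Tibble with `patient_id`, `view`, `roi_id`, `label2`,
#'   `mask` (and optionally `lesion_type`).
#' @param iou_thr,score_thr,class_prob_thr Strict thresholds (defaults
#'   0.1, 0.1, 0.5).
#' @return A `match_result`: tibbles `matched` (with `iou`, `gt_class`,
#'   `pred_class`, `correct`), `unmatched_preds`, `unmatched_gts`, and the
#'   surviving `preds`.
#' @export
match_rois <- function(preds, gts, iou_thr = 0.1, score_thr = 0.1,
                       class_prob_thr = 0.5) {
  if (!all(c("p_ben", "p_mal") %in% names(preds))) {
    preds <- dplyr::bind_cols(preds,
                              dl_score_to_binomial(preds$label4, preds$score))
  }
  preds <- dplyr::filter(preds, .data$score > score_thr)
  preds$pred_class <- ifelse(preds$p_mal >= 0.5, "malignant", "benign")
  scopes <- dplyr::distinct(dplyr::bind_rows(
    dplyr::select(preds, "patient_id", "view"),
    dplyr::select(gts, "patient_id", "view")))
  matched <- list(); un_p <- list(); un_g <- list()
  for (s in seq_len(nrow(scopes))) {
    p <- dplyr::filter(preds, .data$patient_id == scopes$patient_id[s],
                       .data$view == scopes$view[s])
    g <- dplyr::filter(gts, .data$patient_id == scopes$patient_id[s],
                       .data$view == scopes$view[s])
    if (nrow(p) == 0L && nrow(g) == 0L) next
    iou <- matrix(0, nrow(p), nrow(g))
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(g))) {
        iou[i, j] <- compute_iou(p$mask[[i]], g$mask[[j]])
      }
    }
    asg <- assign_pairs(iou, iou_thr)
    hit <- which(!is.na(asg))
    if (length(hit)) {
      gt_cls <- g$label2[asg[hit]]
      prob_true <- ifelse(gt_cls == "malignant", p$p_mal[hit], p$p_ben[hit])
      matched[[length(matched) + 1L]] <- tibble::tibble(
        patient_id = scopes$patient_id[s], view = scopes$view[s],
        pred_id = p$roi_id[hit], gt_id = g$roi_id[asg[hit]],
        iou = iou[cbind(hit, asg[hit])],
        gt_class = gt_cls, pred_class = p$pred_class[hit],
        p_mal = p$p_mal[hit],
        correct = prob_true > class_prob_thr)
    }
    if (length(hit) < nrow(p)) {
      un_p[[length(un_p) + 1L]] <- p[setdiff(seq_len(nrow(p)), hit), ]
    }
    ghit <- asg[hit]
    if (length(ghit) < nrow(g)) {
      un_g[[length(un_g) + 1L]] <- g[setdiff(seq_len(nrow(g)), ghit), ]
    }
  }
  empty_m <- tibble::tibble(patient_id = character(), view = character(),
                            pred_id = integer(), gt_id = integer(),
                            iou = numeric(), gt_class = character(),
                            pred_class = character(), p_mal = numeric(),
                            correct = logical())
  structure(list(
    matched = if (length(matched)) dplyr::bind_rows(matched) else empty_m,
    unmatched_preds = if (length(un_p)) dplyr::bind_rows(un_p) else preds[0, ],
    unmatched_gts = if (length(un_g)) dplyr::bind_rows(un_g) else gts[0, ],
    preds = preds, gts = gts,
    thresholds = c(iou = iou_thr, score = score_thr, class = class_prob_thr)),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched (%d correct), %d false ROIs, %d missed GTs\n",
              nrow(x$matched), sum(x$matched$correct),
              nrow(x$unmatched_preds), nrow(x$unmatched_gts)))
  invisible(x)
}

#' Detection sensitivity and precision
#'
#' Sensitivity = correct detections / all true ROIs; precision = correct
#' detections / all predicted ROIs (correct + non-overlapping + wrongly
#' classified).  With a class restriction, sensitivity counts ground
#' truths of that class and precision counts predictions whose predicted
#' class is that class.  With no surviving predictions, precision is
#' undefined (`NA`) while sensitivity is still computed.
#'
#' @param match A `match_result`.
#' @param restrict_class Optional `"benign"`/`"malignant"`.
#' @param restrict_type Optional `"mass"`/`"cluster"` (requires
#'   `lesion_type` on the ground-truth table).
#' @return One-row tibble: `sensitivity`, `precision`, `n_gt`, `n_pred`,
#'   `n_correct`.
#' @export
detection_metrics <- function(match, restrict_class = NULL,
                              restrict_type = NULL) {
  stopifnot(inherits(match, "match_result"))
  gts <- match$gts
  m <- match$matched
  preds <- match$preds
  if (!is.null(restrict_type)) {
    gts <- dplyr::filter(gts, .data$lesion_type == restrict_type)
    m <- dplyr::semi_join(m, gts, by = c("patient_id", "view",
                                         "gt_id" = "roi_id"))
  }
  if (!is.null(restrict_class)) {
    gts <- dplyr::filter(gts, .data$label2 == restrict_class)
    m <- dplyr::filter(m, .data$gt_class == restrict_class)
    preds <- dplyr::filter(preds, .data$pred_class == restrict_class)
  }
  n_gt <- nrow(gts)
  n_pred <- nrow(preds)
  n_correct <- sum(m$correct)
  tibble::tibble(
    sensitivity = if (n_gt > 0) n_correct / n_gt else NA_real_,
    precision = if (n_pred > 0) n_correct / n_pred else NA_real_,
    n_gt = n_gt, n_pred = n_pred, n_correct = n_correct)
}

#' ROC-AUC of benign/malignant classification over predicted ROIs
#'
#' Every surviving predicted ROI enters the ROC: the reference label is
#' the overlapped ground truth's class for matched ROIs and benign for
#' unmatched ROIs (a model is penalized more for hallucinating malignancy
#' than benignity); the score is the malignant probability.  AUC by the
#' rank statistic with midranks for ties; `NA` when only one reference
#' class is present.
#'
#' @param match A `match_result`.
#' @return Scalar AUC (or `NA`).
#' @export
classification_auc <- function(match) {
  stopifnot(inherits(match, "match_result"))
  ref <- c(match$matched$gt_class,
           rep("benign", nrow(match$unmatched_preds)))
  score <- c(match$matched$p_mal, match$unmatched_preds$p_mal)
  auc_rank(score, ref == "malignant")
}

# Rank-statistic AUC with midranks.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level bootstrap confidence interval
#'
#' Resamples patients with replacement (as many as in the original set),
#' recomputes the metric on each resample and returns the percentile
#' interval.  Resamples on which the metric is undefined (`NA`) are
#' redrawn and logged.
#'
#' @param metric_fn Function `records -> scalar`.
#' @param records Tibble with a `patient_id` column.
#' @param n_boot Number of resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; fixed seed gives a bit-identical interval.
#' @return One-row tibble: `point`, `lo`, `hi`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, records, n_boot = 2000L, level = 0.95,
                         seed = 1L) {
  patients <- unique(records$patient_id)
  if (length(patients) < 1L) abort("need at least one patient")
  point <- metric_fn(records)
  by_patient <- split(seq_len(nrow(records)), records$patient_id)
  stats_out <- numeric(n_boot)
  n_redrawn <- 0L
  withr::with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(n_boot)) {
      repeat {
        take <- sample(patients, length(patients), replace = TRUE)
        rows <- unlist(by_patient[take], use.names = FALSE)
        v <- metric_fn(records[rows, , drop = FALSE])
        if (!is.na(v)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10L * n_boot) {
          abort("metric undefined on too many bootstrap resamples")
        }
      }
      stats_out[b] <- v
    }
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(stats_out, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(point = point, lo = ci[1], hi = ci[2],
                 n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Paired bootstrap CI of a metric difference between two setups
#'
#' Both setups must be evaluated on the same patient set; each bootstrap
#' resample of patients is applied to both, and the difference
#' `metric(A) - metric(B)` is accumulated.
#'
#' @param metric_fn Function `records -> scalar`.
#' @param records_a,records_b Tibbles with a `patient_id` column covering
#'   the same patients.
#' @inheritParams bootstrap_ci
#' @return One-row tibble: `mean_diff` (point difference on the full
#'   data), `lo`, `hi`.
#' @export
metric_difference_ci <- function(metric_fn, records_a, records_b,
                                 n_boot = 2000L, level = 0.95, seed = 1L) {
  patients <- union(records_a$patient_id, records_b$patient_id)
  idx_a <- split(seq_len(nrow(records_a)), records_a$patient_id)
  idx_b <- split(seq_len(nrow(records_b)), records_b$patient_id)
  diffs <- numeric(n_boot)
  withr::with_seed(derive_seed(seed, "bootstrap_diff"), {
    for (b in seq_len(n_boot)) {
      take <- sample(patients, length(patients), replace = TRUE)
      ra <- records_a[unlist(idx_a[take], use.names = FALSE), , drop = FALSE]
      rb <- records_b[unlist(idx_b[take], use.names = FALSE), , drop = FALSE]
      diffs[b] <- metric_fn(ra) - metric_fn(rb)
    }
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(mean_diff = metric_fn(records_a) - metric_fn(records_b),
                 lo = ci[1], hi = ci[2])
}

#' Full ROI-level metrics report with bootstrap CIs
#'
#' Convenience wrapper: matches predictions to ground truths, computes
#' sensitivity, precision and AUC overall (and per class), and attaches
#' patient-level bootstrap CIs.
#'
#' @inheritParams match_rois
#' @inheritParams bootstrap_ci
#' @return Tibble with one row per (subset, metric):
#'   `subset`, `metric`, `value`, `lo`, `hi`.
#' @export
evaluate_rois <- function(preds, gts, iou_thr = 0.1, score_thr = 0.1,
                          class_prob_thr = 0.5, n_boot = 2000L,
                          level = 0.95, seed = 1L) {
  # Matching is scoped per (patient, view), so it is done once; bootstrap
  # resampling of patients then only re-aggregates per-patient records.
  mm <- match_rois(preds, gts, iou_thr, score_thr, class_prob_thr)
  counts <- patient_counts(mm)
  auc_rec <- dplyr::bind_rows(
    dplyr::transmute(mm$matched, patient_id = .data$patient_id,
                     positive = .data$gt_class == "malignant",
                     p_mal = .data$p_mal),
    if (nrow(mm$unmatched_preds))
      dplyr::transmute(mm$unmatched_preds, patient_id = .data$patient_id,
                       positive = FALSE, p_mal = .data$p_mal))
  ratio <- function(num, den) {
    function(rec) {
      d <- sum(rec[[den]])
      if (d == 0) NA_real_ else sum(rec[[num]]) / d
    }
  }
  rows <- list()
  for (sub in c("all", "benign", "malignant")) {
    sfx <- if (sub == "all") "" else paste0("_", sub)
    for (met in c("sensitivity", "precision")) {
      den <- if (met == "sensitivity") paste0("n_gt", sfx) else
        paste0("n_pred", sfx)
      ci <- bootstrap_ci(ratio(paste0("n_correct", sfx), den), counts,
                         n_boot = n_boot, level = level, seed = seed)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset = sub, metric = met, value = ci$point, lo = ci$lo, hi = ci$hi)
    }
  }
  auc_fn <- function(rec) auc_rank(rec$p_mal, rec$positive)
  ci <- if (nrow(auc_rec)) {
    bootstrap_ci(auc_fn, auc_rec, n_boot = n_boot, level = level, seed = seed)
  } else {
    tibble::tibble(point = NA_real_, lo = NA_real_, hi = NA_real_)
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    subset = "all", metric = "auc", value = ci$point, lo = ci$lo, hi = ci$hi)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metrics_report", class(out))
  out
}

# Per-patient correct-detection / GT / prediction counts, overall and per
# benign/malignant class.
patient_counts <- function(mm) {
  pats <- unique(c(mm$gts$patient_id, mm$preds$patient_id))
  purrr::map_dfr(pats, function(p) {
    g <- dplyr::filter(mm$gts, .data$patient_id == p)
    pr <- dplyr::filter(mm$preds, .data$patient_id == p)
    m <- dplyr::filter(mm$matched, .data$patient_id == p)
    tibble::tibble(
      patient_id = p,
      n_gt = nrow(g), n_pred = nrow(pr), n_correct = sum(m$correct),
      n_gt_benign = sum(g$label2 == "benign"),
      n_pred_benign = sum(pr$pred_class == "benign"),
      n_correct_benign = sum(m$correct & m$gt_class == "benign"),
      n_gt_malignant = sum(g$label2 == "malignant"),
      n_pred_malignant = sum(pr$pred_class == "malignant"),
      n_correct_malignant = sum(m$correct & m$gt_class == "malignant"))
  })
}

#' @rdname evaluate_rois
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$metric, y = .data$value,
                               colour = .data$subset)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "value (95% bootstrap CI)", x = NULL) +
    ggplot2::theme_minimal()
}
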