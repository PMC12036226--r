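test_that("label binarization covers the four classes", {
  l4 <- c("benign_mass", "benign_cluster", "malignant_mass",
          "malignant_cluster")
  out <- binarize_label(l4)
  expect_equal(out, c("benign", "benign", "malignant", "malignant"))
  expect_equal(sum(out == "benign"), 2)
  expect_error(binarize_label("weird"), "invalid")
})

test_that("DL score binomialization follows the printed mapping", {
  expect_equal(dl_score_to_binomial("benign_mass", 0),
               tibble::tibble(p_ben = 0.5, p_mal = 0.5))
  expect_equal(dl_score_to_binomial("malignant_mass", 1)$p_mal, 1)
  expect_equal(dl_score_to_binomial("benign_cluster", 0.6)$p_ben, 0.8)
  s <- seq(0, 1, by = 0.01)
  for (lab in c("benign_mass", "malignant_cluster")) {
    p <- dl_score_to_binomial(rep(lab, length(s)), s)
    expect_equal(p$p_ben + p$p_mal, rep(1, length(s)))
    pred <- if (startsWith(lab, "benign")) p$p_ben else p$p_mal
    expect_equal(pred, 0.5 * s + 0.5)
    expect_true(all(pred >= 0.5))
  }
  expect_error(dl_score_to_binomial("benign_mass", 1.2), "0, 1")
})

test_that("ensembling averages probabilities and can overrule a class", {
  dl <- tibble::tibble(p_ben = 0.8, p_mal = 0.2)
  hr <- tibble::tibble(p_ben = 0.4, p_mal = 0.6)
  expect_equal(ensemble_probs(dl, hr), tibble::tibble(p_ben = 0.6, p_mal = 0.4))
  expect_equal(ensemble_probs(dl, dl), dl)
  flip <- ensemble_probs(tibble::tibble(p_ben = 0.55, p_mal = 0.45),
                         tibble::tibble(p_ben = 0.1, p_mal = 0.9))
  expect_equal(flip$p_mal, 0.675)
  expect_gt(flip$p_mal, 0.5)   # confident radiomics overrules the DL class
  expect_error(ensemble_probs(dl, tibble::tibble(p_ben = 0.5, p_mal = 0.6)),
               "sum to 1")
})

test_that("IoU is intersection over union with an empty-union convention", {
  a <- roi_mask(disc_mat(c(40, 40), c(20, 20), 6))
  expect_equal(compute_iou(a, a), 1)
  b <- roi_mask(disc_mat(c(40, 40), c(8, 8), 3))
  expect_equal(compute_iou(a, b), 0)
  m1 <- matrix(FALSE, 20, 20); m1[1:10, 1:10] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[6:15, 1:10] <- TRUE
  expect_equal(compute_iou(m1, m2), 50 / 150)
  expect_equal(compute_iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 0)
})

test_that("score and IoU thresholds gate matching as specified", {
  frame <- c(64L, 64L)
  gts <- tibble::tibble(patient_id = "P1", view = "CC", roi_id = 1L,
                        label2 = "malignant", lesion_type = "cluster",
                        mask = list(roi_mask_disc(frame, c(30, 30), 8)))
  lowscore <- tibble::tibble(patient_id = "P1", view = "CC", roi_id = 1L,
                             label4 = "malignant_cluster", score = 0.05,
                             mask = list(roi_mask_disc(frame, c(30, 30), 8)))
  m <- match_rois(lowscore, gts)
  expect_equal(nrow(m$matched), 0)
  expect_equal(nrow(m$preds), 0)      # excluded entirely
  expect_equal(nrow(m$unmatched_gts), 1)

  grazing <- tibble::tibble(patient_id = "P1", view = "CC", roi_id = 1L,
                            label4 = "malignant_cluster", score = 0.9,
                            mask = list(roi_mask_disc(frame, c(48, 48), 8)))
  m2 <- match_rois(grazing, gts)     # IoU ~ 0 < 0.1: false positive
  expect_equal(nrow(m2$matched), 0)
  expect_equal(nrow(m2$unmatched_preds), 1)
})

test_that("matching equals the exhaustive assignment oracle", {
  for (seed in 1:120) {
    inst <- random_instance(seed)
    preds <- dplyr::select(inst$preds, -"label2")
    gts <- dplyr::select(inst$gts, -"label4", -"score")
    gts$lesion_type <- "mass"
    m <- match_rois(preds, gts, iou_thr = 0.1, score_thr = 0.1)
    kept <- dplyr::filter(preds, score > 0.1)
    iou <- matrix(0, nrow(kept), nrow(gts))
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(gts))) {
      iou[i, j] <- compute_iou(kept$mask[[i]], gts$mask[[j]])
    }
    oracle <- oracle_assignment(iou, 0.1)
    got <- rep(NA_integer_, nrow(kept))
    if (nrow(m$matched)) {
      got[match(m$matched$pred_id, kept$roi_id)] <-
        match(m$matched$gt_id, gts$roi_id)
    }
    expect_identical(got, oracle)
    # one-to-one
    expect_false(anyDuplicated(m$matched$gt_id) > 0)
    expect_false(anyDuplicated(m$matched$pred_id) > 0)
  }
})

test_that("planted toy annotations reproduce hand-computed metrics", {
  toy <- generate_toy_annotations(20, list(miss = 0.3, flip = 0,
                                           fp_per_patient = 0.5), seed = 8)
  m <- match_rois(toy$preds, toy$gts)
  met <- detection_metrics(m)
  n_gt <- toy$log$n_gt
  n_det <- n_gt - toy$log$n_missed
  expect_equal(met$n_gt, n_gt)
  expect_equal(met$n_correct, n_det)           # no flips: all matches correct
  expect_equal(met$sensitivity, n_det / n_gt)
  expect_equal(met$precision, n_det / (n_det + toy$log$n_spurious))

  # perfect predictor
  perfect <- generate_toy_annotations(10, seed = 9)
  mp <- match_rois(perfect$preds, perfect$gts)
  metp <- detection_metrics(mp)
  expect_equal(metp$sensitivity, 1)
  expect_equal(metp$precision, 1)
  expect_equal(classification_auc(mp), 1)

  # total miss
  none <- generate_toy_annotations(10, list(miss = 1), seed = 10)
  mn <- match_rois(none$preds, none$gts)
  metn <- detection_metrics(mn)
  expect_equal(metn$sensitivity, 0)
  expect_true(is.na(metn$precision))           # undefined without predictions
})

test_that("label flips are wrong detections and lower the AUC reference", {
  toy <- generate_toy_annotations(25, list(flip = 0.4), seed = 12)
  m <- match_rois(toy$preds, toy$gts)
  met <- detection_metrics(m)
  expect_equal(met$n_correct, met$n_gt - toy$log$n_flipped)
  expect_equal(met$sensitivity, 1 - toy$log$n_flipped / met$n_gt)
})

test_that("AUC equals the pairwise concordance oracle and is rank-invariant", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(5:25, 1)
      pos <- runif(n) < 0.5
      if (length(unique(pos)) < 2) next
      sc <- round(runif(n), 2)     # rounded: force some ties
      expect_equal(cemsim:::auc_rank(sc, pos), oracle_auc(sc, pos))
      expect_equal(cemsim:::auc_rank(qlogis((sc + 0.5) / 2), pos),
                   cemsim:::auc_rank(sc, pos))  # monotone transform
    }
  })
  expect_equal(cemsim:::auc_rank(c(1, 1, 1), c(TRUE, FALSE, TRUE)), 0.5)
  expect_true(is.na(cemsim:::auc_rank(c(1, 2), c(TRUE, TRUE))))
})

test_that("unmatched predictions are referenced benign in the ROC", {
  frame <- c(64L, 64L)
  gts <- tibble::tibble(patient_id = "P1", view = "CC", roi_id = 1L,
                        label2 = "malignant", lesion_type = "cluster",
                        mask = list(roi_mask_disc(frame, c(30, 30), 8)))
  preds <- tibble::tibble(
    patient_id = "P1", view = "CC", roi_id = 1:2,
    label4 = c("malignant_cluster", "malignant_mass"),
    score = c(0.9, 0.8),
    mask = list(roi_mask_disc(frame, c(30, 30), 8),
                roi_mask_disc(frame, c(10, 52), 5)))
  m <- match_rois(preds, gts)
  # matched ROI: reference malignant, p_mal 0.95; unmatched: benign, 0.9
  expect_equal(classification_auc(m), 1)
})

test_that("patient bootstrap is reproducible with sane degenerate behaviour", {
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                        value = rep(0.7, 30))
  fn <- function(d) mean(d$value)
  ci <- bootstrap_ci(fn, rec, n_boot = 200, seed = 5)
  expect_equal(ci$lo, 0.7)
  expect_equal(ci$hi, 0.7)
  rec$value <- runif(30)
  ci1 <- bootstrap_ci(fn, rec, n_boot = 500, seed = 9)
  ci2 <- bootstrap_ci(fn, rec, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lo, ci1$point)
  expect_gte(ci1$hi, ci1$point)
  # undefined resamples are redrawn
  rec2 <- rec; rec2$value[1] <- NA
  fn2 <- function(d) if (anyNA(d$value)) NA_real_ else mean(d$value)
  ci3 <- bootstrap_ci(fn2, rec2, n_boot = 100, seed = 2)
  expect_gt(ci3$n_redrawn, 0)
  expect_false(is.na(ci3$lo))
})

test_that("paired metric differences are centred and antisymmetric", {
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:40),
                        value = runif(40))
  fn <- function(d) mean(d$value)
  same <- metric_difference_ci(fn, rec, rec, n_boot = 300, seed = 1)
  expect_equal(same$mean_diff, 0)
  expect_lte(same$lo, 0); expect_gte(same$hi, 0)
  shifted <- dplyr::mutate(rec, value = value + 0.1)
  up <- metric_difference_ci(fn, shifted, rec, n_boot = 300, seed = 1)
  dn <- metric_difference_ci(fn, rec, shifted, n_boot = 300, seed = 1)
  expect_equal(up$mean_diff, 0.1)
  expect_equal(dn$mean_diff, -up$mean_diff)
  expect_gt(up$lo, 0)   # planted uniform improvement excludes zero
})

test_that("evaluate_rois reports coherent CIs on a noisy toy set", {
  toy <- generate_toy_annotations(15, list(miss = 0.2, flip = 0.2,
                                           fp_per_patient = 0.5), seed = 21)
  rep <- evaluate_rois(toy$preds, toy$gts, n_boot = 200, seed = 3)
  expect_s3_class(rep, "metrics_report")
  vals <- rep[!is.na(rep$value), ]
  expect_true(all(vals$value >= 0 & vals$value <= 1))
  expect_true(all(vals$lo <= vals$value + 1e-12))
  expect_true(all(vals$hi >= vals$value - 1e-12))
})
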