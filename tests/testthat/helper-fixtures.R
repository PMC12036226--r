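# Shared test fixtures, computed lazily and cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# One default fixture pair reused across unit tests.
test_pair <- function(seed = 7) {
  cached(paste0("pair", seed), generate_background_pair(fixture_spec(seed = seed)))
}

# Rasterized disc mask (logical matrix).
disc_mat <- function(frame, center, radius) {
  rr <- matrix(seq_len(frame[1]), frame[1], frame[2])
  cc <- matrix(seq_len(frame[2]), frame[1], frame[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Batch of seeded simulations shared by several acceptance checks.
# Fixtures are reused across the two classes of a seed.
acceptance_sims <- function(seeds = 1:50) {
  cached("acc_sims", {
    dists <- default_enhancement_distributions(n = 50, seed = 101)
    cfg <- simulation_config(enhancement_dists = dists)
    out <- list()
    for (s in seeds) {
      pair <- generate_background_pair(fixture_spec(seed = s))
      for (cl in c("benign", "malignant")) {
        res <- tryCatch(simulate_case(pair, cl, cfg, seed = s),
                        cemsim_infeasible_cluster = function(e) NULL)
        out[[paste(cl, s, sep = "_")]] <- res
      }
    }
    out
  })
}

# Independent Chebyshev distance transform by brute force (small frames):
# k iterations of 3x3-box dilation reach exactly the pixels with
# chessboard distance <= k from the seed set.
chebyshev_dist <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pts))) {
    dr <- abs(matrix(seq_len(nr), nr, nc) - pts[i, 1])
    dc <- abs(matrix(seq_len(nc), nr, nc, byrow = TRUE) - pts[i, 2])
    d <- pmin(d, pmax(dr, dc))
  }
  d
}

# Exhaustive one-to-one assignment oracle: enumerate all injective
# pred -> gt mappings over pairs with IoU > thr, maximizing total IoU
# (ties: more pairs, then lexicographically smallest gt choice).
oracle_assignment <- function(iou, thr) {
  m <- nrow(iou); n <- ncol(iou)
  best <- list(score = -1, cnt = -1L, asg = rep(NA_integer_, m))
  opts <- lapply(seq_len(m), function(p) c(NA_integer_, which(iou[p, ] > thr)))
  grid <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(m)), drop = FALSE]  # column p = choice for pred p
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(unlist(grid[r, ]))
    g <- asg[!is.na(asg)]
    if (anyDuplicated(g)) next
    sc <- sum(iou[cbind(which(!is.na(asg)), g)])
    cnt <- length(g)
    better <- sc > best$score + 1e-12 ||
      (abs(sc - best$score) <= 1e-12 &&
         (cnt > best$cnt ||
            (cnt == best$cnt && !is.na(lex_less(asg, best$asg)) &&
               lex_less(asg, best$asg))))
    if (better) best <- list(score = sc, cnt = cnt, asg = asg)
  }
  best$asg
}

lex_less <- function(a, b) {
  a[is.na(a)] <- .Machine$integer.max
  b[is.na(b)] <- .Machine$integer.max
  i <- which(a != b)[1]
  if (is.na(i)) return(FALSE)
  a[i] < b[i]
}

# Pairwise-concordance AUC oracle.
oracle_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Random toy ROI tables on a small frame for matching property tests.
random_instance <- function(seed, frame = c(48L, 48L), max_n = 5L) {
  withr::with_seed(seed, {
    n_p <- sample(0:max_n, 1L); n_g <- sample(1:max_n, 1L)
    mk <- function(n, prefix) {
      if (n == 0L) {
        return(tibble::tibble(patient_id = character(), view = character(),
                              roi_id = integer(), label4 = character(),
                              label2 = character(), score = numeric(),
                              mask = list()))
      }
      tibble::tibble(
        patient_id = "P1", view = "CC", roi_id = seq_len(n),
        label4 = sample(c("benign_mass", "malignant_cluster"), n, TRUE),
        label2 = sample(c("benign", "malignant"), n, TRUE),
        score = stats::runif(n, 0.2, 1),
        mask = lapply(seq_len(n), function(i)
          roi_mask_disc(frame, c(stats::runif(1, 10, 38),
                                 stats::runif(1, 10, 38)),
                        stats::runif(1, 4, 10))))
    }
    list(preds = mk(n_p, "p"), gts = mk(n_g, "g"))
  })
}
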