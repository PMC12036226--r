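# Deterministic synthetic fixtures: breast-like CEM image pairs and toy
# prediction/ground-truth sets.  These stand in for clinical data so every
# pipeline stage is testable; they emulate the statistical structure the
# pipeline relies on (lumpy dense-tissue texture, bright curvilinear
# structures for the vesselness filter, a flat recombined background with
# enhancement ratio ~1.0), not X-ray physics.

#' Fixture generation parameters
#'
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param spacing_mm Pixel pitch in mm.
#' @param view Mammographic view of the generated pair.
#' @param background_level Mean glandular-tissue intensity (DN) of the
#'   low-energy breast interior.
#' @param outside_level Intensity outside the breast (DN).
#' @param lump_density Clustered-lumpy-background blob density per mm^2.
#' @param lump_radius_mm Gaussian blob sigma in mm.
#' @param lump_amplitude Peak blob amplitude (DN).
#' @param n_curvilinear Number of bright curvilinear structures (vessel /
#'   duct surrogates the Frangi filter responds to).
#' @param curv_width_px Cross-section sigma of curvilinear structures (px).
#' @param curv_intensity Peak ridge intensity above background (DN).
#' @param bead_rate Per-step probability of depositing a bright nodular
#'   spot ("bead") along a curvilinear walk; dense tissue shows such
#'   compact opacities strung along ducts and vessels, and they give the
#'   candidate extractor round regions to work with.
#' @param bead_intensity Peak bead intensity above background (DN).
#' @param bead_sigma Range of bead Gaussian sigmas (px).
#' @param noise_sigma Additive Gaussian noise sigma of the low-energy
#'   image (DN).
#' @param recombined_level Recombined-image breast plateau (DN).
#' @param recombined_noise Recombined-image noise sigma (DN).
#' @param seed Integer seed; fixes the whole fixture deterministically.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(shape = c(800L, 640L), spacing_mm = 0.1,
                         view = c("CC", "MLO"),
                         background_level = 12000, outside_level = 50,
                         lump_density = 0.6, lump_radius_mm = 0.7,
                         lump_amplitude = 1500,
                         n_curvilinear = 30, curv_width_px = 1.2,
                         curv_intensity = 4800,
                         bead_rate = 0.95, bead_intensity = 6500,
                         bead_sigma = c(1.2, 1.8),
                         noise_sigma = 260,
                         recombined_level = 2000, recombined_noise = 20,
                         seed = 1L) {
  view <- match.arg(view)
  spec <- list(shape = as.integer(shape), spacing_mm = spacing_mm,
               view = view,
               background_level = background_level,
               outside_level = outside_level,
               lump_density = lump_density, lump_radius_mm = lump_radius_mm,
               lump_amplitude = lump_amplitude,
               n_curvilinear = n_curvilinear, curv_width_px = curv_width_px,
               curv_intensity = curv_intensity,
               bead_rate = bead_rate, bead_intensity = bead_intensity,
               bead_sigma = bead_sigma, noise_sigma = noise_sigma,
               recombined_level = recombined_level,
               recombined_noise = recombined_noise,
               seed = as.integer(seed))
  num <- spec[!(names(spec) %in% c("view", "shape"))]
  if (any(vapply(num, function(x) !is.numeric(x) || any(x < 0), logical(1)))) {
    abort("fixture parameters must be nonnegative numbers")
  }
  structure(spec, class = "fixture_spec")
}

# Half-ellipse breast support attached to the left image border (the
# breast projects wider than deep in a CC view).
breast_support <- function(shape) {
  rows <- shape[1]; cols <- shape[2]
  ra <- 0.94 * rows / 2
  rb <- 0.94 * cols
  if (min(ra, rb) < 32) abort("image shape too small for a breast half-ellipse")
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (rr - rows / 2)^2 / ra^2 + cc^2 / rb^2 <= 1
}

#' Generate a synthetic low-energy / recombined image pair
#'
#' Low-energy image: clustered lumpy texture (superposed Gaussian blobs, a
#' standard mammographic texture surrogate) plus bright smoothed
#' random-walk polylines (curvilinear structures) plus Gaussian noise,
#' inside a half-disc breast on a near-zero background.  Recombined image:
#' a flat low-contrast plateau over the same breast support with mild
#' noise, i.e. no enhancement anywhere (measured enhancement ratio ~1.0).
#'
#' @param spec A [fixture_spec()].
#' @return A [case_pair()] with integer-valued 16-bit-range pixels, fully
#'   determined by `spec$seed`.
#' @export
generate_background_pair <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  breast <- breast_support(spec$shape)
  withr::with_seed(spec$seed, {
    le <- matrix(spec$outside_level, rows, cols)
    le[breast] <- spec$background_level

    # clustered lumpy texture
    area_mm2 <- sum(breast) * spec$spacing_mm^2
    n_lumps <- round(spec$lump_density * area_mm2)
    if (n_lumps > 0 && spec$lump_amplitude > 0) {
      sigma <- max(spec$lump_radius_mm / spec$spacing_mm, 0.5)
      inside <- which(breast)
      at <- sample(inside, n_lumps, replace = TRUE)
      imp <- matrix(0, rows, cols)
      amp <- stats::runif(n_lumps, 0.4, 1) * spec$lump_amplitude
      imp[at] <- imp[at] + amp * 2 * pi * sigma^2
      lumps <- conv2_zero(imp, gauss_kernel2(sigma, ceiling(4 * sigma)))
      le <- le + lumps * breast
    }

    # bright curvilinear structures: smoothed random walks
    if (spec$n_curvilinear > 0 && spec$curv_intensity > 0) {
      imp <- matrix(0, rows, cols)
      beads <- matrix(0, rows, cols)
      inside <- which(breast)
      for (k in seq_len(spec$n_curvilinear)) {
        # ducts fan out from the nipple region into the breast
        start <- c(round(rows / 2 + stats::runif(1, -0.18, 0.18) * rows),
                   round(stats::runif(1, 0.05, 0.25) * cols))
        if (!breast[start[1], start[2]]) {
          start <- arrayInd(sample(inside, 1L), dim(breast))
        }
        theta <- stats::runif(1, -pi / 4, pi / 4)  # heading into the breast
        len <- sample(150:400, 1L)
        r <- start[1]; c <- start[2]
        since_bead <- 10L  # beads are spaced, not contiguous
        lum <- 0           # AR(1) log-brightness modulation along the duct
        for (s in seq_len(len)) {
          theta <- theta + stats::rnorm(1, 0, 0.10)
          lum <- 0.92 * lum + stats::rnorm(1, 0, 0.14)
          r <- r + sin(theta); c <- c + cos(theta)
          ri <- round(r); ci <- round(c)
          if (ri < 1 || ri > rows || ci < 1 || ci > cols || !breast[ri, ci]) break
          # duct stays dimmer right around a bead so the bead reads as its
          # own compact opacity
          damp <- if (since_bead < 4L) 0.35 else 1
          imp[ri, ci] <- spec$curv_intensity * exp(lum) * damp
          # compact nodular opacities strung along the structure
          since_bead <- since_bead + 1L
          if (spec$bead_rate > 0 && since_bead >= 10L &&
              stats::runif(1) < spec$bead_rate) {
            since_bead <- 0L
            # mildly elongated along the walk direction, as beading along
            # a duct appears; set off the duct axis so the spot reads as
            # its own compact opacity rather than a ridge thickening
            bs <- stats::runif(1, spec$bead_sigma[1], spec$bead_sigma[2])
            amp <- stats::runif(1, 0.6, 1) * spec$bead_intensity
            rad <- ceiling(5 * bs)
            rr2 <- max(1, ri - rad):min(rows, ri + rad)
            cc2 <- max(1, ci - rad):min(cols, ci + rad)
            dr <- matrix(rr2 - ri, length(rr2), length(cc2))
            dc <- matrix(cc2 - ci, length(rr2), length(cc2), byrow = TRUE)
            dpar <- sin(theta) * dr + cos(theta) * dc
            dperp <- cos(theta) * dr - sin(theta) * dc
            bump <- amp * exp(-(dpar^2 / (2 * (2.2 * bs)^2) +
                                  dperp^2 / (2 * bs^2)))
            beads[rr2, cc2] <- pmax(beads[rr2, cc2], bump)
          }
        }
      }
      sig <- spec$curv_width_px
      ridge <- conv2_zero(imp, gauss_kernel2(sig, ceiling(4 * sig))) *
        sqrt(2 * pi) * sig
      le <- le + (ridge + beads) * breast
    }

    if (spec$noise_sigma > 0) {
      le <- le + matrix(stats::rnorm(rows * cols, 0, spec$noise_sigma),
                        rows, cols) * breast
    }
    le <- round(pmin(pmax(le, 0), 65535))

    rc <- matrix(0, rows, cols)
    rc[breast] <- spec$recombined_level
    if (spec$recombined_noise > 0) {
      rc <- rc + matrix(stats::rnorm(rows * cols, 0, spec$recombined_noise),
                        rows, cols) * breast
    }
    rc <- round(pmin(pmax(rc, 0), 65535))

    case_pair(
      gray_image(le, spec$spacing_mm, spec$view, "low_energy"),
      gray_image(rc, spec$spacing_mm, spec$view, "recombined"),
      patient_id = sprintf("fixture%04d", spec$seed)
    )
  })
}

#' Generate toy prediction/ground-truth ROI sets with planted error rates
#'
#' Ground-truth ROIs are discs with known 4-class labels; predictions are
#' derived from them by jittering masks (keeping IoU high), dropping ground
#' truths (misses), adding spurious non-overlapping ROIs (false positives)
#' and flipping benign/malignant labels, each at a stated rate.  The
#' generation log retains the planted counts so evaluation metrics can be
#' checked against hand-computed values.
#'
#' @param n_patients Number of patients (two views each).
#' @param error_rates List with elements `miss`, `flip` (probabilities) and
#'   `fp_per_patient` (expected spurious ROIs per patient).
#' @param frame Mask frame `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A list of class `toy_annotations` with tibbles `gts`, `preds`
#'   and a `log` of planted counts.
#' @export
generate_toy_annotations <- function(n_patients,
                                     error_rates = list(miss = 0, flip = 0,
                                                        fp_per_patient = 0),
                                     frame = c(128L, 128L), seed = 1L) {
  miss <- error_rates$miss %||% 0
  flip <- error_rates$flip %||% 0
  fp <- error_rates$fp_per_patient %||% 0
  if (any(c(miss, flip) < 0) || any(c(miss, flip) > 1) || fp < 0) {
    abort("error rates must be probabilities (fp_per_patient >= 0)")
  }
  classes <- c("benign", "malignant")
  types <- c("mass", "cluster")
  withr::with_seed(seed, {
    gts <- list(); preds <- list()
    n_missed <- 0L; n_spurious <- 0L; n_flipped <- 0L
    gid <- 0L; pid_ctr <- 0L
    for (p in seq_len(n_patients)) {
      patient <- sprintf("P%04d", p)
      for (view in c("CC", "MLO")) {
        n_gt <- sample(1:2, 1L)
        centers <- cbind(stats::runif(n_gt, 25, frame[1] - 25),
                         stats::runif(n_gt, 25, frame[2] - 25))
        for (g in seq_len(n_gt)) {
          gid <- gid + 1L
          radius <- stats::runif(1, 8, 14)
          m <- roi_mask_disc(frame, centers[g, ], radius)
          cls <- sample(classes, 1L)
          typ <- sample(types, 1L)
          gts[[gid]] <- tibble::tibble(
            patient_id = patient, view = view, roi_id = gid,
            label2 = cls, lesion_type = typ, mask = list(m))
          if (stats::runif(1) < miss) {
            n_missed <- n_missed + 1L
          } else {
            pid_ctr <- pid_ctr + 1L
            jit <- centers[g, ] + stats::runif(2, -3, 3)
            pm <- roi_mask_disc(frame, jit, radius + stats::runif(1, -1, 1))
            flipped <- stats::runif(1) < flip
            if (flipped) n_flipped <- n_flipped + 1L
            pcls <- if (flipped) setdiff(classes, cls) else cls
            preds[[pid_ctr]] <- tibble::tibble(
              patient_id = patient, view = view, roi_id = pid_ctr,
              label4 = paste(pcls, typ, sep = "_"),
              score = stats::runif(1, 0.5, 0.95),
              mask = list(pm), planted_gt = gid, planted_flipped = flipped)
          }
        }
        n_fp <- stats::rpois(1, fp / 2)  # fp rate is per patient, 2 views
        for (k in seq_len(n_fp)) {
          # place spurious ROI far from every GT of this view
          for (try in 1:50) {
            ctr <- c(stats::runif(1, 15, frame[1] - 15),
                     stats::runif(1, 15, frame[2] - 15))
            sm <- roi_mask_disc(frame, ctr, stats::runif(1, 5, 9))
            this_view <- which(vapply(gts, function(x)
              x$patient_id == patient && x$view == view, logical(1)))
            ious <- vapply(this_view, function(i)
              compute_iou(gts[[i]]$mask[[1]], sm), numeric(1))
            if (!length(ious) || max(ious) <= 0.05) break
          }
          pid_ctr <- pid_ctr + 1L
          n_spurious <- n_spurious + 1L
          preds[[pid_ctr]] <- tibble::tibble(
            patient_id = patient, view = view, roi_id = pid_ctr,
            label4 = paste(sample(classes, 1L), sample(types, 1L), sep = "_"),
            score = stats::runif(1, 0.2, 0.95),
            mask = list(sm), planted_gt = NA_integer_, planted_flipped = FALSE)
        }
      }
    }
    gts <- dplyr::bind_rows(gts)
    preds <- if (length(preds)) dplyr::bind_rows(preds) else
      tibble::tibble(patient_id = character(), view = character(),
                     roi_id = integer(), label4 = character(),
                     score = numeric(), mask = list(),
                     planted_gt = integer(), planted_flipped = logical())
    structure(list(gts = gts, preds = preds,
                   log = list(n_gt = nrow(gts), n_missed = n_missed,
                              n_spurious = n_spurious, n_flipped = n_flipped)),
              class = "toy_annotations")
  })
}

#' Synthetic measured enhancement values from planted lesions
#'
#' Plants discs with known multiplicative enhancement factors into small
#' flat recombined-style frames, then measures them back with
#' [build_rings()] + [measure_enhancement()].  Feeds distribution fitting
#' where real measured lesions are unavailable.
#'
#' @param n Number of lesions.
#' @param seed Integer seed.
#' @param e_sampler Function `n -> factors`; default draws
#'   `1 + 0.06 * Beta(2, 3)`, concentrating mass at mild enhancement within
#'   the observed 1.00--1.06 range.
#' @param radius_px Range of planted disc radii in pixels.
#' @param frame Per-lesion frame size.
#' @param level,noise Recombined plateau and noise sigma (DN).
#' @return Tibble with `e_true` and `e_measured` per lesion.
#' @export
synth_enhancement_values <- function(n, seed = 1L,
                                     e_sampler = function(n)
                                       1 + 0.06 * stats::rbeta(n, 2, 3),
                                     radius_px = c(18, 28),
                                     frame = c(160L, 160L),
                                     level = 2000, noise = 15) {
  withr::with_seed(seed, {
    e_true <- e_sampler(n)
    radii <- stats::runif(n, radius_px[1], radius_px[2])
    out <- purrr::map2_dfr(e_true, radii, function(e, rad) {
      rc <- matrix(pmax(stats::rnorm(prod(frame), level, noise), 0),
                   frame[1], frame[2])
      img <- gray_image(round(rc), kind = "recombined")
      mask <- roi_mask_matrix(roi_mask_disc(frame, frame / 2, rad))
      enhanced <- apply_enhancement(img, mask, e, smooth_sigma = 5)
      rings <- build_rings(mask)
      tibble::tibble(e_true = e,
                     e_measured = measure_enhancement(enhanced, rings))
    })
    out
  })
}
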