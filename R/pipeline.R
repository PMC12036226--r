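# End-to-end orchestration: configuration, single-case simulation
# (low-energy insertion + recombined enhancement), dataset composition.

#' Simulation configuration
#'
#' Bundles all module parameters with documented defaults.  Every run of
#' [simulate_case()] records the resolved configuration in its provenance
#' so outputs are reproducible from (config, seed).
#'
#' @param spacing_mm Pixel pitch in mm (default 0.1).
#' @param cell_px Grid cell side for site selection (default 200).
#' @param subcell_px Sub-cell side for cluster growth (default 10).
#' @param min_coverage Minimum breast coverage of an eligible cell.
#' @param frangi_scales,frangi_beta,frangi_quantile,thr_k Candidate-mask
#'   parameters (see [candidate_mask()]).
#' @param amplitude Template peak excess (see [build_template()]).
#' @param psf_sigma_px,scatter_fraction Degradation (see
#'   [degrade_template()]).
#' @param expand_iterations,offset_px,dilation_px Mask generation (see
#'   [generate_lesion_mask()]).
#' @param smooth_sigma Enhancement smoothing sigma in pixels (default 5).
#' @param grid_n,bandwidth Enhancement distribution fitting.
#' @param clahe_nx,clahe_ny,clahe_limit CLAHE parameters for
#'   [compose_rgb()].
#' @param feature_specs Site-ranking feature table
#'   ([default_feature_specs()]).
#' @param enhancement_dists Named list of `enhancement_distribution`
#'   objects keyed `"<class>_<view>"` (e.g. `"benign_CC"`); defaults to
#'   distributions fitted to synthetic planted-lesion measurements
#'   ([default_enhancement_distributions()]).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(spacing_mm = 0.1, cell_px = 200L,
                              subcell_px = 10L, min_coverage = 0.9,
                              frangi_scales = 1:4, frangi_beta = 0.5,
                              frangi_quantile = 0.95, thr_k = 1,
                              amplitude = 0.15, psf_sigma_px = 1,
                              scatter_fraction = 0.2,
                              expand_iterations = 2L, offset_px = 2,
                              dilation_px = 5, smooth_sigma = 5,
                              grid_n = 121L, bandwidth = NULL,
                              clahe_nx = 8, clahe_ny = 8, clahe_limit = 2,
                              feature_specs = NULL,
                              enhancement_dists = NULL) {
  cfg <- list(spacing_mm = spacing_mm, cell_px = as.integer(cell_px),
              subcell_px = as.integer(subcell_px),
              min_coverage = min_coverage,
              frangi_scales = frangi_scales, frangi_beta = frangi_beta,
              frangi_quantile = frangi_quantile, thr_k = thr_k,
              amplitude = amplitude, psf_sigma_px = psf_sigma_px,
              scatter_fraction = scatter_fraction,
              expand_iterations = as.integer(expand_iterations),
              offset_px = offset_px, dilation_px = dilation_px,
              smooth_sigma = smooth_sigma, grid_n = as.integer(grid_n),
              bandwidth = bandwidth,
              clahe_nx = clahe_nx, clahe_ny = clahe_ny,
              clahe_limit = clahe_limit,
              feature_specs = feature_specs %||% default_feature_specs(),
              enhancement_dists = enhancement_dists)
  if (cfg$spacing_mm <= 0) abort("`spacing_mm` must be positive")
  if (cfg$cell_px %% cfg$subcell_px != 0L) {
    abort("`subcell_px` must divide `cell_px`")
  }
  structure(cfg, class = "simulation_config")
}

#' Default per-(class, view) enhancement distributions
#'
#' Fits Gaussian-kernel distributions to synthetic measured enhancement
#' values from planted-lesion fixtures ([synth_enhancement_values()]),
#' one per (class, view) subset.  A stand-in for fits to real measured
#' lesions, labelled synthetic by construction.
#'
#' @param n Measured values per subset (default 50).
#' @param seed Integer seed.
#' @return Named list of `enhancement_distribution` objects.
#' @export
default_enhancement_distributions <- function(n = 50L, seed = 1L) {
  keys <- c("benign_CC", "benign_MLO", "malignant_CC", "malignant_MLO")
  out <- lapply(seq_along(keys), function(i) {
    vals <- synth_enhancement_values(n, seed = derive_seed(seed, keys[i]))
    fit_enhancement_distribution(pmax(vals$e_measured, 1), subset_key = keys[i])
  })
  stats::setNames(out, keys)
}

#' Simulate one synthetic lesion case
#'
#' Runs the full per-view pipeline on a lesion-free image pair: breast
#' segmentation, grid-feature site selection, candidate extraction and
#' class-specific filtering, cluster growth, template build / degradation /
#' multiplicative insertion into the low-energy image, automatic lesion
#' mask generation, and sampled, smoothed enhancement of the recombined
#' image.  CC and MLO views of one breast must be simulated with the same
#' class label (enforced by the caller passing the same `class_label`);
#' infeasible views signal a `"cemsim_infeasible_cluster"` condition the
#' caller can catch and log.
#'
#' @param pair A lesion-free [case_pair()].
#' @param class_label `"benign"` or `"malignant"`.
#' @param config A [simulation_config()].
#' @param seed Integer master seed; fans out to per-stage streams.
#' @return A list of class `simulated_case`: `pair` (inserted images),
#'   `mask` (lesion mask), `cluster`, `provenance`.
#' @export
simulate_case <- function(pair, class_label = c("benign", "malignant"),
                          config = simulation_config(), seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(pair, "case_pair"),
            inherits(config, "simulation_config"))
  le <- pair$low_energy
  breast <- segment_breast(le)
  cells <- compute_grid_features(le, breast, cell_px = config$cell_px,
                                 min_coverage = config$min_coverage)
  site <- select_insertion_site(cells, config$feature_specs)
  cell <- crop_cell(le, site)
  cmask <- candidate_mask(cell, frangi_scales = config$frangi_scales,
                          frangi_beta = config$frangi_beta,
                          frangi_quantile = config$frangi_quantile,
                          thr_k = config$thr_k)
  regions <- extract_candidates(cmask, spacing_mm = le$spacing_mm,
                                intensity = cell)
  criteria <- class_criteria(class_label)
  kept <- filter_candidates(regions, criteria)
  cluster <- grow_cluster(cell, kept, criteria,
                          subcell_px = config$subcell_px,
                          seed = derive_seed(seed, "grow"), anchor = site)
  tpl <- build_template(cluster, amplitude = config$amplitude,
                        frame = dim(le$pixels))
  tpl <- degrade_template(tpl, psf_sigma_px = config$psf_sigma_px,
                          scatter_fraction = config$scatter_fraction)
  inserted_le <- insert_template(le, tpl)
  mask <- generate_lesion_mask(template_support(tpl),
                               expand_iterations = config$expand_iterations,
                               offset_px = config$offset_px,
                               dilation_px = config$dilation_px)
  dists <- config$enhancement_dists %||%
    default_enhancement_distributions(seed = derive_seed(seed, "dists"))
  key <- paste(class_label, le$view, sep = "_")
  if (!key %in% names(dists)) {
    abort(sprintf("no enhancement distribution for subset '%s'", key))
  }
  e <- sample_enhancement(dists[[key]], n = 1L,
                          seed = derive_seed(seed, "sample_e"))
  enhanced_rc <- apply_enhancement(pair$recombined, unclass(mask), e,
                                   smooth_sigma = config$smooth_sigma)
  out_pair <- case_pair(inserted_le, enhanced_rc,
                        patient_id = pair$patient_id,
                        laterality = pair$laterality)
  structure(list(
    pair = out_pair, mask = mask, cluster = cluster,
    provenance = list(seed = seed, class = class_label,
                      view = le$view, site = site[, c("row", "col")],
                      count = cluster$count, target = cluster$target,
                      enhancement = e,
                      config = config[setdiff(names(config),
                                              "enhancement_dists")])),
    class = "simulated_case")
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("<simulated_case> %s %s: %d calcifications at cell (%d, %d), enhancement %.4f\n",
              x$provenance$class, x$provenance$view, x$provenance$count,
              x$provenance$site$row, x$provenance$site$col,
              x$provenance$enhancement))
  invisible(x)
}

#' Compose a training dataset manifest from real and synthetic records
#'
#' Samples a fraction of real patients stratified by (class, lesion type)
#' so benign/malignant and mass/cluster ratios are preserved, then adds a
#' synthetic set sized as a multiple of the sampled real cluster count,
#' preserving the real benign/malignant cluster ratio.
#'
#' @param real_records Tibble with `patient_id`, `label2`, `lesion_type`
#'   (and any file-path columns).
#' @param synthetic_records Tibble with `label2` and `lesion_type ==
#'   "cluster"` records to draw from.
#' @param real_fraction Fraction of real patients to keep, in (0, 1].
#' @param synth_multiple Synthetic cluster count as a multiple of the
#'   selected real cluster count (>= 0).
#' @param seed Integer seed.
#' @return Manifest tibble: the selected records with a `source` column
#'   (`"real"`/`"synthetic"`).
#' @export
compose_dataset <- function(real_records, synthetic_records = NULL,
                            real_fraction = 1, synth_multiple = 0,
                            seed = 1L) {
  if (real_fraction <= 0 || real_fraction > 1) {
    abort("`real_fraction` must be in (0, 1]")
  }
  if (synth_multiple < 0) abort("`synth_multiple` must be >= 0")
  withr::with_seed(derive_seed(seed, "compose"), {
    # stratify patients by their (class, type) profile
    strata <- dplyr::summarise(
      dplyr::group_by(real_records, .data$patient_id),
      stratum = paste(sort(unique(paste(.data$label2, .data$lesion_type))),
                      collapse = "+"), .groups = "drop")
    picked <- dplyr::group_modify(
      dplyr::group_by(strata, .data$stratum),
      function(d, g) {
        k <- round(real_fraction * nrow(d))
        if (real_fraction < 1) k <- max(k, 1L)
        d[sample.int(nrow(d), min(k, nrow(d))), , drop = FALSE]
      })
    real_sel <- dplyr::semi_join(real_records, picked, by = "patient_id")
    real_sel$source <- "real"
    if (synth_multiple == 0 || is.null(synthetic_records)) {
      return(tibble::as_tibble(real_sel))
    }
    clusters <- dplyr::filter(real_sel, .data$lesion_type == "cluster")
    synth <- purrr::map_dfr(unique(clusters$label2), function(cls) {
      n_want <- round(synth_multiple * sum(clusters$label2 == cls))
      pool <- dplyr::filter(synthetic_records, .data$label2 == cls)
      if (n_want > nrow(pool)) {
        abort(sprintf("requested %d synthetic '%s' clusters but pool has %d",
                      n_want, cls, nrow(pool)))
      }
      pool[sample.int(nrow(pool), n_want), , drop = FALSE]
    })
    if (nrow(synth)) synth$source <- "synthetic"
    dplyr::bind_rows(tibble::as_tibble(real_sel), synth)
  })
}
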