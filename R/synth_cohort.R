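#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic study: cohort sizes, template
#' geometry, ground-truth perfusion effects, acquisition per site, and the
#' linear model generating Western Aphasia Battery (WAB) scores from
#' ground-truth ROI perfusion, lesion load and demographic covariates.
#'
#' The defaults emulate the study conditions the pipeline is designed for:
#' grey-matter CBF in the normal range, a single left-hemisphere lesion per
#' patient with graded perilesional hypoperfusion (multipliers 0.85 / 0.95 /
#' 1.00 over the 0-5 / 5-10 / 10-15 mm bands), a group-level left deficit in
#' the first two (frontoparietal-analogue) language ROIs, and language
#' scores coupled to adjusted perfusion of the last two (temporal-analogue)
#' language ROIs.
#'
#' WAB scores are generated as
#' `clip(intercept + sum_r w_r * adjusted_perfusion_r
#'       - sum_r v_r * lesion_load_r + covariate terms + noise, bounds)`
#' where adjusted perfusion and lesion load are computed from the
#' ground-truth CBF field, so the planted couplings are exact. The intercept
#' is parameterized as `target_mean - sum_r w_r * reference_r`, with the
#' reference taken from an unlesioned, effect-free template subject, so the
#' configured target mean is where scores land when nothing is planted.
#'
#' @param n_aphasia,n_control subjects per group (>= 2 each).
#' @param grid template [vox_grid()].
#' @param n_roi_pairs,n_control_rois,roi_radius_mm atlas layout, see
#'   [make_brain()].
#' @param gm_baseline,wm_baseline tissue CBF baselines, ml/100 g/min.
#' @param roi_effect_sd sd (ml/100 g/min) of per-subject random ROI offsets.
#' @param roi_effect_mode `"independent"` (each ROI draws its own offset) or
#'   `"paired"` (homologous left/right ROIs share one offset, preserving
#'   mirror symmetry).
#' @param group_deficit named numeric: additive CBF offset (usually
#'   negative) applied to patients in the named left-ROI labels.
#' @param peri_multipliers perilesional gradient multipliers for the
#'   0-5 / 5-10 / 10-15 mm bands.
#' @param lesion_centre_rois left-ROI labels lesions may centre on.
#' @param lesion_radius_mm range (min, max) of lesion radii in mm.
#' @param site_prob probability a subject is scanned at site A.
#' @param male_prob probability a subject is male.
#' @param n_pairs_site_a,n_pairs_site_b tag/control pairs acquired per site.
#' @param asl_noise_sd per-volume ASL noise sd in M0 units (M0 = 1000).
#' @param conserve_global_flow if TRUE (default), each patient's planted
#'   focal deficit (ROI offsets plus perilesional suppression) is
#'   redistributed as a uniform tissue-weighted increase over brain tissue
#'   outside every analysis ROI and the 0-15 mm perilesional shell, so the
#'   whole-brain mean (lesion masked) is preserved. This models approximate
#'   conservation of total cerebral blood flow with post-stroke
#'   redistribution; without it, whole-brain normalization mechanically
#'   inflates every unaffected ROI's adjusted value in patients.
#' @param behaviour list per outcome with elements `target_mean`,
#'   `perfusion_weights` (named by left-ROI label or perilesional band
#'   name), `lesion_load_weights` (named by left-ROI label, per percentage
#'   point), `covariate_effects` (named: age, months_post_onset, sex_m,
#'   site_b), `noise_sd`, `bounds`. Defaults via
#'   [default_behaviour_model()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_aphasia = 20, n_control = 20,
                          grid = vox_grid(c(20, 24, 20), c(2, 2, 2)),
                          n_roi_pairs = 4, n_control_rois = 2,
                          roi_radius_mm = 5,
                          gm_baseline = 55, wm_baseline = 22,
                          roi_effect_sd = 6,
                          roi_effect_mode = c("independent", "paired"),
                          group_deficit = c("1" = -8, "2" = -8),
                          peri_multipliers = c(0.85, 0.95, 1.0),
                          lesion_centre_rois = 1,
                          lesion_radius_mm = c(5, 9),
                          site_prob = 0.7, male_prob = 0.68,
                          n_pairs_site_a = 20, n_pairs_site_b = 8,
                          asl_noise_sd = 2,
                          conserve_global_flow = TRUE,
                          behaviour = default_behaviour_model()) {
  if (n_aphasia < 2 || n_control < 2)
    stop("at least 2 subjects per group are required", call. = FALSE)
  structure(list(
    n_aphasia = n_aphasia, n_control = n_control, grid = grid,
    n_roi_pairs = n_roi_pairs, n_control_rois = n_control_rois,
    roi_radius_mm = roi_radius_mm,
    gm_baseline = gm_baseline, wm_baseline = wm_baseline,
    roi_effect_sd = roi_effect_sd,
    roi_effect_mode = match.arg(roi_effect_mode),
    group_deficit = group_deficit,
    peri_multipliers = peri_multipliers,
    lesion_centre_rois = lesion_centre_rois,
    lesion_radius_mm = lesion_radius_mm,
    site_prob = site_prob, male_prob = male_prob,
    n_pairs_site_a = n_pairs_site_a, n_pairs_site_b = n_pairs_site_b,
    asl_noise_sd = asl_noise_sd,
    conserve_global_flow = conserve_global_flow,
    behaviour = behaviour),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @param planted_rois left-ROI labels whose adjusted perfusion drives
#'   language scores.
#' @param perfusion_weight weight per unit adjusted perfusion for the
#'   planted ROIs.
#' @param noise_sd behaviour noise sd on the 0-10 subtest scale.
#' @export
default_behaviour_model <- function(planted_rois = c(3, 4),
                                    perfusion_weight = 8,
                                    noise_sd = 0.25) {
  pw <- stats::setNames(rep(perfusion_weight, length(planted_rois)),
                        as.character(planted_rois))
  sub_cov <- c(age = -0.01, months_post_onset = 0.002,
               sex_m = 0.1, site_b = 0.05)
  subtest <- function(target, weights = pw, ll = NULL,
                      cov = sub_cov, nsd = noise_sd)
    list(target_mean = target, perfusion_weights = weights,
         lesion_load_weights = ll, covariate_effects = cov,
         noise_sd = nsd, bounds = c(0, 10))
  list(
    information_content = subtest(8.5),
    fluency = subtest(8),
    repetition = subtest(8, weights = NULL, nsd = noise_sd),
    naming = subtest(7.5, ll = c("2" = 0.02)),
    auditory_comprehension = subtest(9),
    aq = list(target_mean = 80, perfusion_weights = pw * 10,
              lesion_load_weights = c("2" = 0.1),
              covariate_effects = sub_cov * 10,
              noise_sd = noise_sd * 10, bounds = c(0, 100))
  )
}

# Restore a patient's whole-brain mean (lesion masked) to what it would be
# without the planted group deficit and perilesional suppression, by adding a
# uniform tissue-weighted offset to brain voxels outside every atlas ROI and
# outside the 0-15 mm perilesional shell. Keeps all planted focal effects
# intact while preventing the normalization denominator from carrying them
# into unaffected ROIs.
redistribute_flow <- function(cbf_true, brain, lesion, offs, config) {
  grid <- config$grid
  # reference: same lesion and same subject-level random offsets, but no
  # group deficit and no perilesional suppression
  offs_ref <- offs
  if (length(config$group_deficit))
    offs_ref[names(config$group_deficit)] <-
      offs_ref[names(config$group_deficit)] - config$group_deficit
  ref <- make_cbf_truth(
    brain$tissue, grid, brain$atlas, lesion,
    gm_baseline = config$gm_baseline, wm_baseline = config$wm_baseline,
    roi_effects = offs_ref,
    peri_multipliers = rep(1, length(config$peri_multipliers)))
  support <- brain$brain_mask
  if (!is.null(lesion)) support <- support & !lesion
  deficit <- sum(ref[support]) - sum(cbf_true[support])
  if (abs(deficit) < 1e-9) return(cbf_true)
  eligible <- support & brain$atlas == 0L
  if (!is.null(lesion) && any(lesion)) {
    d <- distance_to_lesion(lesion, grid)
    eligible <- eligible & d > 15
  }
  w <- brain$tissue$gm + brain$tissue$wm
  denom <- sum(w[eligible])
  if (denom <= 0) {
    warning("no eligible tissue to redistribute the focal deficit into",
            call. = FALSE)
    return(cbf_true)
  }
  cbf_true[eligible] <- cbf_true[eligible] + (deficit / denom) * w[eligible]
  cbf_true
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) %% 2147483647) * 1009 + i * 7919) %%
    2147483561L + 1L
}

#' Simulate a full synthetic cohort
#'
#' Generates the shared brain template, then per subject: demographics, a
#' left-hemisphere lesion (patients only), a ground-truth CBF field with
#' planted ROI offsets and perilesional gradient, a noisy interleaved
#' tag/control ASL series with site-specific acquisition, and WAB scores
#' from the configured linear model on ground-truth adjusted perfusion,
#' lesion load and covariates. Each subject draws from a private random
#' stream derived from (master seed, subject index), so the cohort is
#' reproducible subject-by-subject under resizing.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return cohort bundle: list with `subjects` (per-subject volumes and
#'   ground truth), `grid`, `atlas`, `lookup`, `brain` (template), `table`
#'   (cohort data.frame), `truth` (per-subject generating parameters),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = 1) {
  grid <- config$grid
  brain <- make_brain(grid, config$n_roi_pairs, config$n_control_rois,
                      seed = seed, roi_radius_mm = config$roi_radius_mm)
  n <- config$n_aphasia + config$n_control
  groups <- rep(c("aphasia", "control"), c(config$n_aphasia, config$n_control))
  left_labels <- brain$lookup$label[brain$lookup$hemisphere == "L"]
  outcomes <- names(config$behaviour)

  # reference adjusted perfusion of an unlesioned, effect-free template
  # subject: the behaviour model applies its weights to deviations from
  # this reference so the planted intercepts land near the target means
  cbf_ref <- make_cbf_truth(brain$tissue, grid, brain$atlas, NULL,
                            gm_baseline = config$gm_baseline,
                            wm_baseline = config$wm_baseline)
  ref_tab <- subject_roi_metrics(cbf_ref, grid, brain$atlas, brain$lookup,
                                 brain$brain_mask, brain$tissue, NULL)
  adj_ref <- stats::setNames(ref_tab$mean_adjusted, ref_tab$roi)
  ref_for <- function(nms)  # perilesional bands fall back to the atlas mean
    ifelse(nms %in% names(adj_ref), adj_ref[nms], mean(adj_ref))

  subjects <- vector("list", n)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- subject_seed(seed, i)
    rng <- local_rng(sseed)
    id <- sprintf("sub%03d", i)
    group <- groups[i]
    site <- if (rng$runif(1) < config$site_prob) "A" else "B"
    sex <- if (rng$runif(1) < config$male_prob) "M" else "F"
    age <- round(rng$runif(1, 43, 88), 1)
    months <- if (group == "aphasia")
      round(3 + stats::qlnorm(rng$runif(1), log(30), 0.9), 1) else NA_real_

    # per-subject ROI perfusion offsets (+ group deficit for patients)
    offs <- if (config$roi_effect_mode == "paired") {
      o <- rng$rnorm(length(left_labels), 0, config$roi_effect_sd)
      stats::setNames(c(o, o),
                      c(as.character(left_labels),
                        as.character(brain$lookup$homologue[
                          match(left_labels, brain$lookup$label)])))
    } else {
      stats::setNames(rng$rnorm(nrow(brain$lookup), 0, config$roi_effect_sd),
                      as.character(brain$lookup$label))
    }
    if (group == "aphasia" && length(config$group_deficit)) {
      gd <- config$group_deficit
      offs[names(gd)] <- offs[names(gd)] + gd
    }

    lesion <- NULL
    if (group == "aphasia") {
      centre <- config$lesion_centre_rois[
        1L + (rng$sample(length(config$lesion_centre_rois), 1) - 1L)]
      radius <- rng$runif(1, config$lesion_radius_mm[1],
                          config$lesion_radius_mm[2])
      lesion <- make_lesion(brain, centre, radius, seed = sseed + 1L)
    }

    cbf_true <- make_cbf_truth(
      brain$tissue, grid, brain$atlas, lesion,
      gm_baseline = config$gm_baseline, wm_baseline = config$wm_baseline,
      roi_effects = offs, peri_multipliers = config$peri_multipliers)
    if (config$conserve_global_flow && group == "aphasia")
      cbf_true <- redistribute_flow(cbf_true, brain, lesion, offs, config)

    acq <- acq_preset(if (site == "A") "site_a" else "site_b")
    n_pairs <- if (site == "A") config$n_pairs_site_a else config$n_pairs_site_b
    sim <- simulate_asl(cbf_true, acq, n_pairs = n_pairs,
                        noise_sd = config$asl_noise_sd, seed = sseed + 2L,
                        brain_mask = brain$brain_mask)

    lesion_volume <- if (is.null(lesion)) 0 else
      sum(lesion) * voxel_volume_mm3(grid)

    # ground-truth ROI summaries feed the behaviour model
    tm <- subject_roi_metrics(cbf_true, grid, brain$atlas, brain$lookup,
                              brain$brain_mask, brain$tissue, lesion)
    scores <- rep(NA_real_, length(outcomes))
    names(scores) <- outcomes
    if (group == "aphasia") {
      adj <- stats::setNames(tm$mean_adjusted, tm$roi)
      ll <- stats::setNames(tm$lesion_load, tm$roi)
      for (o in outcomes) {
        bm <- config$behaviour[[o]]
        val <- bm$target_mean
        if (length(bm$perfusion_weights)) {
          w <- bm$perfusion_weights
          val <- val + sum(w * (adj[names(w)] - ref_for(names(w))))
        }
        if (length(bm$lesion_load_weights)) {
          v <- bm$lesion_load_weights
          val <- val - sum(v * ll[names(v)])
        }
        ce <- bm$covariate_effects
        if (length(ce))
          val <- val + ce[["age"]] * (age - 65) +
            ce[["months_post_onset"]] * (months - 52) +
            ce[["sex_m"]] * (sex == "M") + ce[["site_b"]] * (site == "B")
        val <- val + rng$rnorm(1, 0, bm$noise_sd)
        scores[o] <- min(max(val, bm$bounds[1]), bm$bounds[2])
      }
    }

    subjects[[i]] <- list(
      id = id, group = group, site = site, acq = acq,
      asl = sim$asl, m0 = if (acq$m0_mode == "separate_volume") sim$m0 else NULL,
      brain_mask = brain$brain_mask, tissue = brain$tissue,
      lesion = lesion, cbf_true = cbf_true)
    truth[[i]] <- list(id = id, seed = sseed, roi_offsets = offs,
                       true_adjusted = stats::setNames(tm$mean_adjusted, tm$roi),
                       true_lesion_load = stats::setNames(tm$lesion_load, tm$roi))
    rows[[i]] <- data.frame(
      id = id, group = group, age = age, sex = sex,
      months_post_onset = months, site = site,
      lesion_volume = lesion_volume,
      information_content = scores[["information_content"]],
      fluency = scores[["fluency"]], repetition = scores[["repetition"]],
      naming = scores[["naming"]],
      auditory_comprehension = scores[["auditory_comprehension"]],
      aq = scores[["aq"]], stringsAsFactors = FALSE)
  }

  list(subjects = subjects, grid = grid, atlas = brain$atlas,
       lookup = brain$lookup, brain = brain,
       table = do.call(rbind, rows), truth = truth,
       config = config, seed = seed)
}

#' Study conditions for the support-recovery experiment
#'
#' A [cohort_config()] in which language scores are driven *only* by the
#' adjusted perfusion of two planted left ROIs (equal positive weights,
#' behaviour noise sd 0.25 on the subtest scale): no lesion-load effects and
#' no covariate effects. These are the conditions under which the lasso and
#' partial-correlation analyses are asked to recover exactly the planted
#' ROIs.
#'
#' @param n_aphasia aphasia-group size (default 40).
#' @param planted_rois left-ROI labels carrying the coupling.
#' @param perfusion_weight weight per unit adjusted perfusion.
#' @param noise_sd behaviour noise sd (subtest scale).
#' @return a `cohort_config`.
#' @export
recovery_config <- function(n_aphasia = 40, planted_rois = c(3, 4),
                            perfusion_weight = 8, noise_sd = 0.25) {
  beh <- default_behaviour_model(planted_rois, perfusion_weight, noise_sd)
  beh <- lapply(beh, function(b) {
    b$lesion_load_weights <- NULL
    b$covariate_effects <- NULL
    b
  })
  cohort_config(n_aphasia = n_aphasia, n_control = 2, behaviour = beh)
}
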