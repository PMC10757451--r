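test_that("make_brain places the requested mirrored atlas", {
  g <- tiny_grid()
  b <- make_brain(g, n_roi_pairs = 3, n_control_rois = 1, seed = 7,
                  roi_radius_mm = 5)
  labs <- setdiff(sort(unique(as.vector(b$atlas))), 0L)
  expect_length(labs, 8)                       # 4 pairs -> 8 labels
  expect_equal(sum(b$lookup$hemisphere == "L"), 4)
  # every left ROI voxel has its homologue under reflection
  mirrored <- mirror_volume(b$atlas, g)
  for (i in seq_len(nrow(b$lookup))) {
    lab <- b$lookup$label[i]
    hom <- b$lookup$homologue[i]
    expect_identical(which(mirrored == lab), which(b$atlas == hom))
  }
  # tissue probabilities are proper and sum to <= 1
  for (tm in b$tissue) {
    expect_true(all(tm >= 0 & tm <= 1))
  }
  expect_true(all(b$tissue$gm + b$tissue$wm + b$tissue$csf <= 1 + 1e-9))
  # CSF rim and ventricles exist
  expect_true(sum(b$tissue$csf >= 0.5) > 0)
})

test_that("make_brain is deterministic and fails loudly on impossible layouts", {
  g <- tiny_grid()
  b1 <- make_brain(g, 2, 1, seed = 3)
  b2 <- make_brain(g, 2, 1, seed = 3)
  expect_identical(b1$atlas, b2$atlas)
  expect_identical(b1$tissue, b2$tissue)
  expect_error(make_brain(vox_grid(c(6, 6, 6), c(2, 2, 2)), 5, 2, seed = 1),
               "ROI")
})

test_that("make_lesion respects hemisphere, connectivity and volume bookkeeping", {
  b <- template_brain()
  g <- b$grid
  expect_equal(sum(make_lesion(b, 1, 0, seed = 1)), 0)   # radius 0 -> empty
  les <- make_lesion(b, 1, 8, seed = 3)
  expect_true(any(les))
  expect_false(any(les & hemisphere_masks(g)$right))
  expect_true(all(les[!b$brain_mask] == FALSE))
  # volume equals voxel count times voxel volume
  expect_equal(sum(les) * voxel_volume_mm3(g), sum(les) * 8)
  # connected: the component containing any lesion voxel is the whole lesion
  seedvox <- arrayInd(which(les)[1], g$shape)
  expect_identical(connected_component(les, seedvox), les)
  # reproducible under seed
  expect_identical(les, make_lesion(b, 1, 8, seed = 3))
  # a right-hemisphere centre ROI is rejected
  rlab <- b$lookup$label[b$lookup$hemisphere == "R"][1]
  expect_error(make_lesion(b, rlab, 5, seed = 1), "left hemisphere")
})

test_that("make_cbf_truth composes baselines, offsets and the perilesional gradient", {
  g <- vox_grid(c(12, 12, 12), c(1, 1, 1))
  # hand-built tissue: pure GM except one pure-CSF voxel
  tissue <- plain_tissue(g)
  tissue$gm[2, 2, 2] <- 0; tissue$csf[2, 2, 2] <- 1
  cbf <- make_cbf_truth(tissue, g, gm_baseline = 60, wm_baseline = 20)
  expect_equal(cbf[2, 2, 2], 0)     # pure CSF -> 0
  expect_equal(cbf[5, 5, 5], 60)    # pure GM, no effects -> baseline
  # multiplier 0.8 within 5 mm: a pure-GM voxel 3 mm from the lesion -> 48
  lesion <- array(FALSE, g$shape); lesion[6, 6, 6] <- TRUE
  cbf2 <- make_cbf_truth(tissue, g, lesion_mask = lesion, gm_baseline = 60,
                         wm_baseline = 20,
                         peri_multipliers = c(0.8, 0.9, 1))
  expect_equal(cbf2[9, 6, 6], 48)   # distance exactly 3 mm
  expect_equal(cbf2[6, 6, 6], 0)    # inside lesion
  # negative results are clipped with a warning
  atlas <- array(1L, g$shape)
  expect_warning(
    cbf3 <- make_cbf_truth(tissue, g, atlas, gm_baseline = 35,
                           roi_effects = c("1" = -100)),
    "clipped")
  expect_true(all(cbf3 >= 0))
})

test_that("noiseless ASL simulation round-trips through quantification", {
  b <- template_brain()
  g <- b$grid
  lesion <- make_lesion(b, 1, 6, seed = 2)
  cbf <- make_cbf_truth(b$tissue, g, b$atlas, lesion,
                        roi_effects = c("3" = -5))
  for (site in c("site_a", "site_b")) {
    acq <- acq_preset(site)
    sim <- simulate_asl(cbf, acq, n_pairs = 2, noise_sd = 0,
                        brain_mask = b$brain_mask)
    dm <- mean_difference(sim$asl, acq)
    m0 <- resolve_m0(sim$asl, acq, sim$m0)
    est <- quantify_cbf(dm, m0, acq, b$brain_mask)
    rel <- abs(est[b$brain_mask] - cbf[b$brain_mask]) /
      pmax(abs(cbf[b$brain_mask]), 1e-12)
    expect_lt(max(rel), 1e-6)
  }
  # zero CBF -> all difference volumes identically zero
  sim0 <- simulate_asl(array(0, g$shape), acq_preset("site_a"), n_pairs = 3,
                       noise_sd = 0)
  expect_equal(mean_difference(sim0$asl, acq_preset("site_a")),
               array(0, g$shape))
})

test_that("averaging more pairs shrinks the voxelwise quantification error", {
  b <- template_brain()
  cbf <- make_cbf_truth(b$tissue, b$grid)
  acq <- acq_preset("site_b")  # separate M0: isolates difference noise
  err <- vapply(c(4, 64), function(np) {
    sim <- simulate_asl(cbf, acq, n_pairs = np, noise_sd = 2, seed = 9,
                        brain_mask = b$brain_mask)
    est <- quantify_cbf(mean_difference(sim$asl, acq), sim$m0, acq,
                        b$brain_mask)
    mean(abs(est[b$brain_mask] - cbf[b$brain_mask]))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)  # expected sqrt(16) = 4-fold reduction
})

test_that("simulate_cohort is deterministic and respects its contracts", {
  cfg <- cohort_config(n_aphasia = 3, n_control = 2)
  co1 <- simulate_cohort(cfg, seed = 5)
  co2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(co1$table, co2$table)
  expect_identical(co1$subjects[[1]]$asl, co2$subjects[[1]]$asl)
  # controls carry no lesion and zero lesion volume
  ctrl <- co1$table[co1$table$group == "control", ]
  expect_true(all(ctrl$lesion_volume == 0))
  expect_true(all(vapply(co1$subjects, function(s)
    s$group != "control" || is.null(s$lesion), logical(1))))
  # WAB bounds respected
  aph <- co1$table[co1$table$group == "aphasia", ]
  for (o in c("information_content", "fluency", "repetition", "naming",
              "auditory_comprehension"))
    expect_true(all(aph[[o]] >= 0 & aph[[o]] <= 10))
  expect_true(all(aph$aq >= 0 & aph$aq <= 100))
  expect_true(all(aph$months_post_onset >= 3))
  expect_error(cohort_config(n_aphasia = 1), "at least 2")
})

test_that("zero weights and zero noise pin scores at the configured targets", {
  beh <- default_behaviour_model()
  beh <- lapply(beh, function(b) {
    b$perfusion_weights <- NULL; b$lesion_load_weights <- NULL
    b$covariate_effects <- NULL; b$noise_sd <- 0
    b
  })
  cfg <- cohort_config(n_aphasia = 2, n_control = 2, behaviour = beh)
  co <- simulate_cohort(cfg, seed = 8)
  aph <- co$table[co$table$group == "aphasia", ]
  expect_equal(aph$naming, rep(beh$naming$target_mean, 2))
  expect_equal(aph$aq, rep(beh$aq$target_mean, 2))
})

test_that("an unlesioned cohort with symmetric effects is mirror-symmetric", {
  cfg <- cohort_config(n_aphasia = 2, n_control = 2,
                       roi_effect_mode = "paired", group_deficit = numeric(0))
  co <- simulate_cohort(cfg, seed = 4)
  s <- co$subjects[[3]]  # a control: no lesion
  lookup <- co$lookup
  left <- lookup[lookup$hemisphere == "L", ]
  for (i in seq_len(nrow(left))) {
    ml <- mean(s$cbf_true[co$atlas == left$label[i]])
    mr <- mean(s$cbf_true[co$atlas == left$homologue[i]])
    expect_lt(abs(ml - mr), 1e-9)
  }
})
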