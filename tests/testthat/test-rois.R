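test_that("single-voxel lesion yields the 514-point 0-5 mm band on a 1 mm grid", {
  # lesion centred deep in the left hemisphere of a 31^3 1 mm grid, no
  # exclusions: the 0-5 mm band is the set of lattice points with
  # 0 < d <= 5, which has 514 elements
  g <- vox_grid(c(31, 31, 31), c(1, 1, 1))
  lesion <- array(FALSE, g$shape)
  i <- which.min(abs(grid_coords(g)[[1]] + 8))
  lesion[i, 16, 16] <- TRUE
  bands <- perilesional_bands(lesion, array(TRUE, g$shape),
                              plain_tissue(g), g)
  expect_equal(sum(bands$peri_0_5), 514)
})

test_that("bands partition the 0-15 mm shell and are ordered by distance", {
  g <- tiny_grid()
  brain <- template_brain()
  lesion <- make_lesion(brain, 1, 6, seed = 3)
  bands <- perilesional_bands(lesion, brain$brain_mask, brain$tissue, g)
  # pairwise disjoint
  expect_false(any(bands[[1]] & bands[[2]]))
  expect_false(any(bands[[1]] & bands[[3]]))
  expect_false(any(bands[[2]] & bands[[3]]))
  # union equals the full shell after the same exclusions
  d <- distance_to_lesion(lesion, g)
  keep <- brain$brain_mask & hemisphere_masks(g)$left &
    !csf_exclusion_mask(brain$tissue) & !lesion
  shell <- (d > 0) & (d <= 15) & keep
  expect_identical(bands[[1]] | bands[[2]] | bands[[3]], shell)
  # mean distance increases with the band
  md <- vapply(bands, function(b) mean(d[b]), numeric(1))
  expect_true(md[1] < md[2] && md[2] < md[3])
  # no lesion or right-hemisphere voxels in any band
  right <- hemisphere_masks(g)$right
  for (b in bands) {
    expect_false(any(b & lesion))
    expect_false(any(b & right))
  }
})

test_that("a lesion touching the midline never produces right-hemisphere band voxels", {
  g <- vox_grid(c(16, 16, 16), c(2, 2, 2))
  lesion <- array(FALSE, g$shape)
  lesion[8, 8, 8] <- TRUE  # x world = -1: leftmost column next to midline
  expect_true(grid_coords(g)[[1]][8] < 0)
  bands <- perilesional_bands(lesion, array(TRUE, g$shape),
                              plain_tissue(g), g)
  right <- hemisphere_masks(g)$right
  for (b in bands) expect_false(any(b & right))
})

test_that("prepare_atlas_rois applies the exclusion rules and lesion load", {
  g <- vox_grid(c(10, 10, 4), c(1, 1, 1))
  atlas <- array(0L, g$shape)
  atlas[1:10, 1:10, 1] <- 1L   # a 100-voxel slab ROI (left ROI by fiat)
  lookup <- data.frame(label = 1L, name = "roi_a", hemisphere = "L",
                       class = "perisylvian", homologue = 1L)
  tissue <- plain_tissue(g)
  brain <- array(TRUE, g$shape)
  # control subject: effective = original minus CSF/out-of-brain
  tissue$csf[1:2, 1, 1] <- 1; tissue$gm[1:2, 1, 1] <- 0
  brain[3, 1, 1] <- FALSE
  prep <- prepare_atlas_rois(atlas, lookup, brain, tissue, NULL)
  expect_equal(prep$table$original_voxels, 100L)
  expect_equal(prep$table$effective_voxels, 97L)
  expect_equal(prep$table$lesion_load, 0)
  # 25 of 100 voxels lesioned -> lesion load 25%
  lesion <- array(FALSE, g$shape)
  lesion[1:5, 1:5, 1] <- TRUE
  prep2 <- prepare_atlas_rois(atlas, lookup, brain, tissue, lesion)
  expect_equal(prep2$table$lesion_load, 25)
  expect_false(any(prep2$masks[["1"]] & lesion))
  # monotone: growing the lesion never grows the effective mask
  lesion3 <- lesion; lesion3[6, 6, 1] <- TRUE
  prep3 <- prepare_atlas_rois(atlas, lookup, brain, tissue, lesion3)
  expect_true(all(which(prep3$masks[["1"]]) %in% which(prep2$masks[["1"]])))
  # fully lesioned ROI -> empty effective mask, load 100, flagged
  full <- array(FALSE, g$shape); full[1:10, 1:10, 1] <- TRUE
  expect_warning(prep4 <- prepare_atlas_rois(atlas, lookup, brain, tissue,
                                             full),
                 "empty effective mask")
  expect_equal(prep4$table$lesion_load, 100)
  expect_equal(prep4$table$effective_voxels, 0L)
  # unknown labels are named in the error
  atlas_bad <- atlas; atlas_bad[1, 1, 2] <- 9L
  expect_error(prepare_atlas_rois(atlas_bad, lookup, brain, tissue, NULL),
               "9")
})

test_that("CSF exclusion requires both threshold and argmax", {
  g <- vox_grid(c(2, 2, 2))
  tissue <- list(gm = array(0.6, g$shape), wm = array(0, g$shape),
                 csf = array(0.4, g$shape))
  expect_false(any(csf_exclusion_mask(tissue)))       # below threshold
  tissue$csf[] <- 0.55; tissue$gm[] <- 0.45
  expect_true(all(csf_exclusion_mask(tissue)))        # above and argmax
  tissue$gm[] <- 0.60                                  # csf 0.55 not argmax
  expect_false(any(csf_exclusion_mask(tissue)))
})
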