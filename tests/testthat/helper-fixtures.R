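# Shared fixtures, built in code at test time.

# small symmetric grid used by most geometry tests
tiny_grid <- function(shape = c(20, 24, 20), vox = c(2, 2, 2))
  vox_grid(shape, vox)

# cached template brain on the default grid (built once per test run)
template_brain <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_brain(tiny_grid(), n_roi_pairs = 4, n_control_rois = 2,
                           seed = 11, roi_radius_mm = 5)
    cache
  }
})

# uniform "all grey matter" tissue with no CSF: exclusion rules become no-ops
plain_tissue <- function(grid) {
  one <- array(1, dim = grid$shape)
  zero <- array(0, dim = grid$shape)
  list(gm = one, wm = zero, csf = zero)
}

# brute-force Euclidean distance oracle: all-pairs minimum over lesion voxels
brute_force_distance <- function(lesion_mask, grid) {
  co <- grid_coords(grid)
  idx <- which(lesion_mask)
  ai <- arrayInd(idx, grid$shape)
  pts <- cbind(co[[1]][ai[, 1]], co[[2]][ai[, 2]], co[[3]][ai[, 3]])
  out <- array(Inf, dim = grid$shape)
  all_ai <- arrayInd(seq_along(out), grid$shape)
  vox <- cbind(co[[1]][all_ai[, 1]], co[[2]][all_ai[, 2]],
               co[[3]][all_ai[, 3]])
  for (k in seq_len(nrow(pts))) {
    d <- sqrt((vox[, 1] - pts[k, 1])^2 + (vox[, 2] - pts[k, 2])^2 +
                (vox[, 3] - pts[k, 3])^2)
    out <- pmin(out, array(d, dim = grid$shape))
  }
  out
}

# partial correlation via the inverse-correlation-matrix identity:
# r_xy.given.Z = -P_12 / sqrt(P_11 P_22), P = solve(cor(cbind(x, y, Z)))
partial_cor_matrix_oracle <- function(x, y, z) {
  m <- cbind(x, y, z)
  p <- solve(stats::cor(m))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# a small deterministic metrics table for group-stat tests that do not need
# images: n subjects per group, one row per subject x ROI
fake_metrics <- function(lookup, n_aphasia = 20, n_control = 20, seed = 1,
                         aphasia_shift = NULL, raw_scale_aphasia = 1) {
  set.seed(seed)
  subj <- c(sprintf("a%02d", seq_len(n_aphasia)),
            sprintf("c%02d", seq_len(n_control)))
  grp <- rep(c("aphasia", "control"), c(n_aphasia, n_control))
  rows <- list()
  for (i in seq_len(nrow(lookup))) {
    lab <- as.character(lookup$label[i])
    adj <- rnorm(length(subj), 1, 0.08)
    if (!is.null(aphasia_shift) && lab %in% names(aphasia_shift))
      adj[grp == "aphasia"] <- adj[grp == "aphasia"] + aphasia_shift[[lab]]
    raw <- adj * 30
    raw[grp == "aphasia"] <- raw[grp == "aphasia"] * raw_scale_aphasia
    rows[[i]] <- data.frame(
      subject = subj, group = grp, roi = lab, name = lookup$name[i],
      hemisphere = lookup$hemisphere[i], class = lookup$class[i],
      mean_raw = raw, mean_adjusted = adj,
      effective_voxels = 60L, lesion_load = 0, wb_mean = 30,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
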