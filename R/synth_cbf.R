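#' Ground-truth CBF field
#'
#' Composes a ground-truth perfusion volume from tissue probabilities
#' (grey-matter and white-matter baselines in the normal 35-80 and ~20
#' ml/100 g/min ranges), additive per-ROI offsets, and a multiplicative
#' perilesional gradient as a function of distance to the lesion. CBF is
#' zero inside the lesion (infarcted tissue) and in pure CSF.
#'
#' @param tissue list with `gm`, `wm`, `csf` probability arrays.
#' @param grid a [vox_grid()].
#' @param atlas integer label array (or NULL for no ROI effects).
#' @param lesion_mask logical array or NULL.
#' @param gm_baseline,GM baseline CBF, ml/100 g/min (within 35-80).
#' @param wm_baseline WM baseline CBF, ml/100 g/min.
#' @param roi_effects named numeric vector: additive CBF offset (applied in
#'   proportion to the tissue fraction GM + WM, so both cortical and deep
#'   ROIs respond) per ROI label.
#' @param peri_breaks_mm,peri_multipliers perilesional gradient: voxels with
#'   lesion distance in `(breaks[i-1], breaks[i]]` are scaled by
#'   `multipliers[i]` (each in (0, 1]); distance beyond the last break is
#'   unscaled.
#' @return CBF array (ml/100 g/min); negative values are clipped to zero
#'   with a warning.
#' @export
make_cbf_truth <- function(tissue, grid, atlas = NULL, lesion_mask = NULL,
                           gm_baseline = 55, wm_baseline = 22,
                           roi_effects = NULL,
                           peri_breaks_mm = c(5, 10, 15),
                           peri_multipliers = c(0.85, 0.95, 1.0)) {
  stopifnot(gm_baseline >= 35, gm_baseline <= 80,
            all(peri_multipliers > 0), all(peri_multipliers <= 1))
  cbf <- gm_baseline * tissue$gm + wm_baseline * tissue$wm
  if (!is.null(roi_effects) && length(roi_effects) > 0) {
    stopifnot(!is.null(atlas), all(is.finite(roi_effects)))
    for (lab in names(roi_effects)) {
      sel <- atlas == as.integer(lab)
      cbf[sel] <- cbf[sel] +
        roi_effects[[lab]] * (tissue$gm[sel] + tissue$wm[sel])
    }
  }
  if (!is.null(lesion_mask) && any(lesion_mask)) {
    d <- distance_to_lesion(lesion_mask, grid)
    lo <- c(0, peri_breaks_mm[-length(peri_breaks_mm)])
    for (i in seq_along(peri_breaks_mm)) {
      sel <- d > lo[i] & d <= peri_breaks_mm[i]
      cbf[sel] <- cbf[sel] * peri_multipliers[i]
    }
    cbf[lesion_mask] <- 0
  }
  if (any(cbf < 0)) {
    warning(sum(cbf < 0), " negative ground-truth CBF voxel(s) clipped to 0",
            call. = FALSE)
    cbf[cbf < 0] <- 0
  }
  cbf
}

#' Simulate an interleaved tag/control ASL series
#'
#' Forward model: the expected control-minus-tag difference at each voxel is
#' the single-compartment kinetic model evaluated at the ground-truth CBF,
#' i.e. `delta_m = kinetic_scale(acq) * cbf * m0`. Control volumes sit at
#' M0, tag volumes at M0 - delta_m, and independent Gaussian noise of sd
#' `noise_sd` (M0 units) is added per volume. With `noise_sd = 0` the
#' quantification inverts this exactly, including the first-control M0
#' convention.
#'
#' @param cbf_true ground-truth CBF array (ml/100 g/min).
#' @param acq an [acq_params()].
#' @param n_pairs number of tag/control pairs (>= 1).
#' @param noise_sd per-volume Gaussian noise sd in M0 units.
#' @param seed integer seed.
#' @param m0_value equilibrium magnetization level (arbitrary units).
#' @param brain_mask logical array; M0 is `m0_value` inside, a small
#'   background value outside.
#' @return list: `asl` (4D array), `m0` (3D array, returned regardless of
#'   `acq$m0_mode`), `acq`.
#' @export
simulate_asl <- function(cbf_true, acq, n_pairs = 20, noise_sd = 0, seed = 1,
                         m0_value = 1000, brain_mask = NULL) {
  stopifnot(n_pairs >= 1, noise_sd >= 0)
  sh <- dim(cbf_true)
  m0 <- array(m0_value, dim = sh)
  if (!is.null(brain_mask)) m0[!brain_mask] <- m0_value * 0.02
  delta <- kinetic_scale(acq) * cbf_true * m0
  tag <- m0 - delta
  ctrl <- m0
  series <- array(0, dim = c(sh, 2L * n_pairs))
  for (p in seq_len(n_pairs)) {
    if (acq$pair_order == "tag_first") {
      series[, , , 2L * p - 1L] <- tag
      series[, , , 2L * p] <- ctrl
    } else {
      series[, , , 2L * p - 1L] <- ctrl
      series[, , , 2L * p] <- tag
    }
  }
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    series <- series + array(rng$rnorm(length(series), 0, noise_sd),
                             dim = dim(series))
  }
  list(asl = series, m0 = m0, acq = acq)
}
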