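#' ASL acquisition parameters
#'
#' Constants of the single-compartment pseudo-continuous ASL kinetic model.
#' All times are milliseconds on the interface; conversion to seconds happens
#' inside the quantification equation. The two bundled presets mirror common
#' clinical protocols: `site_a` (labelling 1470 ms, post-label delay 1500 ms,
#' first control volume used as the M0 calibration image) and `site_b`
#' (labelling 1800 ms, delay 2000 ms, separate M0 volume).
#'
#' @param alpha labelling efficiency, in (0, 1].
#' @param t1_blood longitudinal relaxation time of arterial blood, ms.
#' @param tau label duration, ms.
#' @param pld post-labelling delay, ms.
#' @param lambda_p blood-brain partition coefficient, ml/g.
#' @param m0_mode `"separate_volume"` or `"first_control"`.
#' @param pair_order `"tag_first"` or `"control_first"` within each pair.
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(alpha = 0.72, t1_blood = 1650, tau = 1470, pld = 1500,
                       lambda_p = 0.9,
                       m0_mode = c("first_control", "separate_volume"),
                       pair_order = c("tag_first", "control_first")) {
  m0_mode <- match.arg(m0_mode)
  pair_order <- match.arg(pair_order)
  stopifnot(alpha > 0, alpha <= 1, t1_blood > 0, tau > 0, pld > 0,
            lambda_p > 0)
  structure(list(alpha = alpha, t1_blood = t1_blood, tau = tau, pld = pld,
                 lambda_p = lambda_p, m0_mode = m0_mode,
                 pair_order = pair_order),
            class = "acq_params")
}

#' @rdname acq_params
#' @param site `"site_a"` or `"site_b"`.
#' @export
acq_preset <- function(site = c("site_a", "site_b")) {
  switch(match.arg(site),
         site_a = acq_params(tau = 1470, pld = 1500,
                             m0_mode = "first_control"),
         site_b = acq_params(tau = 1800, pld = 2000,
                             m0_mode = "separate_volume"))
}

# Scale factor k such that delta_m = k * cbf * m0, from the single-compartment
# single-PLD model. Shared by the forward simulator and the inverse
# quantification so the round trip is exact by construction of the algebra,
# not by cancellation of implementation quirks.
kinetic_scale <- function(acq) {
  t1b_s <- acq$t1_blood / 1000
  (2 * acq$alpha * t1b_s * (1 - exp(-acq$tau / acq$t1_blood))) /
    (6000 * acq$lambda_p * exp(acq$pld / acq$t1_blood))
}

#' Mean tag/control difference of an interleaved ASL series
#'
#' @param series 4D array, volumes interleaved in tag/control pairs.
#' @param acq an [acq_params()]; `pair_order` decides which of each pair is
#'   the tag.
#' @return 3D array, the mean over pairs of (control - tag).
#' @export
mean_difference <- function(series, acq) {
  stopifnot(length(dim(series)) == 4)
  nt <- dim(series)[4]
  if (nt %% 2 != 0)
    stop("ASL series has an odd number of volumes (", nt,
         "); tag/control pairs are incomplete", call. = FALSE)
  odd <- series[, , , seq(1, nt, by = 2), drop = FALSE]
  even <- series[, , , seq(2, nt, by = 2), drop = FALSE]
  d <- if (acq$pair_order == "tag_first") even - odd else odd - even
  apply_mean4 <- function(x) {
    if (dim(x)[4] == 1) return(array(x, dim = dim(x)[1:3]))
    array(rowMeans(matrix(x, ncol = dim(x)[4])), dim = dim(x)[1:3])
  }
  apply_mean4(d)
}

#' Resolve the M0 calibration volume
#'
#' Returns the equilibrium-magnetization image used to scale the ASL
#' difference signal: either a separately acquired M0 volume, or the first
#' control image of the series for protocols that did not acquire one.
#'
#' @param series 4D ASL array.
#' @param acq an [acq_params()].
#' @param m0_volume optional 3D M0 array (required when
#'   `acq$m0_mode == "separate_volume"`).
#' @return 3D M0 array.
#' @export
resolve_m0 <- function(series, acq, m0_volume = NULL) {
  if (acq$m0_mode == "separate_volume") {
    if (is.null(m0_volume))
      stop("acq$m0_mode is 'separate_volume' but no m0_volume was supplied",
           call. = FALSE)
    return(m0_volume)
  }
  stopifnot(length(dim(series)) == 4, dim(series)[4] >= 2)
  first_control_index <- if (acq$pair_order == "tag_first") 2L else 1L
  array(series[, , , first_control_index], dim = dim(series)[1:3])
}

#' Quantify cerebral blood flow from an ASL difference image
#'
#' Voxelwise closed-form evaluation of the single-compartment, single-delay
#' kinetic model:
#' \deqn{CBF = \frac{6000\,\lambda_p\,\Delta M\,e^{PLD/T_{1b}}}
#'   {2\,\alpha\,T_{1b}[s]\,M_0\,(1 - e^{-\tau/T_{1b}})}}
#' in ml/100 g/min. No smoothing and no partial-volume correction are
#' applied. Negative values are retained (one-sided truncation would bias
#' ROI means); the attribute `n_negative` counts them inside the mask.
#' Voxels with non-positive M0 inside the brain mask are set to 0 and
#' counted in attribute `n_bad_m0`.
#'
#' @param delta_m 3D mean difference array (control - tag).
#' @param m0 3D calibration array.
#' @param acq an [acq_params()].
#' @param brain_mask logical 3D array; voxels outside are set to 0.
#' @param m0_epsilon M0 values at or below this are treated as unusable.
#' @return 3D CBF array (ml/100 g/min) with attributes `n_negative`,
#'   `n_bad_m0` and `acq`.
#' @export
quantify_cbf <- function(delta_m, m0, acq, brain_mask,
                         m0_epsilon = 1e-6) {
  if (!identical(dim(delta_m), dim(m0)) ||
      !identical(dim(delta_m), dim(brain_mask)))
    stop("delta_m, m0 and brain_mask must share one grid", call. = FALSE)
  mask <- brain_mask & is.finite(m0) & (m0 > m0_epsilon)
  n_bad_m0 <- sum(brain_mask) - sum(mask)
  cbf <- array(0, dim = dim(delta_m))
  cbf[mask] <- delta_m[mask] / (kinetic_scale(acq) * m0[mask])
  attr(cbf, "n_negative") <- sum(cbf[mask] < 0)
  attr(cbf, "n_bad_m0") <- n_bad_m0
  attr(cbf, "acq") <- acq
  cbf
}
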