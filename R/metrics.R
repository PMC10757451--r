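#' ROI mean perfusion
#'
#' @param cbf 3D CBF array.
#' @param effective_mask logical array of the voxels to average.
#' @return arithmetic mean over the mask, or `NA_real_` (with a warning)
#'   when the mask is empty.
#' @export
roi_mean <- function(cbf, effective_mask) {
  n <- sum(effective_mask)
  if (n == 0) {
    warning("empty effective mask; ROI mean undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(cbf[effective_mask])
}

#' Whole-brain mean perfusion with the lesion masked
#'
#' By default the mean runs over the full brain mask (CSF included, only the
#' lesion masked); pass `csf_mask` to exclude CSF as well.
#'
#' @param cbf 3D CBF array.
#' @param brain_mask logical array.
#' @param lesion_mask logical array or NULL (controls).
#' @param csf_mask optional logical array of CSF voxels to exclude.
#' @return mean CBF over in-brain, non-lesioned voxels.
#' @export
whole_brain_mean <- function(cbf, brain_mask, lesion_mask = NULL,
                             csf_mask = NULL) {
  support <- brain_mask
  if (!is.null(lesion_mask)) support <- support & !lesion_mask
  if (!is.null(csf_mask)) support <- support & !csf_mask
  if (!any(support))
    stop("no voxels left in brain mask after lesion masking", call. = FALSE)
  mean(cbf[support])
}

#' Whole-brain normalization of ROI means
#'
#' Divides raw ROI means by the subject's whole-brain mean, removing
#' session- and scanner-specific scale (tagging-efficiency variability).
#'
#' @param mean_raw numeric vector of raw ROI means (NA allowed).
#' @param wb_mean the subject's whole-brain mean (> 0).
#' @return vector of adjusted (dimensionless) perfusion values.
#' @export
adjust_perfusion <- function(mean_raw, wb_mean) {
  if (!is.finite(wb_mean) || wb_mean <= 0)
    stop("whole-brain mean must be positive, got ", wb_mean, call. = FALSE)
  mean_raw / wb_mean
}

#' Right-minus-left perfusion asymmetry
#'
#' @param adjusted_right,adjusted_left adjusted perfusion of a homologous
#'   ROI pair.
#' @return right - left, or NA when either side is missing.
#' @export
asymmetry <- function(adjusted_right, adjusted_left) {
  ifelse(is.na(adjusted_right) | is.na(adjusted_left), NA_real_,
         adjusted_right - adjusted_left)
}

#' Per-subject ROI perfusion table
#'
#' Runs quantification (if given a raw series) or takes a CBF map, prepares
#' effective atlas ROIs and, when a lesion is present, the perilesional
#' bands, and returns one row per ROI with raw and adjusted means.
#'
#' @param cbf 3D CBF array.
#' @param grid a [vox_grid()].
#' @param atlas integer label array.
#' @param lookup atlas lookup data.frame (see [prepare_atlas_rois()]).
#' @param brain_mask logical array.
#' @param tissue tissue probability list.
#' @param lesion_mask logical array or NULL.
#' @param csf_threshold CSF exclusion threshold.
#' @return data.frame: roi (label or band name), name, hemisphere, class,
#'   mean_raw, mean_adjusted, effective_voxels, lesion_load, wb_mean.
#' @export
subject_roi_metrics <- function(cbf, grid, atlas, lookup, brain_mask, tissue,
                                lesion_mask = NULL, csf_threshold = 0.5) {
  prep <- prepare_atlas_rois(atlas, lookup, brain_mask, tissue,
                             lesion_mask, csf_threshold)
  wb <- whole_brain_mean(cbf, brain_mask, lesion_mask)
  tab <- prep$table
  tab$mean_raw <- vapply(as.character(tab$roi), function(lab) {
    m <- prep$masks[[lab]]
    if (sum(m) == 0) NA_real_ else mean(cbf[m])
  }, numeric(1))
  if (!is.null(lesion_mask) && any(lesion_mask)) {
    bands <- perilesional_bands(lesion_mask, brain_mask, tissue, grid,
                                csf_threshold = csf_threshold)
    btab <- data.frame(
      roi = names(bands), name = names(bands), hemisphere = "ipsilesional",
      class = "perilesional",
      original_voxels = vapply(bands, sum, integer(1)),
      effective_voxels = vapply(bands, sum, integer(1)),
      lesion_load = 0)
    btab$mean_raw <- vapply(bands, function(m)
      if (sum(m) == 0) NA_real_ else mean(cbf[m]), numeric(1))
    tab$roi <- as.character(tab$roi)
    tab <- rbind(tab, btab)
  } else {
    tab$roi <- as.character(tab$roi)
  }
  tab$mean_adjusted <- adjust_perfusion(tab$mean_raw, wb)
  tab$wb_mean <- wb
  rownames(tab) <- NULL
  tab
}

#' Long-format cohort metrics table
#'
#' Applies [subject_roi_metrics()] to every subject of an in-memory cohort
#' (as produced by [simulate_cohort()] or [validate_and_load()]) after
#' quantifying each subject's ASL series.
#'
#' @param cohort a cohort bundle: list with `subjects` (per-subject volume
#'   bundles), `grid`, `atlas`, `lookup`, and `table` (the cohort CSV).
#' @param csf_threshold CSF exclusion threshold.
#' @return data.frame with one row per subject x ROI, including subject id
#'   and group.
#' @export
cohort_metrics <- function(cohort, csf_threshold = 0.5) {
  rows <- lapply(cohort$subjects, function(s) {
    acq <- s$acq
    dm <- mean_difference(s$asl, acq)
    m0 <- resolve_m0(s$asl, acq, s$m0)
    cbf <- quantify_cbf(dm, m0, acq, s$brain_mask)
    tab <- subject_roi_metrics(cbf, cohort$grid, cohort$atlas, cohort$lookup,
                               s$brain_mask, s$tissue, s$lesion,
                               csf_threshold)
    tab$subject <- s$id
    tab
  })
  out <- do.call(rbind, rows)
  out <- merge(out, cohort$table[, c("id", "group")],
               by.x = "subject", by.y = "id", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Homologous right-minus-left asymmetry table
#'
#' @param metrics long metrics table from [cohort_metrics()].
#' @param lookup atlas lookup data.frame.
#' @return data.frame: subject, group, pair (left label), name, asymmetry.
#' @export
asymmetry_table <- function(metrics, lookup) {
  left <- lookup[lookup$hemisphere == "L", ]
  rows <- lapply(seq_len(nrow(left)), function(i) {
    l <- as.character(left$label[i]); r <- as.character(left$homologue[i])
    ml <- metrics[metrics$roi == l, c("subject", "group", "mean_adjusted")]
    mr <- metrics[metrics$roi == r, c("subject", "mean_adjusted")]
    m <- merge(ml, mr, by = "subject", suffixes = c("_left", "_right"))
    data.frame(subject = m$subject, group = m$group, pair = l,
               name = left$name[i],
               asymmetry = asymmetry(m$mean_adjusted_right,
                                     m$mean_adjusted_left))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
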