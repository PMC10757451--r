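#' Covariate-adjusted partial correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares projection on an intercept plus the covariate matrix.
#' The two-tailed p-value uses `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k` where k is the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k) or NULL/0-column for a plain
#'   Pearson correlation.
#' @return list: r, p_value, n, df, plus `degenerate` message when a
#'   residual is (numerically) constant.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  k <- ncol(covariates)
  ok <- is.finite(x) & is.finite(y) &
    (if (k > 0) apply(is.finite(covariates), 1, all) else TRUE)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2)
    stop("need n > #covariates + 2 complete cases (n = ", n, ", k = ", k,
         ")", call. = FALSE)
  design <- cbind(intercept = 1, covariates)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)),
                                    qd$pivot[seq_len(qd$rank)])]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  df <- n - 2 - k
  tiny <- 1e-12 * max(1, stats::sd(x), stats::sd(y))
  if (stats::sd(rx) <= tiny || stats::sd(ry) <= tiny) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, df = df,
                degenerate = "residual variance ~ 0 after projection"))
  }
  r <- stats::cor(rx, ry)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  list(r = r, p_value = p, n = n, df = df)
}

#' Partial-correlation grid between ROI perfusion and language scores
#'
#' For every ROI (left atlas ROIs and perilesional bands by default) and
#' every WAB outcome, computes the partial correlation between adjusted
#' perfusion and the score in the aphasia group, controlling for age, sex,
#' months post-onset, scanning site and lesion volume
#' (`covariate_set = "lesion_volume"`), optionally adding the ROI's own
#' lesion load (`covariate_set = "lesion_volume_and_load"`; skipped for
#' perilesional bands, which are lesion-free by construction). Cells are
#' flagged at the Bonferroni threshold `family_alpha / m` with m the number
#' of atlas ROIs per hemisphere. Missing scores are excluded pairwise; each
#' cell reports its own n.
#'
#' @param metrics long metrics table from [cohort_metrics()].
#' @param cohort_table cohort data.frame (one row per subject).
#' @param lookup atlas lookup data.frame.
#' @param covariate_set `"lesion_volume"` or `"lesion_volume_and_load"`.
#' @param outcomes character vector of score columns.
#' @param hemisphere `"L"` (default, plus perilesional bands) or `"R"`
#'   (right-hemisphere null check, no bands).
#' @param family_alpha family-wise alpha.
#' @return data.frame: roi, name, class, outcome, r, p_value, n, df,
#'   covariate_set, bonferroni_threshold, significant.
#' @export
correlate_language <- function(metrics, cohort_table, lookup,
                               covariate_set = c("lesion_volume",
                                                 "lesion_volume_and_load"),
                               outcomes = c("information_content", "fluency",
                                            "repetition", "naming",
                                            "auditory_comprehension", "aq"),
                               hemisphere = "L",
                               family_alpha = 0.05) {
  covariate_set <- match.arg(covariate_set)
  m_per_hemi <- sum(lookup$hemisphere == "L")
  thr <- bonferroni_threshold(family_alpha, m_per_hemi)
  aph <- cohort_table[cohort_table$group == "aphasia", ]
  met <- metrics[metrics$group == "aphasia", ]

  rois <- lookup[lookup$hemisphere == hemisphere,
                 c("label", "name", "class")]
  rois$roi <- as.character(rois$label)
  if (hemisphere == "L") {
    peri <- unique(met$roi[met$class == "perilesional"])
    if (length(peri))
      rois <- rbind(rois, data.frame(label = NA, name = peri,
                                     class = "perilesional", roi = peri))
  }

  base_cov <- function(tab)
    cbind(age = tab$age, sex_m = as.numeric(tab$sex == "M"),
          months_post_onset = tab$months_post_onset,
          site_b = as.numeric(tab$site == "B"),
          lesion_volume = tab$lesion_volume)

  out <- list()
  for (i in seq_len(nrow(rois))) {
    sub <- met[met$roi == rois$roi[i],
               c("subject", "mean_adjusted", "lesion_load")]
    tab <- merge(aph, sub, by.x = "id", by.y = "subject", sort = TRUE)
    covs <- base_cov(tab)
    if (covariate_set == "lesion_volume_and_load" &&
        rois$class[i] != "perilesional" &&
        stats::sd(tab$lesion_load, na.rm = TRUE) > 0)
      # a lesion load that never varies (e.g. a never-lesioned control ROI)
      # carries no information and would make the projection rank deficient
      covs <- cbind(covs, roi_lesion_load = tab$lesion_load)
    for (o in outcomes) {
      pc <- tryCatch(
        partial_correlation(tab$mean_adjusted, tab[[o]], covs),
        error = function(e)
          list(r = NA_real_, p_value = NA_real_,
               n = sum(is.finite(tab$mean_adjusted) & is.finite(tab[[o]])),
               df = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        roi = rois$roi[i], name = rois$name[i], class = rois$class[i],
        outcome = o, r = pc$r, p_value = pc$p_value, n = pc$n, df = pc$df,
        covariate_set = covariate_set, bonferroni_threshold = thr,
        significant = is.finite(pc$p_value) && pc$p_value < thr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
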