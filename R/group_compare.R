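#' Group comparison of perfusion for every atlas ROI
#'
#' Runs the test cascade (see [select_two_sample_test()]) per ROI and
#' measure (raw and adjusted perfusion) comparing the aphasia and control
#' groups, and flags significance at the Bonferroni threshold
#' `family_alpha / m`, where m is the number of atlas ROIs per hemisphere.
#' ROIs missing (empty effective mask) in more than half of either group are
#' excluded with a warning; within a retained ROI, subjects with a missing
#' value are dropped pairwise.
#'
#' @param metrics long metrics table from [cohort_metrics()].
#' @param lookup atlas lookup data.frame.
#' @param family_alpha family-wise alpha (default 0.05).
#' @param gate_alpha alpha for the cascade gates.
#' @return data.frame: roi, name, hemisphere, class, measure, test,
#'   statistic, df, p_value, n_aphasia, n_control, bonferroni_threshold,
#'   significant.
#' @export
compare_groups_all_rois <- function(metrics, lookup, family_alpha = 0.05,
                                    gate_alpha = 0.05) {
  m_per_hemi <- sum(lookup$hemisphere == "L")
  thr <- bonferroni_threshold(family_alpha, m_per_hemi)
  atlas_rows <- metrics[metrics$class != "perilesional", ]
  out <- list()
  for (lab in as.character(lookup$label)) {
    sub <- atlas_rows[atlas_rows$roi == lab, ]
    info <- lookup[lookup$label == as.integer(lab), ]
    for (measure in c("mean_raw", "mean_adjusted")) {
      a <- sub[[measure]][sub$group == "aphasia"]
      c_ <- sub[[measure]][sub$group == "control"]
      miss_a <- mean(!is.finite(a)); miss_c <- mean(!is.finite(c_))
      if (miss_a > 0.5 || miss_c > 0.5) {
        warning("ROI ", lab, " missing in >50% of a group; excluded",
                call. = FALSE)
        next
      }
      tr <- select_two_sample_test(a, c_, gate_alpha)
      out[[length(out) + 1L]] <- data.frame(
        roi = lab, name = info$name, hemisphere = info$hemisphere,
        class = info$class,
        measure = if (measure == "mean_raw") "raw" else "adjusted",
        test = tr$test_name, statistic = tr$statistic, df = tr$df,
        p_value = tr$p_value, n_aphasia = tr$n[1], n_control = tr$n[2],
        bonferroni_threshold = thr,
        significant = is.finite(tr$p_value) && tr$p_value < thr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired left-versus-right comparisons of homologous ROIs
#'
#' For each homologous pair and group, tests whether adjusted perfusion
#' differs between hemispheres with the normality-gated paired test on the
#' within-subject left-minus-right differences.
#'
#' @param metrics long metrics table.
#' @param lookup atlas lookup data.frame.
#' @param family_alpha,gate_alpha as in [compare_groups_all_rois()].
#' @return data.frame: pair, name, group, test, statistic, df, p_value,
#'   n, bonferroni_threshold, significant.
#' @export
compare_left_right <- function(metrics, lookup, family_alpha = 0.05,
                               gate_alpha = 0.05) {
  left <- lookup[lookup$hemisphere == "L", ]
  thr <- bonferroni_threshold(family_alpha, nrow(left))
  out <- list()
  for (i in seq_len(nrow(left))) {
    l <- as.character(left$label[i]); r <- as.character(left$homologue[i])
    ml <- metrics[metrics$roi == l, c("subject", "group", "mean_adjusted")]
    mr <- metrics[metrics$roi == r, c("subject", "mean_adjusted")]
    mm <- merge(ml, mr, by = "subject", suffixes = c("_L", "_R"))
    for (g in unique(mm$group)) {
      d <- mm$mean_adjusted_L[mm$group == g] - mm$mean_adjusted_R[mm$group == g]
      d <- d[is.finite(d)]
      if (length(d) < 3) next
      tr <- select_paired_test(d, gate_alpha)
      out[[length(out) + 1L]] <- data.frame(
        pair = l, name = left$name[i], group = g, test = tr$test_name,
        statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
        n = tr$n, bonferroni_threshold = thr,
        significant = is.finite(tr$p_value) && tr$p_value < thr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group comparison of hemispheric asymmetry
#'
#' Compares the right-minus-left adjusted perfusion asymmetry of every
#' homologous pair between groups with the two-sample cascade.
#'
#' @inheritParams compare_left_right
#' @return data.frame as in [compare_groups_all_rois()], keyed by pair.
#' @export
compare_asymmetry <- function(metrics, lookup, family_alpha = 0.05,
                              gate_alpha = 0.05) {
  asym <- asymmetry_table(metrics, lookup)
  pairs <- unique(asym$pair)
  thr <- bonferroni_threshold(family_alpha, length(pairs))
  out <- list()
  for (p in pairs) {
    sub <- asym[asym$pair == p, ]
    a <- sub$asymmetry[sub$group == "aphasia"]
    c_ <- sub$asymmetry[sub$group == "control"]
    a <- a[is.finite(a)]; c_ <- c_[is.finite(c_)]
    if (length(a) < 3 || length(c_) < 3) next
    tr <- select_two_sample_test(a, c_, gate_alpha)
    out[[length(out) + 1L]] <- data.frame(
      pair = p, name = sub$name[1], test = tr$test_name,
      statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
      n_aphasia = tr$n[1], n_control = tr$n[2],
      bonferroni_threshold = thr,
      significant = is.finite(tr$p_value) && tr$p_value < thr,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lesioned-versus-spared comparison for one ROI
#'
#' Splits the aphasia group by lesion status of a left ROI (lesion load > 0
#' versus = 0) and compares adjusted perfusion between the two subgroups in
#' that ROI and in its right homologue.
#'
#' @param roi left-hemisphere ROI label.
#' @param metrics long metrics table.
#' @param lookup atlas lookup data.frame.
#' @param gate_alpha cascade gate alpha.
#' @param min_n minimal subgroup size (results withheld below).
#' @return list with elements `left` and `right`, each a `perfband_test` or
#'   NULL when a subgroup is empty/too small, plus `n_lesioned`,
#'   `n_spared`.
#' @export
lesioned_vs_spared <- function(roi, metrics, lookup, gate_alpha = 0.05,
                               min_n = 3) {
  lab <- as.character(roi)
  info <- lookup[lookup$label == as.integer(lab), ]
  if (nrow(info) != 1 || info$hemisphere != "L")
    stop("roi must be a left-hemisphere atlas label", call. = FALSE)
  aph <- metrics[metrics$group == "aphasia", ]
  left <- aph[aph$roi == lab, ]
  lesioned_ids <- left$subject[left$lesion_load > 0]
  spared_ids <- left$subject[left$lesion_load == 0]
  if (length(lesioned_ids) == 0 || length(spared_ids) == 0)
    stop("lesioned/spared split is empty for ROI ", lab, call. = FALSE)
  run_side <- function(side_lab) {
    sub <- aph[aph$roi == side_lab, ]
    x <- sub$mean_adjusted[sub$subject %in% lesioned_ids]
    y <- sub$mean_adjusted[sub$subject %in% spared_ids]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < min_n || length(y) < min_n) return(NULL)
    select_two_sample_test(x, y, gate_alpha)
  }
  list(left = run_side(lab),
       right = run_side(as.character(info$homologue)),
       n_lesioned = length(lesioned_ids), n_spared = length(spared_ids))
}

#' Spearman correlations between adjusted perfusion and lesion load
#'
#' One correlation per left atlas ROI across the aphasia group.
#'
#' @param metrics long metrics table.
#' @param lookup atlas lookup data.frame.
#' @return data.frame: roi, name, rho, p_value, n.
#' @export
lesionload_correlations <- function(metrics, lookup) {
  left <- lookup[lookup$hemisphere == "L", ]
  aph <- metrics[metrics$group == "aphasia", ]
  out <- lapply(seq_len(nrow(left)), function(i) {
    sub <- aph[aph$roi == as.character(left$label[i]), ]
    tr <- spearman_lesionload(sub$mean_adjusted, sub$lesion_load)
    data.frame(roi = as.character(left$label[i]), name = left$name[i],
               rho = tr$statistic, p_value = tr$p_value, n = tr$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired comparisons between perilesional bands
#'
#' Tests, within the aphasia group, whether adjusted perfusion in each band
#' is lower than in the next more distant band (0-5 vs 5-10, 5-10 vs 10-15)
#' and whether each band differs from the whole-brain level (adjusted value
#' 1 by construction), using the normality-gated paired test.
#'
#' @param metrics long metrics table.
#' @param gate_alpha cascade gate alpha.
#' @return data.frame: comparison, mean_1, mean_2, test, statistic, df,
#'   p_value, n.
#' @export
compare_perilesional_bands <- function(metrics, gate_alpha = 0.05) {
  peri <- metrics[metrics$class == "perilesional", ]
  bands <- unique(peri$roi)
  wide <- stats::reshape(
    peri[, c("subject", "roi", "mean_adjusted")],
    idvar = "subject", timevar = "roi", direction = "wide")
  names(wide) <- sub("^mean_adjusted\\.", "", names(wide))
  out <- list()
  add <- function(name, d, m1, m2) {
    d <- d[is.finite(d)]
    if (length(d) < 3) return()
    tr <- select_paired_test(d, gate_alpha)
    out[[length(out) + 1L]] <<- data.frame(
      comparison = name, mean_1 = m1, mean_2 = m2, test = tr$test_name,
      statistic = tr$statistic, df = tr$df, p_value = tr$p_value, n = tr$n,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(length(bands) - 1)) {
    b1 <- wide[[bands[i]]]; b2 <- wide[[bands[i + 1]]]
    add(paste(bands[i], "vs", bands[i + 1]), b1 - b2,
        mean(b1, na.rm = TRUE), mean(b2, na.rm = TRUE))
  }
  for (b in bands)
    add(paste(b, "vs whole-brain"), wide[[b]] - 1,
        mean(wide[[b]], na.rm = TRUE), 1)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
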