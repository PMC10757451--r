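#' Normality-gated two-sample test cascade
#'
#' Implements the test-selection cascade used for every between-group
#' comparison: Shapiro-Wilk normality check in each group; if both pass, an
#' F-test of variance homogeneity decides between the pooled-variance t-test
#' and Welch's unequal-variance t-test; if either group fails normality, the
#' two-sample Wilcoxon rank-sum test is used. All tests are two-tailed. The
#' returned `decision_trace` records every gate evaluated so the choice is
#' fully auditable and deterministic.
#'
#' @param x,y numeric samples (each of length >= 3).
#' @param gate_alpha alpha for the Shapiro and F gates (default 0.05).
#' @return a `perfband_test` list: test_name, statistic, df, p_value,
#'   n (per group), decision_trace.
#' @export
select_two_sample_test <- function(x, y, gate_alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs at least 3 finite values for the cascade",
         call. = FALSE)
  trace <- list(gate_alpha = gate_alpha)

  sw <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)  # Shapiro undefined: constant
    stats::shapiro.test(v)$p.value
  }
  trace$shapiro_x <- sw(x)
  trace$shapiro_y <- sw(y)
  normal_x <- is.finite(trace$shapiro_x) && trace$shapiro_x > gate_alpha
  normal_y <- is.finite(trace$shapiro_y) && trace$shapiro_y > gate_alpha

  if (identical(x, y) || (stats::sd(c(x, y)) == 0)) {
    # identical or fully degenerate samples: no evidence of a difference
    res <- if (normal_x && normal_y && stats::sd(x) > 0) {
      trace$f_test <- stats::var.test(x, y)$p.value
      tt <- stats::t.test(x, y, var.equal = TRUE)
      list(test_name = "t", statistic = unname(tt$statistic),
           df = unname(tt$parameter), p_value = tt$p.value)
    } else {
      list(test_name = "degenerate", statistic = 0, df = NA_real_,
           p_value = 1)
    }
    return(new_test_result(res, c(length(x), length(y)), trace))
  }

  if (normal_x && normal_y) {
    ft <- stats::var.test(x, y)
    trace$f_test <- ft$p.value
    if (ft$p.value > gate_alpha) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      res <- list(test_name = "t", statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      res <- list(test_name = "welch", statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value)
    }
  } else {
    res <- wilcoxon_two_sample(x, y)
  }
  new_test_result(res, c(length(x), length(y)), trace)
}

# Rank-sum test with the exact distribution for small samples (combined
# n <= 25, no ties) and the normal approximation with continuity correction
# otherwise.
wilcoxon_two_sample <- function(x, y) {
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(test_name = "wilcoxon_rank", statistic = unname(wt$statistic),
       df = NA_real_, p_value = wt$p.value)
}

new_test_result <- function(res, n, trace) {
  structure(c(res, list(n = n, decision_trace = trace)),
            class = "perfband_test")
}

#' @export
print.perfband_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (n = %s)\n",
              x$test_name, x$statistic,
              ifelse(is.na(x$df), "-", format(x$df, digits = 4)),
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Normality-gated paired test
#'
#' Shapiro-Wilk on the paired differences gates the paired t-test versus the
#' Wilcoxon signed-rank test. Zero-variance differences yield a flagged
#' degenerate result (statistic undefined, p = 1 by convention).
#'
#' @param differences numeric vector of paired differences (length >= 3).
#' @param gate_alpha alpha for the Shapiro gate.
#' @return a `perfband_test`.
#' @export
select_paired_test <- function(differences, gate_alpha = 0.05) {
  d <- differences[is.finite(differences)]
  if (length(d) < 3)
    stop("need at least 3 finite paired differences", call. = FALSE)
  trace <- list(gate_alpha = gate_alpha)
  if (stats::sd(d) == 0) {
    trace$degenerate <- "zero-variance differences"
    return(new_test_result(
      list(test_name = "degenerate", statistic = NA_real_, df = NA_real_,
           p_value = 1), length(d), trace))
  }
  trace$shapiro_d <- stats::shapiro.test(d)$p.value
  if (trace$shapiro_d > gate_alpha) {
    tt <- stats::t.test(d)
    res <- list(test_name = "paired_t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    ties <- any(duplicated(abs(d[d != 0]))) || any(d == 0)
    exact <- length(d) <= 25 && !ties
    wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                              correct = TRUE))
    res <- list(test_name = "paired_wilcoxon",
                statistic = unname(wt$statistic),
                df = NA_real_, p_value = wt$p.value)
  }
  new_test_result(res, length(d), trace)
}

#' Bonferroni per-test threshold
#'
#' @param family_alpha family-wise alpha.
#' @param m number of comparisons (>= 1).
#' @return `family_alpha / m` (e.g. 0.05/15 = 0.0033).
#' @export
bonferroni_threshold <- function(family_alpha, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  family_alpha / m
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Without continuity correction (df = 1).
#'
#' @param table 2x2 matrix of counts.
#' @return a `perfband_test`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a marginal total is zero", call. = FALSE)
  ct <- stats::chisq.test(table, correct = FALSE)
  new_test_result(
    list(test_name = "chi_square", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value),
    sum(table), list(expected = ct$expected))
}

#' Spearman correlation between perfusion and lesion load
#'
#' Tie-aware (midrank) Spearman rho with a two-tailed p-value from the
#' t approximation (appropriate with ties).
#'
#' @param perfusion,lesion_load paired numeric vectors (n >= 4).
#' @return a `perfband_test` with the estimate in `statistic` and rho also
#'   stored in `decision_trace$rho`.
#' @export
spearman_lesionload <- function(perfusion, lesion_load) {
  ok <- is.finite(perfusion) & is.finite(lesion_load)
  x <- perfusion[ok]; y <- lesion_load[ok]
  if (length(x) < 4)
    stop("need at least 4 complete pairs for a Spearman correlation",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_test_result(
      list(test_name = "spearman", statistic = NA_real_, df = NA_real_,
           p_value = NA_real_), length(x),
      list(degenerate = "constant input, rho undefined")))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  new_test_result(
    list(test_name = "spearman", statistic = unname(ct$estimate),
         df = length(x) - 2, p_value = ct$p.value),
    length(x), list(rho = unname(ct$estimate), S = unname(ct$statistic)))
}
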