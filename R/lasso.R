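#' Standardize a design matrix
#'
#' Centres each column to mean 0 and scales to sample (n-1 denominator)
#' standard deviation 1. Constant columns are dropped with a warning; their
#' names are recorded in the `dropped` attribute.
#'
#' @param design numeric matrix.
#' @return list: `x` (standardized matrix), `centers`, `scales`, `dropped`.
#' @export
standardize <- function(design) {
  design <- as.matrix(design)
  centers <- colMeans(design)
  scales <- apply(design, 2, stats::sd)
  const <- !is.finite(scales) | scales == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(design)[const], collapse = ", "), call. = FALSE)
  }
  x <- sweep(design[, !const, drop = FALSE], 2, centers[!const], "-")
  x <- sweep(x, 2, scales[!const], "/")
  list(x = x, centers = centers[!const], scales = scales[!const],
       dropped = colnames(design)[const])
}

#' Lasso coefficient path by coordinate descent
#'
#' Solves, for each penalty on a strictly decreasing grid,
#' \deqn{\min_{\beta_0,\beta} \frac{1}{2n}\|y - \beta_0 - X\beta\|_2^2 +
#'   \lambda \|\beta\|_1}
#' by cyclic coordinate descent on the Gram-matrix sufficient statistics
#' with warm starts along the grid. `X` is expected standardized; the
#' intercept is then the mean of `y` throughout. Convergence is run to a
#' tight tolerance so the KKT subgradient conditions hold to ~1e-7.
#'
#' @param x standardized design matrix (n x p).
#' @param y outcome vector.
#' @param lambda_grid strictly decreasing penalty grid.
#' @param tol coordinate-update convergence tolerance.
#' @param max_iter maximal sweeps per lambda.
#' @return list: `beta` (p x length(grid) matrix), `intercept` (scalar,
#'   mean of y), `lambda` (the grid).
#' @export
lasso_path <- function(x, y, lambda_grid, tol = 1e-11, max_iter = 100000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in the lasso design or outcome", call. = FALSE)
  if (length(lambda_grid) > 1 && any(diff(lambda_grid) >= 0))
    stop("lambda_grid must be strictly decreasing", call. = FALSE)
  n <- nrow(x)
  b0 <- mean(y)
  xty <- as.numeric(crossprod(x, y - b0)) / n
  gram <- crossprod(x) / n
  out <- .cd_lasso_path(gram, xty, as.numeric(lambda_grid), tol,
                        as.integer(max_iter))
  dimnames(out) <- list(colnames(x), NULL)
  list(beta = out, intercept = b0, lambda = lambda_grid)
}

#' KKT residuals of a lasso solution
#'
#' For each coefficient, the violation of the subgradient optimality
#' condition of the 1/(2n) lasso objective: for active coefficients
#' `|<x_j, r>/n - lambda * sign(beta_j)|`, for inactive ones
#' `max(0, |<x_j, r>/n| - lambda)`.
#'
#' @param x standardized design, `y` outcome, `beta` coefficient vector,
#'   `intercept` fitted intercept, `lambda` penalty.
#' @param y,beta,intercept,lambda see above.
#' @return numeric vector of per-coefficient violations.
#' @export
lasso_kkt <- function(x, y, beta, intercept, lambda) {
  n <- nrow(x)
  r <- y - intercept - as.vector(x %*% beta)
  g <- as.vector(crossprod(x, r)) / n
  ifelse(beta != 0, abs(g - lambda * sign(beta)),
         pmax(0, abs(g) - lambda))
}

#' Default penalty grid
#'
#' Log-spaced from the smallest penalty that zeroes every coefficient
#' (`max_j |<x_j, y - mean(y)>| / n`) down to `ratio` times it.
#'
#' @param x standardized design, `y` outcome.
#' @param y outcome vector.
#' @param length_out grid size.
#' @param ratio smallest/largest penalty ratio.
#' @return strictly decreasing numeric vector.
#' @export
lambda_grid <- function(x, y, length_out = 60, ratio = 1e-3) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / nrow(x)
  if (lmax <= 0) lmax <- 1e-8
  exp(seq(log(lmax), log(lmax * ratio), length.out = length_out))
}

#' Leave-one-out cross-validated penalty selection
#'
#' For every penalty on the grid, each observation is held out in turn, the
#' model is refit on the remainder (standardization recomputed inside the
#' fold, so no information leaks from the held-out case), and the squared
#' prediction error recorded. The penalty minimizing the mean error is
#' selected; ties break toward the larger penalty (the sparser model).
#' Columns that become constant within a fold contribute nothing to that
#' fold's predictions.
#'
#' @param design unstandardized design matrix (n x p), n >= 5.
#' @param y outcome vector.
#' @param grid penalty grid; default from [lambda_grid()] on the full
#'   standardized design.
#' @return list: `lambda_selected`, `cv_errors` (mean squared prediction
#'   error per penalty), `lambda` (the grid).
#' @export
loo_cv_lambda <- function(design, y, grid = NULL) {
  design <- as.matrix(design)
  n <- nrow(design)
  if (n < 5) stop("need at least 5 observations for LOO-CV", call. = FALSE)
  if (is.null(grid)) {
    sz <- suppressWarnings(standardize(design))
    grid <- lambda_grid(sz$x, y)
  }
  errs <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (i in seq_len(n)) {
    xt <- design[-i, , drop = FALSE]
    yt <- y[-i]
    centers <- colMeans(xt)
    scales <- apply(xt, 2, stats::sd)
    usable <- is.finite(scales) & scales > 0
    xs <- sweep(xt[, usable, drop = FALSE], 2, centers[usable], "-")
    xs <- sweep(xs, 2, scales[usable], "/")
    fit <- lasso_path(xs, yt, grid)
    xnew <- (design[i, usable] - centers[usable]) / scales[usable]
    pred <- fit$intercept + as.vector(xnew %*% fit$beta)
    errs[i, ] <- (y[i] - pred)^2
  }
  cv <- colMeans(errs)
  best <- which(cv <= min(cv) + 1e-12)[1]  # grid is decreasing: first = largest
  list(lambda_selected = grid[best], cv_errors = cv, lambda = grid)
}

#' Language outcome design matrix
#'
#' Assembles, for the aphasia group, the predictor block used by the lasso:
#' demographic covariates (age, sex, months post-onset, scanning site,
#' lesion volume), mean adjusted perfusion of every left atlas ROI and the
#' three perilesional bands, and lesion load of every left atlas ROI.
#'
#' @param metrics long metrics table.
#' @param cohort_table cohort data.frame.
#' @param lookup atlas lookup data.frame.
#' @return list: `x` (design matrix with named columns), `ids` (subject
#'   ids), `perfusion_cols`, `lesion_load_cols`, `covariate_cols`.
#' @export
build_language_design <- function(metrics, cohort_table, lookup) {
  aph <- cohort_table[cohort_table$group == "aphasia", ]
  aph <- aph[order(aph$id), ]
  met <- metrics[metrics$group == "aphasia", ]
  left <- lookup[lookup$hemisphere == "L", ]
  get_col <- function(roi, what) {
    sub <- met[met$roi == roi, c("subject", what)]
    sub[[what]][match(aph$id, sub$subject)]
  }
  x <- cbind(age = aph$age, sex_m = as.numeric(aph$sex == "M"),
             months_post_onset = aph$months_post_onset,
             site_b = as.numeric(aph$site == "B"),
             lesion_volume = aph$lesion_volume)
  covariate_cols <- colnames(x)
  perf <- sapply(as.character(left$label), function(l)
    get_col(l, "mean_adjusted"))
  colnames(perf) <- paste0("perf_", left$name)
  peri <- unique(met$roi[met$class == "perilesional"])
  if (length(peri)) {
    pb <- sapply(peri, function(b) get_col(b, "mean_adjusted"))
    colnames(pb) <- paste0("perf_", peri)
    perf <- cbind(perf, pb)
  }
  ll <- sapply(as.character(left$label), function(l)
    get_col(l, "lesion_load"))
  colnames(ll) <- paste0("load_", left$name)
  x <- cbind(x, perf, ll)
  rownames(x) <- aph$id
  list(x = x, ids = aph$id,
       perfusion_cols = colnames(perf),
       lesion_load_cols = colnames(ll),
       covariate_cols = covariate_cols)
}

#' Lasso model of one language outcome
#'
#' Full pipeline: build the design, drop incomplete cases, standardize,
#' select the penalty by leave-one-out cross-validation, refit on all data
#' at the selected penalty, and report standardized coefficients, training
#' R-squared (1 - RSS/TSS) and RMSE. The outcome is centred by the
#' intercept but not variance-scaled, so coefficients are per standard
#' deviation of each predictor in outcome units. Note the 1/(2n) objective:
#' penalty values are convention-bound and not numerically comparable across
#' software using other scalings (recorded in `meta`).
#'
#' @param metrics long metrics table.
#' @param cohort_table cohort data.frame.
#' @param lookup atlas lookup data.frame.
#' @param outcome name of the score column to model.
#' @param grid optional penalty grid.
#' @return `perfband_lasso` list: outcome, lambda_grid, lambda_selected,
#'   coefficients, intercept, r_squared, rmse, cv_errors, n, design_info,
#'   meta.
#' @export
fit_language_lasso <- function(metrics, cohort_table, lookup, outcome,
                               grid = NULL) {
  des <- build_language_design(metrics, cohort_table, lookup)
  y_all <- cohort_table[cohort_table$group == "aphasia", ]
  y_all <- y_all[order(y_all$id), ]
  y <- y_all[[outcome]]
  # predictors undefined for a large share of subjects (e.g. perfusion of a
  # ROI that is fully lesioned in them) would gut the complete-case sample;
  # drop such columns before listwise deletion
  col_missing <- colMeans(!is.finite(des$x))
  sparse_cols <- colnames(des$x)[col_missing > 0.2]
  if (length(sparse_cols))
    warning("dropping predictor(s) missing in >20% of subjects: ",
            paste(sparse_cols, collapse = ", "), call. = FALSE)
  xd <- des$x[, col_missing <= 0.2, drop = FALSE]
  keep <- is.finite(y) & apply(is.finite(xd), 1, all)
  x <- xd[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 5) stop("need at least 5 complete cases, got ", n, call. = FALSE)
  sz <- standardize(x)
  if (is.null(grid)) grid <- lambda_grid(sz$x, y)
  cv <- loo_cv_lambda(x, y, grid)
  fit <- lasso_path(sz$x, y, cv$lambda_selected)
  beta <- stats::setNames(fit$beta[, 1], colnames(sz$x))
  pred <- fit$intercept + as.vector(sz$x %*% beta)
  rss <- sum((y - pred)^2); tss <- sum((y - mean(y))^2)
  structure(list(
    outcome = outcome, lambda_grid = grid,
    lambda_selected = cv$lambda_selected,
    coefficients = beta, intercept = fit$intercept,
    r_squared = 1 - rss / tss, rmse = sqrt(mean((y - pred)^2)),
    cv_errors = cv$cv_errors, n = n,
    design_info = des[c("perfusion_cols", "lesion_load_cols",
                        "covariate_cols")],
    meta = list(objective = "1/(2n) squared loss + lambda * L1",
                outcome_scaling = "centred via intercept, not scaled",
                categorical_coding = "sex_m, site_b coded 0/1 then standardized",
                cv = "leave-one-out, in-fold restandardization, ties -> larger lambda",
                dropped_columns = sz$dropped)),
    class = "perfband_lasso")
}

#' @export
print.perfband_lasso <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat(sprintf("lasso fit of %s (n = %d): lambda = %.4g, R2 = %.3f, RMSE = %.3f\n",
              x$outcome, x$n, x$lambda_selected, x$r_squared, x$rmse))
  cat(sprintf("%d of %d coefficients nonzero\n", length(nz),
              length(x$coefficients)))
  if (length(nz)) print(round(sort(nz), 4))
  invisible(x)
}

#' Lasso summary table across all WAB outcomes
#'
#' Rows are predictors (covariates, perfusion ROIs and bands, lesion
#' loads) plus footer rows `lambda`, `r_squared` and `rmse`; columns are
#' the outcomes.
#'
#' @param fits list of `perfband_lasso` objects.
#' @return data.frame.
#' @export
lasso_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  preds <- names(fits[[1]]$coefficients)
  out <- data.frame(predictor = c(preds, "lambda", "r_squared", "rmse"),
                    stringsAsFactors = FALSE)
  for (f in fits) {
    out[[f$outcome]] <- c(unname(f$coefficients[preds]),
                          f$lambda_selected, f$r_squared, f$rmse)
  }
  out
}
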