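test_that("standardize centres, scales, inverts and drops constants", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  sz <- standardize(x)
  expect_equal(colMeans(sz$x), c(a = 0, b = 0))
  expect_equal(apply(sz$x, 2, sd), c(a = 1, b = 1))
  # centers/scales invert the transform exactly
  back <- sweep(sweep(sz$x, 2, sz$scales, "*"), 2, sz$centers, "+")
  expect_equal(back, x, ignore_attr = TRUE)
  # idempotence
  sz2 <- standardize(sz$x)
  expect_equal(sz2$x, sz$x, ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(sz3 <- standardize(cbind(k = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_equal(colnames(sz3$x), "b")
  expect_equal(sz3$dropped, "k")
})

test_that("the unpenalized lasso limit equals ordinary least squares", {
  set.seed(71)
  n <- 50; p <- 6
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  xs <- standardize(x)$x
  y <- 2 * xs[, 1] - xs[, 3] + rnorm(n, sd = 0.5)
  fit <- lasso_path(xs, y, c(0.5, 0.1, 0))
  ols <- coef(lm(y ~ xs))
  expect_equal(unname(fit$beta[, 3]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("penalties at or above the null threshold zero every coefficient", {
  set.seed(72)
  n <- 40
  x <- standardize(matrix(rnorm(n * 5), n, 5))$x
  y <- rnorm(n)
  lmax <- max(abs(crossprod(x, y - mean(y)))) / n
  fit <- lasso_path(x, y, c(lmax * 2, lmax * 1.000001))
  expect_true(all(fit$beta == 0))
  # and the automatic grid starts exactly there
  g <- lambda_grid(x, y, length_out = 10)
  expect_equal(g[1], lmax)
  fit2 <- lasso_path(x, y, g)
  expect_true(all(fit2$beta[, 1] == 0))
})

test_that("a single standardized predictor follows the soft-threshold closed form", {
  x <- standardize(matrix(c(1, 3, 4, 7, 10), ncol = 1))$x
  y <- c(2, 3.5, 3, 6, 8)
  n <- 5
  z <- sum(x * (y - mean(y))) / n
  xtx <- sum(x^2) / n
  for (lam in c(0, 0.3, 0.8, 2)) {
    fit <- lasso_path(x, y, lam)
    expected <- sign(z) * max(abs(z) - lam, 0) / xtx
    expect_equal(unname(fit$beta[1, 1]), expected, tolerance = 1e-10)
  }
})

test_that("KKT conditions hold along the path and the L1 norm shrinks with lambda", {
  set.seed(73)
  n <- 45; p <- 12
  x <- standardize(matrix(rnorm(n * p), n, p))$x
  y <- x[, 1] * 1.5 - x[, 2] + rnorm(n, sd = 0.4)
  grid <- lambda_grid(x, y, length_out = 40)
  fit <- lasso_path(x, y, grid)
  for (i in seq_along(grid)) {
    kkt <- lasso_kkt(x, y, fit$beta[, i], fit$intercept, grid[i])
    expect_lt(max(kkt), 1e-7)
  }
  l1 <- colSums(abs(fit$beta))
  expect_true(all(diff(l1) >= -1e-10))  # grid decreasing -> L1 non-decreasing
})

test_that("the coordinate-descent solution matches glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(74)
  n <- 60; p <- 8
  x <- standardize(matrix(rnorm(n * p), n, p))$x
  y <- 2 * x[, 2] - 1.2 * x[, 5] + rnorm(n, sd = 0.7)
  grid <- lambda_grid(x, y, length_out = 12, ratio = 1e-2)
  fit <- lasso_path(x, y, grid)
  gl <- glmnet::glmnet(x, y, alpha = 1, lambda = grid, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(as.matrix(gl$beta)), unname(fit$beta),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("LOO-CV penalty selection behaves at its limits", {
  set.seed(75)
  n <- 30
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  # grid of length 1 -> that lambda is returned
  one <- loo_cv_lambda(x, rnorm(n), grid = 0.2)
  expect_equal(one$lambda_selected, 0.2)
  # noiseless y = 2 x1: selected model uses x1 only with near-zero CV error
  xs <- standardize(x)$x
  y <- 2 * xs[, 1]
  cv <- loo_cv_lambda(x, y)
  fit <- lasso_path(standardize(x)$x, y, cv$lambda_selected)
  nz <- which(fit$beta[, 1] != 0)
  expect_equal(unname(nz), 1L)
  expect_lt(min(cv$cv_errors), 1e-2)
  # pure-noise outcome: the selected penalty sits at the sparse end
  set.seed(76)
  sel_rank <- vapply(1:5, function(i) {
    yn <- rnorm(n)
    cvn <- loo_cv_lambda(x, yn)
    which(cvn$lambda == cvn$lambda_selected) / length(cvn$lambda)
  }, numeric(1))
  expect_lt(stats::median(sel_rank), 0.5)  # mostly in the large-lambda half
})

test_that("duplicate predictor columns never crash the language lasso", {
  co <- simulate_cohort(recovery_config(n_aphasia = 12), seed = 77)
  m <- suppressWarnings(cohort_metrics(co))
  f <- fit_language_lasso(m, co$table, co$lookup, "naming")
  expect_s3_class(f, "perfband_lasso")
  expect_true(is.finite(f$r_squared) && f$r_squared <= 1)
  expect_true(is.finite(f$rmse))
  # a duplicated column is tolerated (documented degeneracy contract)
  des <- build_language_design(m, co$table, co$lookup)
  x <- des$x[, colMeans(!is.finite(des$x)) <= 0.2]
  x2 <- cbind(x, dup = x[, "age"])
  aph <- co$table[co$table$group == "aphasia", ]
  y <- aph$naming[order(aph$id)][apply(is.finite(x), 1, all)]
  keep <- apply(is.finite(x2), 1, all)
  cv <- loo_cv_lambda(x2[keep, ], y)
  expect_true(is.finite(cv$lambda_selected))
})

test_that("lasso_table assembles predictors plus footer rows", {
  co <- simulate_cohort(recovery_config(n_aphasia = 10), seed = 78)
  m <- suppressWarnings(cohort_metrics(co))
  f1 <- fit_language_lasso(m, co$table, co$lookup, "naming")
  f2 <- fit_language_lasso(m, co$table, co$lookup, "aq")
  tab <- lasso_table(list(f1, f2))
  expect_equal(names(tab), c("predictor", "naming", "aq"))
  expect_true(all(c("lambda", "r_squared", "rmse") %in% tab$predictor))
})
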