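make_series <- function(vols) {
  # stack a list of 3D arrays into a 4D series
  array(unlist(vols), dim = c(dim(vols[[1]]), length(vols)))
}

test_that("mean_difference averages control-minus-tag pairs", {
  sh <- c(4, 4, 2)
  acq <- acq_params()
  t1 <- array(100, sh); c1 <- array(103, sh)
  t2 <- array(100, sh); c2 <- array(105, sh)
  s <- make_series(list(t1, c1, t2, c2))
  expect_equal(mean_difference(s, acq), array(4, sh))
  # tag == control -> zero
  s0 <- make_series(list(c1, c1))
  expect_equal(mean_difference(s0, acq), array(0, sh))
  # reversing the pair order flips the sign
  acq_cf <- acq_params(pair_order = "control_first")
  expect_equal(mean_difference(s, acq_cf), -mean_difference(s, acq))
  # odd volume count is an error
  expect_error(mean_difference(make_series(list(t1, c1, t2)), acq),
               "odd")
})

test_that("resolve_m0 honours the calibration convention", {
  sh <- c(3, 3, 3)
  acq_sep <- acq_params(m0_mode = "separate_volume")
  m0 <- array(1234, sh)
  s <- make_series(list(array(1, sh), array(2, sh)))
  expect_identical(resolve_m0(s, acq_sep, m0), m0)
  expect_error(resolve_m0(s, acq_sep), "separate_volume")
  # first-control mode picks volume 2 under tag-first interleaving
  acq_fc <- acq_params(m0_mode = "first_control", pair_order = "tag_first")
  s2 <- make_series(list(array(5, sh), array(1000, sh)))
  expect_equal(resolve_m0(s2, acq_fc), array(1000, sh))
  # and volume 1 under control-first
  acq_cf <- acq_params(m0_mode = "first_control", pair_order = "control_first")
  expect_equal(resolve_m0(s2, acq_cf), array(5, sh))
})

test_that("quantify_cbf reproduces hand-evaluated kinetic-model values", {
  sh <- c(2, 2, 2)
  mask <- array(TRUE, sh)
  m0 <- array(1000, sh)
  dm <- array(10, sh)  # delta_m / m0 = 0.01
  va <- acq_params(alpha = 0.72, t1_blood = 1650, tau = 1470, pld = 1500,
                   lambda_p = 0.9)
  ucb <- acq_params(alpha = 0.72, t1_blood = 1650, tau = 1800, pld = 2000,
                    lambda_p = 0.9)
  # frozen from an independent evaluation of the closed form
  expect_equal(quantify_cbf(dm, m0, va, mask)[1], 95.65695, tolerance = 1e-6)
  expect_equal(quantify_cbf(dm, m0, ucb, mask)[1], 115.01079, tolerance = 1e-6)
  expect_equal(quantify_cbf(array(0, sh), m0, va, mask), array(0, sh),
               ignore_attr = TRUE)
})

test_that("quantification is linear in delta-M and inverse in M0", {
  sh <- c(4, 3, 3)
  set.seed(2)
  dm <- array(rnorm(prod(sh), 5, 1), sh)
  m0 <- array(runif(prod(sh), 800, 1200), sh)
  mask <- array(TRUE, sh)
  acq <- acq_params()
  base <- quantify_cbf(dm, m0, acq, mask)
  expect_equal(quantify_cbf(3 * dm, m0, acq, mask), 3 * base,
               ignore_attr = TRUE)
  expect_equal(quantify_cbf(dm, 2 * m0, acq, mask), base / 2,
               ignore_attr = TRUE)
})

test_that("CBF increases with delta-M and decreases with labelling efficiency", {
  sh <- c(2, 2, 2)
  m0 <- array(1000, sh); mask <- array(TRUE, sh)
  v <- function(dm, alpha)
    quantify_cbf(array(dm, sh), m0, acq_params(alpha = alpha), mask)[1]
  expect_true(v(12, 0.72) > v(10, 0.72))
  expect_true(v(10, 0.85) < v(10, 0.72))
})

test_that("negative voxels are retained and bad M0 voxels masked with counts", {
  sh <- c(2, 2, 2)
  dm <- array(c(-5, 5, 5, 5, 5, 5, 5, 5), sh)
  m0 <- array(1000, sh); m0[2, 1, 1] <- 0
  mask <- array(TRUE, sh)
  cbf <- quantify_cbf(dm, m0, acq_params(), mask)
  expect_true(cbf[1, 1, 1] < 0)          # not clipped
  expect_equal(cbf[2, 1, 1], 0)          # unusable M0 -> 0
  expect_equal(attr(cbf, "n_negative"), 1)
  expect_equal(attr(cbf, "n_bad_m0"), 1)
  expect_error(quantify_cbf(dm, m0[, , 1, drop = FALSE], acq_params(), mask),
               "grid")
})

test_that("acq_params rejects invalid constants", {
  expect_error(acq_params(alpha = 0))
  expect_error(acq_params(alpha = 1.2))
  expect_error(acq_params(t1_blood = -1))
  expect_error(acq_params(lambda_p = 0))
  expect_equal(acq_preset("site_a")$m0_mode, "first_control")
  expect_equal(acq_preset("site_b")$tau, 1800)
})
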