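test_that("rolling-ball baseline matches the brute-force opening oracle", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(200:400, 1)
    r <- sample(c(5, 20, 50), 1)
    y <- abs(cumsum(rnorm(n))) + runif(n, 0, 3)
    expect_equal(rolling_ball_baseline(y, r), brute_rolling_ball(y, r),
                 tolerance = 1e-12)
  }
})

test_that("flat and empty-feature inputs are pure baseline", {
  z <- rep(0, 120)
  fit <- rolling_ball_correct(z, 10)
  expect_equal(fit$baseline, z)
  expect_equal(fit$corrected, z)

  const <- rep(7.5, 120)
  fit <- rolling_ball_correct(const, 10)
  expect_equal(fit$corrected, rep(0, 120))
})

test_that("a planted peak on a ramp survives correction within 10%", {
  ax <- seq(602, by = 1.1, length.out = 800)
  ramp <- 100 + 0.05 * (ax - 602)
  peak <- 50 * exp(-(ax - 1003)^2 / (2 * (12 / 2.3548)^2))
  fit <- rolling_ball_correct(ramp + peak, 50)
  expect_equal(max(fit$corrected), 50, tolerance = 0.1)
  expect_true(all(fit$baseline <= ramp + peak + 1e-12))
})

test_that("smooth broad backgrounds reduce to under 5% residual", {
  ax <- seq_len(1000)
  curves <- list(
    concave = 500 - 0.0004 * (ax - 500)^2,
    gaussian = 400 * exp(-(ax - 450)^2 / (2 * 250^2)),
    slope = 200 + 0.3 * ax)
  for (nm in names(curves)) {
    y <- curves[[nm]]
    fit <- rolling_ball_correct(y, 50)
    expect_lt(max(fit$corrected), 0.05 * max(y), label = nm)
  }
})

test_that("re-correcting an already corrected spectrum changes little", {
  # narrow lines on a flat offset: every feature is narrower than the
  # radius, so a second pass must leave the signal essentially unchanged
  ax <- seq(602, by = 1.1, length.out = 800)
  y <- 50 + 40 * exp(-(ax - 1003)^2 / (2 * 5.1^2)) +
    30 * exp(-(ax - 1450)^2 / (2 * 5.1^2))
  once <- rolling_ball_correct(y, 50)$corrected
  twice <- rolling_ball_correct(once, 50)$corrected
  expect_lt(abs(sum(twice) - sum(once)), 0.05 * sum(once))
})

test_that("radius validation and the preprocessed flag are enforced", {
  expect_error(rolling_ball_baseline(rep(1, 20), 20), "smaller")
  expect_error(rolling_ball_baseline(rep(1, 20), 0), "positive")
  ch <- quick_cohort(2, 2, seed = 8)
  pp <- preprocess_cohort(ch, radius_points = 20)
  expect_true(all(pp$preprocessed))
  expect_warning(pp2 <- preprocess_cohort(pp, radius_points = 20),
                 "already preprocessed")
  expect_identical(pp2, pp)
  expect_warning(preprocess_cohort(pp, radius_points = 20, reprocess = TRUE),
                 "again")
})

test_that("standardization statistics match a two-pass oracle", {
  p <- 12
  two <- rbind(rep(0, p), rep(2, p))
  st <- fit_standardization(two)
  expect_equal(unname(st$mean), rep(1, p))
  expect_equal(unname(st$sd), rep(sqrt(2), p))

  set.seed(21)
  x <- matrix(rnorm(40 * p, 5, 3), 40, p)
  st <- fit_standardization(x)
  mu <- colSums(x) / nrow(x)
  sdv <- sqrt(colSums((x - rep(mu, each = nrow(x)))^2) / (nrow(x) - 1))
  expect_equal(unname(st$mean), mu)
  expect_equal(unname(st$sd), sdv)

  z <- apply_standardization(x, st)
  expect_equal(unname(colMeans(z)), rep(0, p), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, p), tolerance = 1e-12)

  expect_error(fit_standardization(x[1, , drop = FALSE]), "at least 2")
})

test_that("standardization is affine-equivariant and leak-free", {
  set.seed(3)
  x <- matrix(abs(rnorm(30 * 8, 10, 2)), 30, 8)
  z1 <- apply_standardization(x, fit_standardization(x))
  z2 <- apply_standardization(3.7 * x, fit_standardization(3.7 * x))
  expect_equal(z1, z2, tolerance = 1e-10)

  # held-out data transformed with training stats keeps its offset
  st <- fit_standardization(x)
  shifted <- x + 2
  z <- apply_standardization(shifted, st)
  expect_true(all(colMeans(z) > 0.5))
  # a spectrum equal to the training mean maps to the zero vector
  expect_equal(apply_standardization(matrix(st$mean, nrow = 1), st)[1, ],
               rep(0, 8), ignore_attr = TRUE)
})

test_that("constant training features standardize to zero with a warning", {
  x <- cbind(rep(4, 10), rnorm(10))
  st <- fit_standardization(x)
  expect_warning(z <- apply_standardization(x + 1, st), "constant")
  expect_equal(z[, 1], rep(0, 10))
  expect_error(apply_standardization(x[, 1, drop = FALSE], st), "mismatch")
})
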