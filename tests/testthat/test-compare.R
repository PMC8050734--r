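t24 <- rep(c(2, 6, 10, 14, 18, 22), each = 4)

test_that("comparing a series with itself gives zero differences and p near 1", {
  set.seed(20)
  y <- cosine_signal(t24, 10, 2, 6) + rnorm(24, 0, 0.3)
  r <- compare_rhythms(y, y, t24)
  expect_equal(r$d_mesor, 0, tolerance = 1e-8)
  expect_equal(r$d_amplitude, 0, tolerance = 1e-8)
  expect_equal(r$d_phase, 0, tolerance = 1e-8)
  expect_gt(r$p_mesor, 0.99)
  expect_gt(r$p_amplitude, 0.99)
  expect_gt(r$p_phase, 0.99)
})

test_that("a constructed antiphase pair is reported as +12 h", {
  ya <- cosine_signal(t24, 10, 2, 6)
  yb <- cosine_signal(t24, 10, 2, 18)
  r <- compare_rhythms(ya, yb, t24)
  expect_equal(r$d_phase, 12)
})

test_that("zero-noise pairs reproduce single-condition cosinor parameters", {
  ya <- cosine_signal(t24, 10, 2, 6)
  yb <- cosine_signal(t24, 12, 1.2, 16)
  r <- compare_rhythms(ya, yb, t24)
  expect_equal(r$mesor_a, 10, tolerance = 1e-8)
  expect_equal(r$mesor_b, 12, tolerance = 1e-8)
  expect_equal(r$amplitude_a, 2, tolerance = 1e-8)
  expect_equal(r$amplitude_b, 1.2, tolerance = 1e-8)
  expect_equal(r$d_phase, 10, tolerance = 1e-8)
})

test_that("swapping conditions negates estimates and keeps p-values", {
  set.seed(21)
  for (i in 1:4) {
    ya <- cosine_signal(t24, 10, 2, runif(1, 0, 24)) + rnorm(24, 0, 0.3)
    yb <- cosine_signal(t24, 11, 1.4, runif(1, 0, 24)) + rnorm(24, 0, 0.3)
    r1 <- compare_rhythms(ya, yb, t24)
    r2 <- compare_rhythms(yb, ya, t24)
    expect_equal(r1$d_mesor, -r2$d_mesor, tolerance = 1e-6)
    expect_equal(r1$d_amplitude, -r2$d_amplitude, tolerance = 1e-6)
    dsum <- (r1$d_phase + r2$d_phase) %% 24
    expect_lt(min(dsum, 24 - dsum), 1e-6)
    expect_equal(r1$p_mesor, r2$p_mesor, tolerance = 1e-4)
    expect_equal(r1$p_amplitude, r2$p_amplitude, tolerance = 1e-4)
    expect_equal(r1$p_phase, r2$p_phase, tolerance = 1e-4)
  }
})

test_that("amplitude differences are estimated without bias and with nominal coverage", {
  ## dA = -0.4 * A_A across 300 features at moderate multiplicative noise
  set.seed(22)
  n <- 300
  est <- tru <- numeric(n)
  cov <- logical(n)
  for (i in 1:n) {
    M <- rlnorm(1, log(100), 0.4)
    A <- pmin(0.9, rlnorm(1, log(0.5), 0.2)) * M
    phi <- runif(1, 0, 24)
    dA <- -0.4 * A
    ya <- cosine_signal(t24, M, A, phi) * exp(rnorm(24, 0, 0.1))
    yb <- cosine_signal(t24, M, A + dA, phi) * exp(rnorm(24, 0, 0.1))
    r <- compare_rhythms(ya, yb, t24)
    est[i] <- r$d_amplitude
    tru[i] <- dA
    half <- qt(0.975, r$n - 6) * r$se_amplitude
    cov[i] <- abs(r$d_amplitude - dA) <= half
  }
  expect_lt(abs(mean(est) / mean(tru) - 1), 0.05)
  ci <- qbinom(c(0.005, 0.995), n, 0.95) / n
  expect_gte(mean(cov), ci[1])
  expect_lte(mean(cov), ci[2])
})

test_that("mesor Wald p approximates the plain two-group t-test for flat series", {
  set.seed(23)
  dif <- replicate(20, {
    ya <- 10 + rnorm(24)
    yb <- 10.4 + rnorm(24)
    r <- compare_rhythms(ya, yb, t24)
    pl <- summary(lm(c(ya, yb) ~ rep(0:1, each = 24)))$coefficients[2, 4]
    abs(r$p_mesor - pl)
  })
  expect_lt(median(dif), 0.05)
  expect_lt(max(dif), 0.2)
})

test_that("pointwise t-tests match t.test and apply the alpha/m threshold", {
  des <- make_design(r = 3)
  a <- des$condition == "NRF"
  b <- des$condition == "DRF"
  set.seed(24)
  M <- matrix(rnorm(2 * nrow(des), 10), 2,
    dimnames = list(c("g1", "g2"), des$sample_id)
  )
  M[1, b & des$zt == 10] <- M[1, b & des$zt == 10] + 50
  pt <- pointwise_tests(M[, a], M[, b], des$zt[a], des$zt[b])
  expect_equal(unique(pt$p_threshold), 0.05 / 6)
  expect_equal(pt$p_threshold[1], 0.008333333, tolerance = 1e-6)
  for (z in c(2, 10, 18)) {
    tt <- t.test(M[1, b & des$zt == z], M[1, a & des$zt == z])
    row <- pt[pt$feature_id == "g1" & pt$zt == z, ]
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
  }
  expect_true(pt$significant[pt$feature_id == "g1" & pt$zt == 10])
  # identical groups -> nothing significant
  pt0 <- pointwise_tests(M[, a], M[, a], des$zt[a], des$zt[a])
  expect_false(any(pt0$significant))
  # a timepoint with < 2 replicates is untestable, not silently dropped
  keep <- !(a & des$zt == 2 & des$replicate > 1)
  pt1 <- pointwise_tests(M[, a & keep, drop = FALSE], M[, b],
    des$zt[a & keep], des$zt[b]
  )
  expect_true(all(pt1$untestable[pt1$zt == 2]))
  expect_false(any(pt1$untestable[pt1$zt != 2]))
})

test_that("z-scored profiles are standardized, affine-invariant, and flag constants", {
  des <- make_design(r = 2)
  set.seed(25)
  M <- matrix(rlnorm(3 * nrow(des)), 3,
    dimnames = list(c("g1", "g2", "flat"), des$sample_id)
  )
  M["flat", ] <- 7
  z <- zscore_profiles(M, des)
  for (cond in c("NRF", "DRF")) {
    zz <- z$z[z$feature_id == "g1" & z$condition == cond]
    expect_equal(mean(zz), 0, tolerance = 1e-12)
    expect_equal(sd(zz), 1, tolerance = 1e-12)
  }
  expect_true(all(z$z[z$feature_id == "flat"] == 0))
  expect_true(all(z$constant[z$feature_id == "flat"]))
  z2 <- zscore_profiles(3.5 * M + 2, des)
  expect_equal(z2$z[z2$feature_id != "flat"], z$z[z$feature_id != "flat"],
    tolerance = 1e-10
  )
})
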