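test_that("circular folding reproduces the worked examples", {
  expect_identical(fold_phase_shift(14, 24), 10)
  expect_identical(fold_phase_shift(0), 0)
  expect_identical(fold_phase_shift(12), 12)
  expect_identical(fold_phase_shift(-14), 10)
  expect_equal(fold_phase_shift(c(20, 26)), c(4, 2))
  expect_error(fold_phase_shift(5, tau = 0), "tau")
  expect_error(fold_phase_shift(Inf), "finite")
})

test_that("folding equals the brute-force oracle and has circular symmetries", {
  g <- seq(-48, 48, by = 0.01)
  f <- fold_phase_shift(g)
  expect_equal(f, fold_oracle(g), tolerance = 1e-12)
  expect_true(all(f >= 0 & f <= 12))
  expect_equal(fold_phase_shift(-g), f) # even
  expect_equal(fold_phase_shift(g + 24), f, tolerance = 1e-9) # periodic
})

test_that("classification bins partition [0, 12] with closed outer bounds", {
  expect_identical(classify_shift(3.9), "phase_locked")
  expect_identical(classify_shift(4.0), "phase_locked")
  expect_identical(classify_shift(8.0), "phase_inverted")
  expect_identical(classify_shift(10), "phase_inverted")
  expect_identical(classify_shift(5), "intermediate")
  expect_error(classify_shift(12.5), "outside")
  expect_error(classify_shift(-0.1), "outside")
  g <- seq(0, 12, by = 0.001)
  cls <- classify_shift(g)
  oracle <- ifelse(g <= 4, "phase_locked",
    ifelse(g < 8, "intermediate", "phase_inverted")
  )
  expect_identical(cls, oracle)
  expect_equal(sort(unique(cls)), sort(unique(oracle))) # every class hit once
})

test_that("dual-oscillating features are the q-threshold intersection", {
  mk <- function(ids, q) {
    data.frame(feature_id = ids, q_value = q, stringsAsFactors = FALSE)
  }
  ids <- letters[1:4]
  fa <- mk(ids, c(0.01, 0.02, 0.03, 0.2))
  fb <- mk(ids, c(0.2, 0.01, 0.04, 0.01))
  du <- dual_oscillating(fa, fb)
  expect_setequal(du$dual, c("b", "c"))
  expect_setequal(du$a_only, "a")
  expect_setequal(du$b_only, "d")
  # disjoint sets: empty dual, no error
  fb2 <- mk(ids, c(0.9, 0.9, 0.9, 0.01))
  fa2 <- mk(ids, c(0.01, 0.9, 0.9, 0.9))
  expect_length(dual_oscillating(fa2, fb2)$dual, 0)
  expect_error(dual_oscillating(fa, mk(letters[2:5], rep(0.01, 4))),
    "universes"
  )
})

test_that("loosening the q threshold never shrinks the dual set", {
  set.seed(30)
  ids <- sprintf("g%03d", 1:200)
  fa <- data.frame(feature_id = ids, q_value = runif(200)^2)
  fb <- data.frame(feature_id = ids, q_value = runif(200)^2)
  d1 <- dual_oscillating(fa, fb, 0.01)$dual
  d5 <- dual_oscillating(fa, fb, 0.05)$dual
  d9 <- dual_oscillating(fa, fb, 0.5)$dual
  expect_true(all(d1 %in% d5))
  expect_true(all(d5 %in% d9))
})

test_that("entrainment summaries count, percentage, and bin correctly", {
  rec <- data.frame(
    feature_id = letters[1:4],
    signed_shift = c(1, -2, 3, 10),
    folded_shift = c(1, 2, 3, 10),
    entrainment_class = c(rep("phase_locked", 3), "phase_inverted"),
    stringsAsFactors = FALSE
  )
  s <- entrainment_summary(rec)
  expect_equal(s$n_dual, 4)
  expect_equal(s$percentages[["phase_inverted"]], 25.00)
  expect_equal(sum(s$percentages), 100, tolerance = 0.01)
  expect_equal(sum(s$histogram$count), 4)
  # all inverted -> 100% with histogram mass in bins 8-12
  rec2 <- data.frame(
    feature_id = letters[1:3], signed_shift = c(9, -11, 12),
    folded_shift = c(9, 11, 12),
    entrainment_class = rep("phase_inverted", 3), stringsAsFactors = FALSE
  )
  s2 <- entrainment_summary(rec2)
  expect_equal(s2$percentages[["phase_inverted"]], 100.00)
  expect_equal(sum(s2$histogram$count[s2$histogram$bin_lo >= 8]), 3)
  expect_equal(s2$histogram$count[12], 2) # folded 11 and 12 in closed last bin
  # permutation invariance of record order
  s3 <- entrainment_summary(rec[sample(4), ])
  expect_equal(s3$counts, s$counts)
  # empty sentinel
  s0 <- entrainment_summary(rec[0, ])
  expect_true(s0$empty)
  expect_equal(s0$n_dual, 0)
})

test_that("cross-dataset integration applies the strict >4 h rule", {
  X <- c(a = 5, b = 3, c = 9)
  Y <- c(a = 6, d = 2)
  res <- cross_dataset_integration(list(X = X, Y = Y))
  expect_setequal(res$shifted_sets$X, c("a", "c"))
  expect_setequal(res$shifted_sets$Y, "a")
  expect_equal(res$per_dataset$pct_shifted, c(66.67, 50.00))
  expect_equal(res$overlap_counts["X", "Y"], 1)
  # folded shift of exactly 4.0 is excluded
  res2 <- cross_dataset_integration(list(Z = c(a = 4.0, b = 4.0001)))
  expect_setequal(res2$shifted_sets$Z, "b")
  expect_error(cross_dataset_integration(list(X, Y)), "names")
})

test_that("cross-dataset fractions equal an independent count oracle", {
  set.seed(31)
  tabs <- lapply(1:3, function(i) {
    n <- sample(20:60, 1)
    setNames(runif(n, 0, 12), sprintf("d%d_g%02d", i, 1:n))
  })
  names(tabs) <- c("A", "B", "C")
  res <- cross_dataset_integration(tabs, threshold = 4)
  for (nm in names(tabs)) {
    oracle <- 100 * sum(tabs[[nm]] > 4) / length(tabs[[nm]])
    expect_equal(res$per_dataset$pct_shifted[res$per_dataset$dataset == nm],
      round(oracle, 2)
    )
  }
})

test_that("licensed oscillators are rhythmic in exactly one condition", {
  mk <- function(ids, q, cond) {
    data.frame(feature_id = ids, q_value = q, condition = cond,
      stringsAsFactors = FALSE
    )
  }
  ids <- letters[1:4]
  fa <- mk(ids, c(0.01, 0.20, 0.01, 0.30), "NRF")
  fb <- mk(ids, c(0.20, 0.01, 0.01, 0.30), "DRF")
  lic <- licensed_oscillators(fa, fb)
  expect_setequal(lic$NRF, "a")
  expect_setequal(lic$DRF, "b")
  expect_setequal(lic$both, "c") # rhythmic in both: excluded from licensed
})

test_that("phase-shift records fall back to acrophase differences", {
  cmp <- data.frame(
    feature_id = c("a", "b"),
    acrophase_a = c(2, 4), acrophase_b = c(12, 20),
    d_phase = c(9.8, NA), converged = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rec <- phase_shift_records(cmp)
  expect_equal(rec$signed_shift, c(9.8, -8)) # b: wrap_signed(20 - 4) = -8
  expect_equal(rec$folded_shift, c(9.8, 8))
  expect_identical(rec$shift_source, c("joint_fit", "acrophase_diff"))
  expect_identical(rec$entrainment_class[2], "phase_inverted")
})
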