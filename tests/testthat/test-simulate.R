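test_that("identical specs with identical seeds give identical datasets", {
  sp <- synthetic_spec(n_features = 40, seed = 11)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(synthetic_spec(n_features = 40, seed = 12))
  expect_false(identical(d1$matrix, d3$matrix))
})

test_that("noiseless generator output equals the cosinor formula exactly", {
  sp <- synthetic_spec(
    n_features = 30, frac_rhythmic = 0.5, noise_sigma = 0,
    seed = 5
  )
  d <- generate_dataset(sp)
  tr <- d$truth
  for (cond in c("a", "b")) {
    lab <- attr(tr, "conditions")[if (cond == "a") 1 else 2]
    sel <- d$design$condition == lab
    zt <- d$design$zt[sel]
    for (f in c(1, 10, 15, 25)) { # rhythmic and flat rows
      A <- tr[[paste0("amplitude_", cond)]][f]
      phi <- tr[[paste0("acrophase_", cond)]][f]
      expected <- if (tr$rhythmic_a[f]) {
        cosine_signal(zt, tr[[paste0("mesor_", cond)]][f], A, phi)
      } else {
        rep(tr[[paste0("mesor_", cond)]][f], length(zt))
      }
      expect_equal(unname(d$matrix[f, sel]), expected, tolerance = 1e-12)
    }
  }
})

test_that("noiseless rhythmic features are recovered exactly by the cosinor fit", {
  sp <- synthetic_spec(
    n_features = 10, frac_rhythmic = 1, noise_sigma = 0,
    seed = 3
  )
  d <- generate_dataset(sp)
  sel <- d$design$condition == "NRF"
  for (f in 1:10) {
    fit <- fit_cosinor(d$matrix[f, sel], d$design$zt[sel])
    expect_equal(fit$mesor, d$truth$mesor_a[f], tolerance = 1e-8)
    expect_equal(fit$amplitude, d$truth$amplitude_a[f], tolerance = 1e-8)
    expect_equal(fit$acrophase, d$truth$acrophase_a[f], tolerance = 1e-8)
  }
})

test_that("ground-truth class frequencies follow the requested mixture", {
  mix <- c(locked = 0.2, intermediate = 0.3, inverted = 0.5)
  sp <- synthetic_spec(
    n_features = 3000, frac_rhythmic = 1,
    class_mixture = mix, seed = 17
  )
  d <- generate_dataset(sp)
  obs <- table(factor(d$truth$class,
    levels = c("locked", "intermediate", "inverted")
  ))
  gof <- chisq.test(obs, p = mix)
  expect_gt(gof$p.value, 0.01)
  # truth classes are consistent with the classifier bins on the folded shift
  mapped <- classify_shift(d$truth$folded_shift)
  expect_identical(
    unname(c(
      locked = "phase_locked", intermediate = "intermediate",
      inverted = "phase_inverted"
    )[d$truth$class]),
    mapped
  )
})

test_that("tissue archetypes carry the reported class weights", {
  expect_equal(tissue_archetype("VAT")$class_mixture[["inverted"]], 0.8046)
  expect_equal(tissue_archetype("liver")$class_mixture[["inverted"]], 0.61)
  expect_equal(tissue_archetype("kidney")$class_mixture[["inverted"]], 0.3911)
  expect_equal(tissue_archetype("kidney")$class_mixture[["locked"]], 0.3711)
  expect_equal(tissue_archetype("heart")$class_mixture[["inverted"]], 0.2168)
  expect_equal(tissue_archetype("heart")$class_mixture[["locked"]], 0.5741)
  for (nm in c("VAT", "liver", "kidney", "heart")) {
    expect_equal(sum(tissue_archetype(nm)$class_mixture), 1)
  }
  expect_error(tissue_archetype("brain"), "unknown tissue")
})

test_that("ultradian features oscillate at 12 h in the licensed condition only", {
  sp <- synthetic_spec(
    n_features = 60, frac_rhythmic = 0.3, frac_ultradian = 0.2,
    noise_sigma = 0, seed = 9
  )
  d <- generate_dataset(sp)
  ult <- which(d$truth$ultradian)
  expect_length(ult, 12)
  sel_lic <- d$design$condition == "DRF"
  sel_oth <- d$design$condition == "NRF"
  for (f in ult[1:3]) {
    f12 <- fit_cosinor(d$matrix[f, sel_lic], d$design$zt[sel_lic], tau = 12)
    expect_equal(f12$amplitude, d$truth$ultradian_amplitude[f],
      tolerance = 1e-8
    )
    expect_equal(sd(d$matrix[f, sel_oth]), 0) # flat in the other condition
  }
})

test_that("spec validation rejects inconsistent settings", {
  expect_error(synthetic_spec(class_mixture = c(
    locked = 0.5, intermediate = 0.5,
    inverted = 0.5
  )), "sum to 1")
  expect_error(synthetic_spec(frac_rhythmic = 0.9, frac_ultradian = 0.2))
  expect_error(synthetic_spec(timepoints = c(2, 25)))
  expect_error(
    synthetic_spec(ultradian_condition = "XX"),
    "ultradian_condition"
  )
})

test_that("pipeline recovers a strongly inverted class mixture within binomial error", {
  ## low-noise validation regime: phase error must stay well under the 1-h
  ## class-bin resolution for the binomial interval (which models only
  ## label-sampling error) to be the right yardstick
  sp <- synthetic_spec(
    n_features = 2500, frac_rhythmic = 0.8,
    class_mixture = c(locked = 0.1, intermediate = 0.1, inverted = 0.8),
    noise_sigma = 0.03, seed = 29
  )
  d <- generate_dataset(sp)
  res <- entrainment_pipeline(d$matrix, d$design, "NRF", "DRF")
  ci <- qbinom(c(0.005, 0.995), 2000, 0.8) / 2000
  frac <- res$summary$counts[["phase_inverted"]] / res$summary$n_dual
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})
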