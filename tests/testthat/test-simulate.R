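test_that("identical seeds reproduce recordings bit for bit", {
  cpl <- singlePairCoupling()
  a <- generateRecording(coupling = cpl, n_trials = 3, fs = 200,
                         tasks = "fist", seed = 7)
  b <- generateRecording(coupling = cpl, n_trials = 3, fs = 200,
                         tasks = "fist", seed = 7)
  expect_identical(a@data, b@data)
  expect_identical(a@events, b@events)
  c <- generateRecording(coupling = cpl, n_trials = 3, fs = 200,
                         tasks = "fist", seed = 8)
  expect_false(identical(a@data, c@data))
})

test_that("invalid coupling and sampling configurations are rejected", {
  bad <- list(alpha = couplingSpec("alpha",
    data.frame(from = "C3", to = "XX9", lag = 0.1, strength = 1)))
  expect_error(generateRecording(coupling = bad, n_trials = 1, fs = 200),
               "XX9")
  cpl <- singlePairCoupling()
  expect_error(generateRecording(coupling = cpl, n_trials = 1, fs = 15),
               "twice")
  expect_error(couplingSpec("alpha",
    data.frame(from = "C3", to = "F3", lag = 4, strength = 1)), "lag")
  expect_error(couplingSpec("alpha",
    data.frame(from = "C3", to = "F3", lag = 0.1, strength = 2)),
    "strength")
  expect_error(couplingSpec("alpha", data.frame()[0, ], noise_sd = 0),
               "noise_sd")
})

test_that("a strongly coupled pair yields near-unit alpha wPLI downstream", {
  rec <- generateRecording(coupling = singlePairCoupling(noise_sd = 0.05),
                           n_trials = 20, fs = 250, tasks = "fist",
                           gap_s = 0.5, seed = 1)
  ep <- epochRecording(rereferenceLinkedEars(rec), "fist")
  m <- bandWpli(stftEpochs(ep), "alpha")
  expect_gte(connValues(m)["C3", "F3"], 0.9)
})

test_that("wPLI calibrates to 1 for a noiseless coupled pair", {
  rec <- generateRecording(coupling = singlePairCoupling(noise_sd = 1e-9),
                           n_trials = 5, fs = 250, tasks = "fist",
                           gap_s = 0.5, seed = 2)
  ep <- epochRecording(rereferenceLinkedEars(rec), "fist")
  m <- bandWpli(stftEpochs(ep), "alpha")
  expect_equal(connValues(m)["C3", "F3"], 1, tolerance = 1e-3)
})

test_that("zero-strength and mixing-only cohorts stay at the estimator null", {
  probe <- function(strength, mixing, seed) {
    cpl <- list(alpha = couplingSpec("alpha",
      data.frame(from = "C3", to = "F3", lag = pi / 2, strength = strength,
                 freq = 10), noise_sd = 1, mixing_strength = mixing))
    r <- generateRecording(coupling = cpl, n_trials = 6, fs = 250,
                           post_s = 1, gap_s = 0.25, tasks = "fist",
                           seed = seed)
    e <- epochRecording(rereferenceLinkedEars(r), "fist", post_s = 1)
    v <- connValues(bandWpli(stftEpochs(e), "alpha"))
    c(pair = v["C3", "F3"], mixed = v["C3", "Cz"])
  }
  ## pure-noise null of the estimator at the same observation count
  nulls <- vapply(1:20, function(s) probe(0, 0, 1000 + s)["pair"], 0)
  ## zero strength: indistinguishable from the null in expectation
  zero <- vapply(1:20, function(s) probe(0, 0, 2000 + s)["pair"], 0)
  se <- sqrt(var(nulls) / 20 + var(zero) / 20)
  expect_lte(abs(mean(zero) - mean(nulls)), 4 * se + 1e-9)
  ## pure zero-lag mixing between neighbors: no spurious wPLI above the
  ## null's 95th percentile in expectation
  mixed <- vapply(1:20, function(s) probe(0, 0.8, 3000 + s)["mixed"], 0)
  expect_lte(mean(mixed), quantile(nulls, 0.95))
})

test_that("cohorts link severity to attenuation and honor group structure", {
  coh <- generateCohort(8, patient_attenuation = 0.3, n_trials = 1,
                        fs = 100, post_s = 1, gap_s = 0.2,
                        tasks = "fist", seed = 11)
  man <- cohortManifest(coh)
  expect_identical(sum(man$group == "patient"), 8L)
  expect_identical(sum(man$group == "control"), 8L)
  expect_identical(sum(man$affected_side == "right", na.rm = TRUE), 1L)
  pats <- Filter(function(s) s$group == "patient", coh)
  att <- vapply(pats, `[[`, 0, "attenuation")
  mas <- masCode(vapply(pats, `[[`, "", "mas_upper"))
  expect_true(all(att <= 1 & att >= 0))
  ## severity rises as attenuation deepens, by construction
  expect_lte(cor(att, mas, method = "spearman"), -0.9)
  ## controls carry no MAS grades
  expect_true(all(is.na(man$mas_upper[man$group == "control"])))
  ## determinism at cohort level
  coh2 <- generateCohort(8, patient_attenuation = 0.3, n_trials = 1,
                         fs = 100, post_s = 1, gap_s = 0.2,
                         tasks = "fist", seed = 11)
  expect_identical(coh[[1]]$recording@data, coh2[[1]]$recording@data)
  expect_identical(man, cohortManifest(coh2))
})

test_that("degenerate and invalid cohort requests behave as declared", {
  expect_error(generateCohort(1), "n_per_group")
  expect_error(generateCohort(4, patient_attenuation = 1.5),
               "patient_attenuation")
  ## smallest legal cohort with full attenuation processes end to end
  coh <- generateCohort(2, patient_attenuation = 0, n_trials = 1,
                        fs = 100, post_s = 1, gap_s = 0.2,
                        tasks = "fist", seed = 5)
  expect_length(coh, 4L)
  ## attenuation 1 leaves patient coupling equal to controls
  cohnull <- generateCohort(2, patient_attenuation = 1, n_trials = 1,
                            fs = 100, post_s = 1, gap_s = 0.2,
                            tasks = "fist", seed = 5)
  pat <- cohnull[[1]]
  expect_identical(pat$attenuation, 1)
  expect_equal(pat$ground_truth$alpha$pairs$strength,
               cohnull[[3]]$ground_truth$alpha$pairs$strength)
})

test_that("MAS coding follows the conventional midpoint scheme", {
  expect_identical(masCode(c("0", "1", "1+", "2")), c(0, 1, 1.5, 2))
  expect_error(masCode("3"), "unknown")
})
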