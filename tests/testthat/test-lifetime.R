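test_that("phase and modulation follow the closed-form single-exponential", {
  pm <- phaseModulation(100, 4.0)
  wt <- 2 * pi * 0.1 * 4.0
  expect_equal(pm$phase_deg, atan(wt) * 180 / pi)
  expect_equal(pm$modulation, 1 / sqrt(1 + wt^2))
  expect_equal(round(pm$phase_deg, 1), 68.3)
  expect_equal(round(pm$modulation, 3), 0.370)
  expect_error(phaseModulation(100, -1), "> 0")
  expect_error(phaseModulation(100, c(1, 2), c(0.7, 0.7)), "sum to 1")
})

test_that("noiseless single-exponential data invert exactly", {
  d <- genLifetime(genSpec("lifetime", truth = list(tau_ns = 4),
                           noise = list(sigma_phase = 0, sigma_mod = 0)))
  fit <- fitResults(lifetimeFit(d, 1))
  expect_equal(fit$tau_ns, 4, tolerance = 1e-6)
  expect_equal(fit$fractions, 1)
})

test_that("two-component decays are recovered at instrumental noise", {
  errs <- sapply(1:5, function(seed) {
    d <- genLifetime(genSpec("lifetime", seed = seed,
                             truth = list(tau_ns = c(1.5, 4.5),
                                          fractions = c(0.4, 0.6))))
    fit <- fitResults(lifetimeFit(d, 2))
    max(abs(fit$tau_ns - c(1.5, 4.5)) / c(1.5, 4.5),
        abs(fit$fractions[1] - 0.4) / 0.4)
  })
  expect_lt(median(errs), 0.05)
})

test_that("residuals of a correctly specified fit are white", {
  pass <- vapply(1:30, function(seed) {
    d <- genLifetime(genSpec("lifetime", seed = seed))
    fit <- fitResults(lifetimeFit(d, 2))
    runs_test_p(fit$residuals) > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("near-equal lifetimes trigger an identifiability warning", {
  d <- genLifetime(genSpec("lifetime", seed = 2,
                           truth = list(tau_ns = c(3.0, 3.05),
                                        fractions = c(0.5, 0.5)),
                           noise = list(sigma_phase = 0, sigma_mod = 0)))
  expect_warning(lifetimeFit(d, 2, start = list(tau_ns = c(2.9, 3.1),
                                                fractions = c(0.5, 0.5))),
                 "identifiable")
})

test_that("lifetime generator is deterministic and range-safe", {
  a <- genLifetime(genSpec("lifetime", seed = 9))
  b <- genLifetime(genSpec("lifetime", seed = 9))
  expect_identical(a@phase_deg, b@phase_deg)
  expect_identical(a@modulation, b@modulation)
  expect_true(all(a@phase_deg >= 0 & a@phase_deg < 90))
  expect_true(all(a@modulation > 0 & a@modulation <= 1))
  expect_error(lifetimeFit(lifetimeData(c(50, 100), c(30, 50),
                                        c(0.9, 0.7)), 2),
               "at least 4")
})
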