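test_that("raw ellipticity normalizes to molar circular dichroism", {
  z <- cdSpectrum(220:340, rep(0, 121))
  expect_equal(normalizeToMolarCD(z, 1e-6, 1)@value, rep(0, 121))
  s <- cdSpectrum(250:270, rep(32.980, 21))
  expect_equal(normalizeToMolarCD(s, 1e-6, 1)@value, rep(1000, 21))
  s2 <- cdSpectrum(250:270, rep(3.298, 21))
  expect_equal(normalizeToMolarCD(s2, 4e-6, 1)@value, rep(25, 21))
  expect_error(normalizeToMolarCD(s, 0, 1), "> 0")
  expect_error(normalizeToMolarCD(s, 1e-6, -1), "> 0")
  expect_error(normalizeToMolarCD(normalizeToMolarCD(s, 1e-6, 1), 1e-6, 1),
               "already")
})

test_that("normalization is linear in the raw signal", {
  set.seed(3)
  v <- rnorm(121)
  a <- 3.7
  s1 <- normalizeToMolarCD(cdSpectrum(220:340, v), 2e-6, 1)
  s2 <- normalizeToMolarCD(cdSpectrum(220:340, a * v), 2e-6, 1)
  expect_equal(s2@value, a * s1@value)
})

test_that("composite spectra are linear and permutation-invariant", {
  comps <- cdComponentSpectra()
  one <- compositeSpectrum(comps["parallel"], 1)
  expect_equal(one@value, resampleSpectrum(comps$parallel, one@wavelength)@value)
  # convexity: averaging a spectrum with itself is the identity
  half <- compositeSpectrum(list(comps$parallel, comps$parallel), c(0.5, 0.5))
  expect_equal(half@value, one@value)
  # (S, w = 2) equals (S + S, w = 1)
  ss <- cdSpectrum(comps$parallel@wavelength, 2 * comps$parallel@value,
                   units = "molar")
  expect_equal(compositeSpectrum(list(comps$parallel), 2)@value,
               compositeSpectrum(list(ss), 1)@value)
  # permutation invariance
  p1 <- compositeSpectrum(comps, c(1, 2, 3))
  p2 <- compositeSpectrum(comps[c(3, 1, 2)], c(3, 1, 2))
  expect_equal(p1@value, p2@value)
  # no common range
  lo <- cdSpectrum(220:240, rep(1, 21), units = "molar")
  hi <- cdSpectrum(300:340, rep(1, 41), units = "molar")
  expect_error(compositeSpectrum(list(lo, hi)), "common wavelength")
})

test_that("quartet-count scaling rescales amplitude and preserves the peak", {
  ref <- parallel_fixture()
  tripled <- quartetScaledPrediction(ref, 9, 3)
  expect_equal(amplitudeAt(tripled, 260), 3 * amplitudeAt(ref, 260))
  expect_equal(quartetScaledPrediction(ref, 3, 3)@value, ref@value)
  doubled <- quartetScaledPrediction(ref, 6, 3)
  expect_equal(doubled@value, 2 * ref@value)
  expect_equal(doubled@wavelength[which.max(doubled@value)],
               ref@wavelength[which.max(ref@value)])
  expect_error(quartetScaledPrediction(ref, 0), ">= 1")
})

test_that("the parallel-topology classifier follows the 260/240 signature", {
  expect_equal(classifyTopology(parallel_fixture()), "parallel")
  flat <- cdSpectrum(220:340, rep(0, 121), units = "molar")
  expect_equal(classifyTopology(flat), "other")
  grid <- 220:340
  anti <- cdSpectrum(grid, 8 * exp(-(grid - 290)^2 / 100), units = "molar")
  expect_equal(classifyTopology(anti), "other")
  narrow <- cdSpectrum(250:270, rep(1, 21), units = "molar")
  expect_error(classifyTopology(narrow), "230-300")
  expect_error(classifyTopology(cdSpectrum(220:340, rep(0, 121))), "molar")
})

test_that("CSV round trip preserves a spectrum", {
  f <- tempfile(fileext = ".csv")
  s <- parallel_fixture()
  writeCDSpectrum(s, f)
  got <- readCDSpectrum(f, units = "molar")
  expect_equal(got@wavelength, s@wavelength)
  expect_equal(got@value, s@value)
})
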