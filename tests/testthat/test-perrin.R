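test_that("polarization follows its definition and flags unphysical values", {
  expect_equal(polarization(1, 1), 0)
  expect_equal(polarization(3, 1), 0.5)
  expect_warning(p <- polarization(1, 0), "one-photon")
  expect_equal(p, 1)
  expect_error(polarization(0, 0), "zero total")
  expect_error(polarization(1, -1), ">= 0")
  expect_equal(polarization(3, 2, G = 0.5), 0.5)
  expect_equal(gratingFactor(0.9, 1.2), 0.75)
  expect_error(gratingFactor(0, 1), "> 0")
})

test_that("correlation time conversions respect both conventions", {
  expect_equal(correlationTime(30.9), 10.3)
  expect_equal(correlationTime(30.9, "inverse"), 92.7)
  expect_equal(3 * correlationTime(correlationTime(9) * 3), 9)
  expect_error(correlationTime(0), "> 0")
})

test_that("sucrose viscosity table hits handbook anchors and is monotone", {
  expect_equal(sucroseViscosity(20, 0), 0.01002)
  expect_equal(sucroseViscosity(0, 0), 0.01787)
  v2020 <- sucroseViscosity(20, 20)
  expect_gt(v2020, 0.0185)
  expect_lt(v2020, 0.0200)
  Tg <- seq(5, 39, 2)
  v <- sucroseViscosity(Tg, 20)
  expect_true(all(diff(v) < 0))
  expect_error(sucroseViscosity(-5, 20), "temperature")
  expect_error(sucroseViscosity(20, 55), "concentration")
})

test_that("noiseless synthetic Perrin data are recovered exactly", {
  spec <- genSpec("perrin", seed = 1,
                  truth = list(rho_ns = 30.9, P0 = 0.46, tau_ns = 2),
                  noise = list(cv = 0))
  series <- genPerrin(spec)
  expect_equal(nrow(series@data), 18)   # 5-39 C at 2 C steps
  fit <- fitResults(perrinFit(series))
  expect_lt(abs(fit$rho_ns - 30.9) / 30.9, 1e-9)
  expect_lt(abs(fit$P0 - 0.46), 1e-9)
  # points lie exactly on the Perrin line
  x <- series@data$temp_K / series@data$eta_poise
  y <- 1 / series@data$P - 1 / 3
  expect_lt(max(abs(residuals(lm(y ~ x)))), 1e-12)
})

test_that("a rigid molecule yields an infinite relaxation time with warning", {
  tk <- seq(278, 312, 2)
  series <- polarizationSeries(tk, sucroseViscosity(tk - 273.15, 20),
                               rep(0.42, length(tk)), tau = 4)
  expect_warning(out <- perrinFit(series), "immobile")
  expect_equal(fitResults(out)$rho_ns, Inf)
  degenerate <- polarizationSeries(rep(293.15, 5), rep(0.01, 5),
                                   seq(0.40, 0.44, 0.01), tau = 4)
  expect_error(perrinFit(degenerate), "degenerate")
  expect_error(perrinFit(polarizationSeries(293:294, c(0.01, 0.01),
                                            c(0.4, 0.41), tau = 4)),
               "3 points")
})

test_that("fitted relaxation times preserve the fast/slow ordering under noise", {
  rho_hat <- function(rho, seed) {
    s <- genPerrin(genSpec("perrin", seed = seed,
                           truth = list(rho_ns = rho, P0 = 0.46,
                                        tau_ns = 2)))
    fitResults(perrinFit(s))$rho_ns
  }
  for (seed in 1:8)
    expect_lt(rho_hat(8.8, seed), rho_hat(31, seed + 100))
})

test_that("generators are seed-deterministic and reject impossible truths", {
  a <- genPerrin(genSpec("perrin", seed = 42))
  b <- genPerrin(genSpec("perrin", seed = 42))
  expect_identical(a@data, b@data)
  c <- genPerrin(genSpec("perrin", seed = 43))
  expect_false(identical(a@data$P, c@data$P))
  expect_error(genPerrin(genSpec("perrin",
                                 truth = list(P0 = 0.52, rho_ns = 1e6))),
               "outside")
  expect_error(genPerrin(genSpec("perrin", truth = list(rho_ns = -1))),
               "> 0")
  expect_equal(a@truth$rho_ns, 8.8)   # ground truth echoed
})
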