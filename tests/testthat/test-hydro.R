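test_that("a single mini-bead has exactly the Stokes friction", {
  sig <- 1.3e-7
  b <- rigidBodyTensors(matrix(0, 1, 3), sig, ETA_W20, 293.15)
  expect_equal(b$f_trans, 6 * pi * ETA_W20 * sig)
})

test_that("shell model reproduces Stokes diffusion for a sphere", {
  R <- 20   # Angstrom
  sigmas <- c(2.0, 1.5, 1.2)
  res <- lapply(sigmas, function(s) {
    beads <- shellBeads(matrix(0, 1, 3), R, s)
    rigidBodyTensors(beads * 1e-8, s * 1e-8, ETA_W20, 293.15)
  })
  Dt <- unname(coef(lm(vapply(res, `[[`, numeric(1), "Dt") ~ sigmas))[1])
  Dr <- unname(coef(lm(vapply(res, function(x) mean(x$Dr_eig), numeric(1))
                       ~ sigmas))[1])
  expect_lt(abs(Dt / stokes_Dt(R * 1e-8) - 1), 0.01)
  expect_lt(abs(Dr / stokes_Dr(R * 1e-8) - 1), 0.02)
  # the isotropic-average relaxation equals the Stokes-Einstein-Debye
  # time 3 eta V / (R T) for the hydrated sphere volume
  rho_sed <- 4 * pi * ETA_W20 * (R * 1e-8)^3 / (KB_ERG * 293.15) * 1e9
  expect_lt(abs(rotationalRelaxation(rep(Dr, 3)) / rho_sed - 1), 0.02)
})

test_that("Kirkwood double sum agrees with the supermatrix on small clusters", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(3:10, 1)
    sig <- 1e-7
    repeat {
      beads <- matrix(rnorm(3 * n, sd = 4e-7), n, 3)
      if (n == 1 || min(dist(beads)) > 2.4 * sig) break
    }
    full <- rigidBodyTensors(beads, sig, ETA_W20, 293.15)$Dt
    kirk <- kirkwoodDt(beads, sig, ETA_W20, 293.15)
    expect_lt(abs(kirk - full) / full, 0.05)
  }
})

test_that("the Svedberg relation behaves and flags buoyancy limits", {
  p <- hydroParams()
  s1 <- sedimentationCoefficient(4e-8, 21632.8, p)
  expect_equal(sedimentationCoefficient(8e-8, 21632.8, p), s1 / 2)
  pneutral <- hydroParams(vbar = 2, rho_solvent = 0.5)
  expect_warning(s0 <- sedimentationCoefficient(4e-8, 21632.8, pneutral),
                 "neutral buoyancy")
  expect_equal(s0, 0)
  expect_error(sedimentationCoefficient(4e-8, 21632.8,
                                        hydroParams(vbar = 1.2)),
               "floats")
  expect_error(sedimentationCoefficient(-1, 21632.8, p), "> 0")
})

test_that("s20,w standardization is exact and invertible", {
  p <- hydroParams()
  expect_equal(s20wStandardize(4.05, 0.01002, 0.99823, p), 4.05)
  expect_equal(s20wStandardize(2.0, 2 * 0.01002, 0.99823, p), 4.0)
  s_obs <- 3.21
  round_trip <- s20wDestandardize(
    s20wStandardize(s_obs, 0.0185, 1.072, p), 0.0185, 1.072, p)
  expect_equal(round_trip, s_obs, tolerance = 1e-12)
  expect_error(s20wStandardize(4, 0.01, 2.2, p), "sign")
})

test_that("frictional ratio conventions bracket the printed value", {
  p <- hydroParams()
  fr_anh <- frictionalRatio(4.05, 21632.8, p, "anhydrous")
  expect_equal(as.numeric(fr_anh), 1.263, tolerance = 0.005)
  fr_hyd <- frictionalRatio(4.05, 21632.8, p, "hydrated")
  expect_equal(as.numeric(fr_hyd), 1.09, tolerance = 0.01)
  expect_equal(attr(fr_hyd, "convention"), "hydrated")
  # the maximally compact hydrated sphere has f/f0(hydrated) = 1
  smax <- maxSphereSedimentation(21632.8, p)
  expect_equal(smax, 4.42, tolerance = 0.01)
  expect_equal(as.numeric(frictionalRatio(smax, 21632.8, p, "hydrated")), 1)
  # monotone: larger s means smaller f/f0 at fixed mass
  expect_lt(as.numeric(frictionalRatio(4.2, 21632.8, p)),
            as.numeric(frictionalRatio(3.8, 21632.8, p)))
})

test_that("equivalent-sphere rotational relaxation matches 3 eta M vbar / RT", {
  p <- hydroParams()
  expect_equal(equivalentSphereRho0(21632.8, p), 14.6, tolerance = 0.01)
  expect_equal(equivalentSphereRho0(0, p), 0)
  expect_equal(equivalentSphereRho0(6991.6, p),
               equivalentSphereRho0(21632.8, p) * 6991.6 / 21632.8)
})

test_that("rotational relaxation and asymmetry ratio follow their closed forms", {
  D <- 5e6
  expect_equal(rotationalRelaxation(c(D, D, D)), 1e9 / (2 * D))
  expect_error(rotationalRelaxation(c(D, -D, D)), "positive")
  expect_equal(asymmetryRatio(30.9, 14.6), 2.116, tolerance = 1e-3)
  expect_equal(asymmetryRatio(14.6, 14.6), 1)
  expect_equal(asymmetryRatio(30.9, 7.3), 2 * asymmetryRatio(30.9, 14.6))
})

test_that("transport properties scale exactly with solvent viscosity", {
  set.seed(5)
  beads <- matrix(rnorm(24, sd = 3e-7), 8, 3)
  sig <- 1e-7
  a <- rigidBodyTensors(beads, sig, ETA_W20, 293.15)
  b <- rigidBodyTensors(beads, sig, 2 * ETA_W20, 293.15)
  expect_equal(b$Dt, a$Dt / 2, tolerance = 1e-10)
  expect_equal(b$Dr_eig, a$Dr_eig / 2, tolerance = 1e-10)
})

test_that("ensemble summaries are sane and order-invariant", {
  st <- xavModel()
  h <- shellModel(st, molecularWeight(referenceSequences()["oneXAV"]))
  one <- ensembleAverage(list(h))
  expect_equal(one$width, rep(0, nrow(one)))
  expect_equal(one$mean[one$property == "s20w"], h@s20w)
  hs <- list(h, h, h)
  expect_equal(ensembleAverage(hs), ensembleAverage(rev(hs)))
  expect_error(ensembleAverage(list()), "empty")
})

test_that("shell resolution cap raises a helpful error", {
  st <- xavModel()
  expect_error(shellModel(st, 6991.6, sigma_ladder = c(1.0, 0.8, 0.6),
                          max_beads = 200),
               "larger sigma")
  expect_error(shellModel(st, 6991.6, sigma_ladder = c(1.0, 1.2, 1.4)),
               "decreasing")
})
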