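test_that("CD mixtures honour their weights and round-trip the classifier", {
  comps <- cdComponentSpectra()
  pure <- genCDMixture(genSpec("cd", truth = list(weights = c(1, 0, 0))),
                       comps)
  expect_equal(classifyTopology(pure), "parallel")
  zero <- genCDMixture(genSpec("cd", truth = list(weights = c(0, 0, 0))),
                       comps)
  expect_equal(zero@value, rep(0, length(zero@value)))
  # tripled parallel content scales the 260-nm amplitude by 3, as the
  # quartet-count prediction requires
  three <- genCDMixture(genSpec("cd", truth = list(weights = c(3, 0, 0))),
                        comps)
  expect_equal(amplitudeAt(three, 260), 3 * amplitudeAt(pure, 260))
  expect_equal(three@value,
               quartetScaledPrediction(pure, 9, 3)@value)
})

test_that("the hybrid and duplex component fixtures are not parallel-like", {
  comps <- cdComponentSpectra()
  expect_equal(classifyTopology(comps$parallel), "parallel")
  expect_equal(classifyTopology(comps$hybrid), "other")
  expect_equal(classifyTopology(comps$duplex), "other")
})

test_that("jitter ensembles keep quartet cores rigid and are seeded", {
  st <- xavModel()
  ens0 <- genJitterEnsemble(st, n = 3, sigma = 0, seed = 1)
  for (m in ens0) expect_identical(m@atoms, st@atoms)
  ens <- genJitterEnsemble(st, n = 3, sigma = 1.0, seed = 5)
  ens2 <- genJitterEnsemble(st, n = 3, sigma = 1.0, seed = 5)
  expect_identical(ens[[2]]@atoms, ens2[[2]]@atoms)
  core <- topology(st)$resid[topology(st)$role == "quartet"]
  sel <- st@atoms$resid %in% core
  for (m in ens)
    expect_equal(atomCoordinates(m)[sel, ], atomCoordinates(st)[sel, ])
  # loop atoms did move
  expect_false(identical(ens[[1]]@atoms, st@atoms))
  # every snapshot satisfies the structural invariants
  for (m in ens) expect_true(validateStructure(m))
  expect_error(genJitterEnsemble(st, 0, 1), ">= 1")
  expect_error(genJitterEnsemble(st, 2, -1), ">= 0")
})

test_that("excessive jitter is rejected by the clash filter", {
  st <- xavModel()
  expect_error(genJitterEnsemble(st, n = 4, sigma = 40, seed = 3),
               "rejects more than half")
})
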