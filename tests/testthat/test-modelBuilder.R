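test_that("a parallel unit has the expected composition and geometry", {
  u <- buildParallelUnit(3, c(1, 2, 1))
  topo <- topology(u)
  expect_equal(sum(topo$role == "quartet"), 12)
  expect_equal(sum(topo$role == "loop"), 4)
  lp <- quartetLayerPositions(u)
  expect_equal(nrow(lp), 3)
  expect_equal(diff(lp$z), c(3.3, 3.3), tolerance = 1e-9)
  expect_error(buildParallelUnit(1, c(1, 1, 1)), "no stack")
  expect_error(buildParallelUnit(3, c(0, 1, 1)), "at least one nucleotide")
})

test_that("builders are deterministic", {
  u1 <- buildParallelUnit(3, c(2, 3, 1))
  u2 <- buildParallelUnit(3, c(2, 3, 1))
  expect_identical(u1@atoms, u2@atoms)
  s1 <- htertStackedModel()
  s2 <- htertStackedModel()
  expect_identical(s1@atoms, s2@atoms)
})

test_that("stacking three units gives nine coaxial layers at the stated spacing", {
  st <- htertStackedModel()
  lp <- quartetLayerPositions(st)
  expect_equal(nrow(lp), 9)
  # 6 intra-unit rises of 3.3 A and 2 interface gaps of 3.4 A
  expect_lt(abs(axialExtent(st) - (6 * 3.3 + 2 * 3.4)), 0.5)
  gaps <- diff(sort(lp$z))
  expect_equal(sort(unique(round(gaps, 2))), c(3.3, 3.4))
  # stacking one unit is the identity
  u <- buildParallelUnit(3, c(1, 2, 1))
  expect_identical(stackUnits(list(u)), u)
  expect_error(stackUnits(list(u, u), interface_gap = 0), "> 0")
})

test_that("the hTERT partition reassembles the 68-mer and builds 68 residues", {
  expect_equal(htertPartitionSequence(),
               unname(referenceSequences()["hTERT"]))
  st <- htertStackedModel()
  expect_equal(nrow(topology(st)), 68)
  expect_equal(sum(topology(st)$role == "quartet"), 36)
})

test_that("beads-on-a-string is extended and unstacked", {
  st <- htertStackedModel()
  bd <- htertBeadsModel()
  expect_gt(radiusOfGyration(bd), radiusOfGyration(st))
  expect_gt(minInterUnitSeparation(bd), 10)
  expect_lt(minInterUnitSeparation(st), 5)
  u <- buildParallelUnit(3, c(1, 2, 1))
  expect_identical(buildBeadsOnString(list(u), list()), u)
  expect_error(buildBeadsOnString(list(u, u), list(character())),
               "linker nucleotide")
})

test_that("the duplex-quadruplex hybrid has an 8-bp B-form stem", {
  hy <- htertHybridModel()
  topo <- topology(hy)
  expect_equal(sum(topo$role == "duplex"), 16)  # 8 bp, two strands
  expect_equal(sum(topo$role == "quartet"), 24) # two 3-quartet units
  expect_lt(abs(duplexDiameter(hy) - 20), 2.5)
  expect_error(buildDuplexQuadruplexHybrid(hairpin_bp = 0),
               "at least one base pair")
})

test_that("quartet layers are planar and models are clash-free by validity", {
  st <- htertStackedModel()
  expect_true(validateStructure(st))
  # a manufactured clash is caught
  bad <- st
  target <- which(bad@atoms$resid == 4)[1]
  sel <- bad@atoms$resid == 40
  bad@atoms$x[sel] <- bad@atoms$x[target]
  bad@atoms$y[sel] <- bad@atoms$y[target]
  bad@atoms$z[sel] <- bad@atoms$z[target]
  expect_error(validateStructure(bad), "clash")
})

test_that("PDB output round-trips coordinates to 0.001 A", {
  u <- xavModel()
  pdb <- tempfile(fileext = ".pdb")
  side <- tempfile(fileext = ".csv")
  writeModelPDB(u, pdb, topology_file = side)
  got <- readModelPDB(pdb, topology_file = side)
  expect_equal(atomCoordinates(got), atomCoordinates(u),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(topology(got)$role, topology(u)$role)
})
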