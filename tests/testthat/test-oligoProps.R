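seqs <- referenceSequences()

test_that("molecular weights reproduce the reference oligonucleotide table", {
  expect_equal(round(molecularWeight(seqs["oneXAV"]), 1), 6991.6)
  expect_lt(abs(molecularWeight(seqs["hTERT"]) - 21632.8), 0.2)
  # closed-form check against an independent composition count
  n <- table(strsplit(as.character(seqs["oneXAV"]), "")[[1]])
  expect_equal(molecularWeight(seqs["oneXAV"]),
               n[["A"]] * 313.21 + n[["G"]] * 329.21 + n[["T"]] * 304.2 -
                 61.96)
})

test_that("nearest-neighbour extinction coefficients match the table", {
  expect_equal(round(extinction260(seqs["oneXAV"]), 1), 228.7)
  expect_equal(round(extinction260(seqs["hTERT"]), 1), 659.3)
  # two-term structure evaluated directly from the shipped table:
  # pairs minus internal monomers (dimer values, vendor convention)
  expect_equal(extinction260("AA"), 27.4)
  expect_equal(extinction260("AAA"), 2 * 27.4 - 15.4)
})

test_that("molecular weight is additive over concatenation", {
  set.seed(11)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:30, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:30, 1), TRUE),
               collapse = "")
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) + 61.96)
  }
})

test_that("homopolymer extinction grows affinely with length", {
  lens <- 2:12
  eps <- vapply(lens, function(L)
    extinction260(strrep("G", L)), numeric(1))
  expect_equal(diff(eps), rep(21.6 - 11.5, length(lens) - 1))
})

test_that("invalid sequences and parameters are rejected", {
  expect_error(molecularWeight(""), "empty")
  expect_error(molecularWeight("ACGU"), "non-ACGT")
  expect_error(extinction260("A"), "length >= 2")
  expect_error(concentrationFromAbsorbance(0.5, -1), "> 0")
  expect_error(concentrationFromAbsorbance(0.5, 100, 0), "> 0")
  expect_error(concentrationFromAbsorbance(-0.1, 100), ">= 0")
})

test_that("Beer-Lambert concentrations are correct", {
  expect_equal(concentrationFromAbsorbance(0, 659.3), 0)
  expect_equal(concentrationFromAbsorbance(0.5, 659.3, 1), 0.758,
               tolerance = 1e-3)
  expect_equal(concentrationFromAbsorbance(0.2287, 228.7, 1), 1.0)
})

test_that("sequence input accepts spacing, FASTA files and DNAStrings", {
  spaced <- "TGA GGG tgg gta ggg tgg gta a"
  expect_equal(molecularWeight(spaced), molecularWeight(seqs["oneXAV"]))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", substr(seqs["hTERT"], 1, 34),
               substr(seqs["hTERT"], 35, 68), ">b", "ACGT"), fa)
  got <- readSequences(fa)
  expect_equal(unname(got["a"]), unname(as.character(seqs["hTERT"])))
  expect_equal(unname(got["b"]), "ACGT")
  tab <- oligoPropertyTable(got)
  expect_equal(tab$mw[tab$name == "a"], 21632.9)
  expect_equal(tab$eps260[tab$name == "b"], round(extinction260("ACGT"), 1))
})
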