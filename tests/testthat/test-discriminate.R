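pred3 <- data.frame(model_id = c("stacked", "beads", "hybrid"),
                    s20w = c(4.00, 3.1, 3.2))

test_that("only the stacked model is consistent with the observed s20,w", {
  out <- compareModels(pred3, c(s20w = 4.05))
  expect_equal(out$model_id[1], "stacked")
  expect_true(out$consistent[out$model_id == "stacked"])
  expect_false(any(out$consistent[out$model_id != "stacked"]))
  expect_equal(sum(out$consistent), 1)
})

test_that("exact predictions score zero and ties break by model id", {
  one <- compareModels(data.frame(model_id = "m", s20w = 4.05),
                       c(s20w = 4.05))
  expect_equal(one$score, 0)
  expect_true(one$consistent)
  twins <- compareModels(data.frame(model_id = c("zeta", "alpha"),
                                    s20w = c(3.5, 3.5)),
                         c(s20w = 4.05))
  expect_equal(twins$model_id, c("alpha", "zeta"))
  expect_equal(twins$score[1], twins$score[2])
})

test_that("ranking is invariant to input order and tolerance rescaling", {
  a <- compareModels(pred3, c(s20w = 4.05))
  b <- compareModels(pred3[c(3, 1, 2), ], c(s20w = 4.05))
  expect_equal(a$model_id, b$model_id)
  c2 <- compareModels(pred3, c(s20w = 4.05), tolerances = c(s20w = 0.05))
  expect_equal(a$model_id, c2$model_id)
})

test_that("multi-property scoring skips unobserved properties with a warning", {
  pred <- data.frame(model_id = c("a", "b"),
                     s20w = c(4.0, 3.1), rho_ns = c(34.4, 67))
  out <- compareModels(pred, c(s20w = 4.05, rho_ns = 30.9))
  expect_true(out$ok_rho_ns[out$model_id == "a"])
  expect_false(out$ok_rho_ns[out$model_id == "b"])
  expect_warning(out2 <- compareModels(pred, c(s20w = 4.05)),
                 "skipped, not imputed")
  expect_false("dev_rho_ns" %in% names(out2))
  expect_error(suppressWarnings(compareModels(pred, c(other = 1))),
               "both predicted and observed")
})

test_that("mutant shift reports classify direction at 2 sigma", {
  rep1 <- mutantShiftReport(4.05, c(m1 = 3.55))
  expect_equal(rep1$delta_s, -0.5)
  expect_equal(rep1$classification, "expanded")
  expect_equal(mutantShiftReport(4.05, c(x = 4.05))$classification,
               "unchanged")
  multi <- mutantShiftReport(4.05, c(3.5, 3.55, 3.6))
  expect_equal(attr(multi, "mean_delta"), -0.5)
  expect_equal(mutantShiftReport(4.0, c(up = 4.2))$classification,
               "compacted")
  expect_error(mutantShiftReport(-1, 3), "> 0")
})
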