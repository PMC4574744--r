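test_that("sigmoid fit recovers known curve parameters", {
  doses <- default_dose_grid()
  y <- 80 / (1 + (1e-10 / doses)^1)
  fit <- fit_dose_response(doses, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$a_max - 80) / 80, 0.01)
  expect_lt(abs(fit$ec50 - 1e-10) / 1e-10, 0.05)
  # IC50 solves the fitted curve at 50%: amax/(1+(ec50/d)^h) = 50
  pred50 <- fit$a_max / (1 + (fit$ec50 / fit$ic50)^fit$hill)
  expect_equal(pred50, 50, tolerance = 1e-6)
})

test_that("flat and sub-50% curves get IC50 at the maximum tested dose", {
  doses <- default_dose_grid()
  flat <- fit_dose_response(doses, rep(0, length(doses)))
  expect_equal(flat$a_max, 0, tolerance = 1e-8)
  expect_identical(flat$ic50, max(doses))

  low <- fit_dose_response(doses, 40 / (1 + (1e-10 / doses)^1))
  expect_lt(low$a_max, 50)
  expect_identical(low$ic50, max(doses))
})

test_that("curve fitting rejects malformed input", {
  expect_error(fit_dose_response(c(1e-9, 2e-9), c(10, 20)), "3 distinct")
  expect_error(fit_dose_response(c(2e-9, 1e-9, 3e-9), c(1, 2, 3)), "ascending")
  expect_error(fit_dose_response(c(1e-9, 2e-9, 4e-9), c(1, NA, 3)), "finite")
})

test_that("sensitivity thresholds apply with closed boundaries", {
  expect_identical(call_sensitivity(75), "sensitive")
  expect_identical(call_sensitivity(40), "insensitive")
  expect_identical(call_sensitivity(60), "intermediate")
  expect_identical(call_sensitivity(70), "sensitive")    # >= 70
  expect_identical(call_sensitivity(50), "insensitive")  # <= 50
  # monotone: increasing Amax never moves toward insensitive
  grid <- seq(0, 100, by = 0.5)
  lv <- c(insensitive = 1, intermediate = 2, sensitive = 3)
  expect_true(all(diff(lv[call_sensitivity(grid)]) >= 0))
})

test_that("consensus vote takes strict majorities and flags ties", {
  expect_identical(consensus_call(c("sensitive", "sensitive", "insensitive")),
                   "sensitive")
  expect_identical(consensus_call(c("sensitive", "insensitive")), "conflict")
  expect_identical(consensus_call("intermediate"), "intermediate")
  expect_identical(
    consensus_call(c("sensitive", "insensitive", "intermediate")), "conflict")
  expect_error(consensus_call(c(NA_character_)), "non-missing")
  # permutation invariance and duplication of the majority element
  set.seed(42)
  for (i in 1:20) {
    calls <- sample(c("sensitive", "intermediate", "insensitive"),
                    sample(1:7, 1), replace = TRUE)
    ref <- consensus_call(calls)
    expect_identical(consensus_call(sample(calls)), ref)
    if (ref != "conflict") {
      expect_identical(consensus_call(c(calls, ref)), ref)
    }
  }
})

test_that("lineage enrichment matches hypergeometric enumeration", {
  # 2x2 table [[8,2],[20,70]]: 8/10 sensitive in lineage vs 20/90 outside
  p_pkg <- fisher_exact_p(8, 2, 20, 70, "greater")
  expect_equal(p_pkg, oracle_fisher_greater(8, 2, 20, 70), tolerance = 1e-12)

  lines <- sprintf("L%03d", 1:100)
  call <- rep("insensitive", 100)
  # lineage A: 10 lines with global-rate sensitivity; global rate 30%
  call[1:30] <- "sensitive"
  lineage <- setNames(c(rep("A", 10), rep("B", 90)), lines)
  call <- c(call[1:3], call[31:37], call[4:30], call[38:100])  # A: 3/10 sens
  cons <- data.frame(cell_line_id = lines, call = call,
                     stringsAsFactors = FALSE)
  enr <- lineage_enrichment(cons, lineage, min_n = 10)
  expect_gt(enr$p_sensitive[enr$lineage == "A"], 0.3)  # no enrichment

  # all sensitives concentrated in one 10-line lineage of 100
  call2 <- c(rep("sensitive", 10), rep("insensitive", 90))
  cons2 <- data.frame(cell_line_id = lines, call = call2,
                      stringsAsFactors = FALSE)
  enr2 <- lineage_enrichment(cons2, lineage, min_n = 10)
  expect_lt(enr2$p_sensitive[enr2$lineage == "A"], 0.05)
  # small lineages are excluded
  lineage3 <- setNames(c(rep("A", 5), rep("B", 95)), lines)
  expect_message(enr3 <- lineage_enrichment(cons2, lineage3, min_n = 10),
                 "excluded")
  expect_false("A" %in% enr3$lineage)
})

test_that("xenograft response formulas follow the printed conditionals", {
  r1 <- in_vivo_response("m1", 100, 150, 100, 300)
  expect_equal(r1$t_over_c, 25)
  expect_true(is.na(r1$regression))
  expect_false(r1$responder)

  r2 <- in_vivo_response("m2", 200, 150, 100, 300)
  expect_true(is.na(r2$t_over_c))
  expect_equal(r2$regression, -25)
  expect_true(r2$responder)

  r3 <- in_vivo_response("m3", 100, 100, 100, 300)  # stasis
  expect_equal(r3$t_over_c, 0)
  expect_true(r3$responder)

  r4 <- in_vivo_response("m4", 100, 150, 300, 100)  # control shrank
  expect_false(r4$valid)
})

test_that("replicate curves are averaged per dose before fitting", {
  doses <- default_dose_grid()
  truth <- 85 / (1 + (2e-10 / doses)^1.2)
  dr <- rbind(
    data.frame(cell_line_id = "c1", screen_id = "s1", dose = doses,
               inhibition = truth + 5, replicate = 1L),
    data.frame(cell_line_id = "c1", screen_id = "s1", dose = doses,
               inhibition = truth - 5, replicate = 2L))
  res <- process_screens(dr)
  expect_equal(nrow(res$fits), 1L)
  expect_lt(abs(res$fits$a_max - 85) / 85, 0.02)
  expect_identical(res$consensus$call, "sensitive")
})
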