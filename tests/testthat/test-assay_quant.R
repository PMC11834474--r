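# qPCR delta-delta-Ct, synergy score, ChIP percent-of-input, metabolite folds.

qpcr_table <- function(conds, ct_t, ct_r) {
  data.frame(condition = conds, ct_target = ct_t, ct_reference = ct_r)
}

test_that("delta-delta-Ct fold changes: identity, one-cycle doubling, replicates", {
  tab <- qpcr_table(c("ctrl", "same", "induced"),
                    c(25, 26, 24), c(20, 21, 20))
  fold <- relative_expression(tab, "ctrl")
  expect_equal(fold[["ctrl"]], 1)
  expect_equal(fold[["same"]], 1)      # ddCt = 0
  expect_equal(fold[["induced"]], 2)   # ddCt = -1

  # replicate Ct values are averaged per condition before differencing
  tab3 <- qpcr_table(rep(c("ctrl", "trt"), each = 3),
                     c(25.0, 25.2, 24.8, 22.1, 22.0, 21.9),
                     c(20.0, 20.1, 19.9, 20.2, 20.0, 20.1))
  fold3 <- relative_expression(tab3, "ctrl")
  dct_ctrl <- mean(c(25.0, 25.2, 24.8)) - mean(c(20.0, 20.1, 19.9))
  dct_trt <- mean(c(22.1, 22.0, 21.9)) - mean(c(20.2, 20.0, 20.1))
  expect_equal(fold3[["trt"]], 2^(-(dct_trt - dct_ctrl)), tolerance = 1e-12)
})

test_that("delta-delta-Ct is invariant to a constant Ct shift and validates input", {
  tab <- qpcr_table(c("ctrl", "trt"), c(25, 22), c(20, 20))
  shifted <- tab
  shifted$ct_target <- shifted$ct_target + 3
  shifted$ct_reference <- shifted$ct_reference + 3
  expect_equal(relative_expression(shifted, "ctrl"),
               relative_expression(tab, "ctrl"))
  expect_error(relative_expression(tab, "missing"), "control")
  tab$ct_reference[1] <- NA
  expect_error(relative_expression(tab, "ctrl"), "reference")
  expect_error(relative_expression(qpcr_table("a", 50, 20), "a"), "\\(0, 45\\]")
})

test_that("synergy score: additive boundary, synergy, and monotonicity", {
  s <- synergy_score(2, 3, 4)
  expect_equal(s$score, 1)
  expect_identical(s$interpretation, "additive")

  s2 <- synergy_score(2, 3, 7)
  expect_equal(s2$score, 0.5)
  expect_identical(s2$interpretation, "synergistic")

  s3 <- synergy_score(1, 1, 5)
  expect_equal(s3$score, 0)  # no single-agent effect, any induction is synergy

  # strictly decreasing in the combined fold for fixed single folds
  scores <- vapply(seq(4.5, 12, by = 0.5),
                   function(ab) synergy_score(2, 3, ab)$score, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores < 1))

  expect_error(synergy_score(2, 3, 1), "exceed 1")
  expect_error(synergy_score(-1, 3, 4), ">= 0")
})

test_that("percent of input: dilution adjustment and per-cycle halving", {
  # ct_ip equal to the adjusted input Ct means 100%
  adj <- 25 - log2(1 / 0.02)
  expect_equal(percent_input(adj, 25, 0.02), 100, tolerance = 1e-12)
  expect_equal(percent_input(adj + 1, 25, 0.02), 50, tolerance = 1e-12)
  # hand evaluation of the stated formula
  expect_equal(percent_input(30, 25, 0.02),
               100 * 2^((25 - log2(50)) - 30), tolerance = 1e-12)
  expect_error(percent_input(30, 25, 0), "\\(0, 1\\]")
})

test_that("percent of input round-trips through its inverse", {
  set.seed(12)
  ct_ip <- runif(20, 20, 35)
  pct <- percent_input(ct_ip, 25, 0.05)
  # invert: ct_ip = adjusted - log2(pct/100)
  back <- (25 - log2(1 / 0.05)) - log2(pct / 100)
  expect_equal(back, ct_ip, tolerance = 1e-10)
})

test_that("metabolite folds: ISTD normalization then ratio to control", {
  rec <- data.frame(
    analyte = rep(c("tryptophan", "kynurenine"), each = 3),
    condition = rep(c("ctrl", "trt", "boost"), 2),
    peak_area = c(100, 100, 200, 50, 100, 25),
    istd_area = c(10, 10, 10, 5, 5, 5))
  out <- metabolite_fold(rec, "ctrl")
  get <- function(an, cc) out$fold[out$analyte == an & out$condition == cc]
  expect_equal(get("tryptophan", "ctrl"), 1)
  expect_equal(get("tryptophan", "trt"), 1)     # identical to control
  expect_equal(get("tryptophan", "boost"), 2)   # doubled area, equal ISTD
  expect_equal(get("kynurenine", "trt"), 2)
  expect_equal(get("kynurenine", "boost"), 0.5)

  # two-step oracle on a replicated table
  set.seed(3)
  rec2 <- data.frame(analyte = "kynurenine",
                     condition = rep(c("ctrl", "trt"), each = 3),
                     peak_area = runif(6, 10, 100),
                     istd_area = runif(6, 4, 6))
  out2 <- metabolite_fold(rec2, "ctrl")
  ratios <- rec2$peak_area / rec2$istd_area
  expected <- mean(ratios[4:6]) / mean(ratios[1:3])
  expect_equal(out2$fold[out2$condition == "trt"], expected, tolerance = 1e-12)
})

test_that("metabolite folds are scale invariant and validated", {
  rec <- data.frame(analyte = "tryptophan", condition = c("ctrl", "trt"),
                    peak_area = c(10, 30), istd_area = c(2, 2))
  scaled <- rec
  scaled$peak_area <- scaled$peak_area * 7
  scaled$istd_area <- scaled$istd_area * 7
  expect_equal(metabolite_fold(scaled, "ctrl")$fold,
               metabolite_fold(rec, "ctrl")$fold)
  rec$peak_area[1] <- 0
  expect_error(metabolite_fold(rec, "ctrl"), "zero control")
  rec$istd_area[1] <- 0
  expect_error(metabolite_fold(rec, "ctrl"), "ISTD")
  expect_error(metabolite_fold(data.frame(analyte = "x", condition = "trt",
                                          peak_area = 1, istd_area = 1), "ctrl"),
               "control")
})
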