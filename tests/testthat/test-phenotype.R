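test_that("percent excreted and engorgement arithmetic anchors", {
  b <- anchor_bug()
  pe <- percent_excreted(b)
  expect_equal(pe$pct_excreted[pe$hour == 24], 50)
  expect_equal(pe$pct_excreted[pe$hour == 12], 100 * (16 - 12) / 12)
  expect_false(any(pe$flagged))

  expect_equal(unname(engorgement_percent(
    data.frame(bug_id = "b", w_prefeed = 4, w_fed = 16.72))), 318)
  expect_equal(unname(engorgement_percent(
    data.frame(bug_id = "b", w_prefeed = 5, w_fed = 10))), 100)
  expect_equal(unname(engorgement_percent(
    data.frame(bug_id = "b", w_prefeed = 5, w_fed = 5))), 0)

  # no weight change at an hour -> 0%; back to prefeed weight -> 100%
  b2 <- data.frame(bug_id = "b", w_prefeed = 4, w_fed = 16,
                   wt_1 = 16, wt_24 = 4)
  pe2 <- percent_excreted(b2)
  expect_equal(pe2$pct_excreted, c(0, 100))
})

test_that("percent excreted rescales with the balance and rejects bad meals", {
  b <- anchor_bug()
  b10 <- b
  b10[c("w_prefeed", "w_fed", "wt_12", "wt_24")] <-
    b10[c("w_prefeed", "w_fed", "wt_12", "wt_24")] * 10
  expect_equal(percent_excreted(b10)$pct_excreted,
               percent_excreted(b)$pct_excreted)
  bad <- b; bad$w_fed <- bad$w_prefeed
  expect_error(percent_excreted(bad), "non-positive meal")
})

test_that("weight increases are flagged, not truncated", {
  b <- data.frame(bug_id = "b", w_prefeed = 4, w_fed = 16,
                  wt_1 = 15, wt_2 = 15.4, wt_24 = 10)
  pe <- percent_excreted(b)
  expect_equal(pe$flagged, c(FALSE, TRUE, FALSE))
  # the non-monotone value is kept as-is
  expect_equal(pe$pct_excreted[2L], 100 * (16 - 15.4) / 12)
})

test_that("urea standard curve fit and validation", {
  cv <- fit_urea_curve(c(0, 10), c(0.05, 0.25))
  expect_equal(cv$slope, 0.02)
  expect_equal(cv$intercept, 0.05)
  expect_equal(cv$r_squared, 1)
  expect_error(fit_urea_curve(c(5, 5), c(0.1, 0.2)), "distinct")
  expect_error(fit_urea_curve(c(0, 5, 10), c(0.2, 0.2, 0.2)), "positive")
})

test_that("urea back-calculation applies the reaction dilution factor", {
  cv <- fit_urea_curve(c(0, 10), c(0.05, 0.25))
  u <- urea_per_bug(0.25, cv)
  expect_equal(u$nmol_reaction, 10)
  expect_equal(u$nmol_per_bug, 50)
  expect_false(u$extrapolated)

  at_blank <- urea_per_bug(0.05, cv)
  expect_equal(at_blank$nmol_per_bug, 0)

  expect_warning(low <- urea_per_bug(0.01, cv), "floored")
  expect_equal(low$nmol_per_bug, 0)
  above <- urea_per_bug(0.40, cv)
  expect_true(above$extrapolated)
  expect_gt(above$nmol_per_bug, 50)
})

test_that("noise-free plate round-trips sample nmol exactly", {
  plate <- sim_urea_plate(0.02, 0.05, standards = c(0, 2, 5, 10),
                          samples = c(10, 3.3), read_noise_sd = 0, seed = 1)
  expect_equal(plate$absorbance[plate$id == "smp1"], 0.25)
  std <- plate[plate$well_type == "standard", ]
  cv <- fit_urea_curve(std$nmol, std$absorbance)
  smp <- plate[plate$well_type == "sample", ]
  u <- urea_per_bug(smp$absorbance, cv)
  expect_equal(u$nmol_reaction, smp$nmol)
  expect_equal(u$nmol_per_bug, smp$nmol * 5)

  only_std <- sim_urea_plate(standards = c(0, 5), samples = numeric(0),
                             seed = 1)
  expect_equal(nrow(only_std), 2L)
  expect_error(sim_urea_plate(standards = c(3, 3)), "distinct")
})

test_that("bug cohort generator matches the stated design", {
  p <- phenotype_sim_params(n_bugs_per_group = 8, seed = 4)
  bugs <- sim_bug_cohort(p)
  expect_equal(nrow(bugs), 16L)
  expect_equal(sort(unique(bugs$group)), c("control", "treatment"))
  expect_true(all(c("wt_1", "wt_2", "wt_3", "wt_4", "wt_6", "wt_8",
                    "wt_12", "wt_24") %in% names(bugs)))
  expect_true(all(bugs$w_fed > bugs$w_prefeed))
  # monotone non-increasing post-feed weights by construction
  wt <- as.matrix(bugs[, paste0("wt_", c(1, 2, 3, 4, 6, 8, 12, 24))])
  expect_true(all(diff(t(wt)) <= 0))
  expect_identical(bugs, sim_bug_cohort(p))

  # engorgement distribution reproduces the 318 +/- 72% design
  big <- sim_bug_cohort(phenotype_sim_params(n_bugs_per_group = 2000,
                                             seed = 8))
  eng <- engorgement_percent(big)
  expect_equal(mean(eng), 318, tolerance = 0.02)
  expect_equal(sd(eng), 72, tolerance = 0.08)
})

test_that("a zero excretion rate leaves weight constant after feeding", {
  bugs <- sim_bug_cohort(phenotype_sim_params(effect_multiplier = 0,
                                              n_bugs_per_group = 3,
                                              seed = 5))
  trt <- bugs[bugs$group == "treatment", ]
  pe <- percent_excreted(trt)
  expect_equal(pe$pct_excreted, rep(0, nrow(pe)))
})

test_that("null cohorts show no expected group difference", {
  diffs <- vapply(1:30, function(k) {
    b <- sim_bug_cohort(phenotype_sim_params(effect_multiplier = 1,
                                             seed = 600 + k))
    endpoint_comparison(b, "excretion_24h")$estimate
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 1)
})

test_that("endpoint comparison reports effect size and handles NAs", {
  b <- sim_bug_cohort(phenotype_sim_params(effect_multiplier = 0.5,
                                           seed = 12))
  cmp <- endpoint_comparison(b, "excretion_24h")
  expect_equal(cmp$method, "welch_t")
  expect_length(cmp$conf_int, 2L)
  expect_gt(cmp$estimate, 0)  # control excretes more than treatment

  b$urea_nmol[1L] <- NA
  expect_message(cmp2 <- endpoint_comparison(b, "urea"), b$bug_id[1L])
  expect_equal(sum(cmp2$group_n), nrow(b) - 1L)

  one_group <- b[b$group == "control", ]
  expect_error(endpoint_comparison(one_group, "eggs"), "exactly 2")
})

test_that("fecundity scenario recovers a doubled egg ratio", {
  b <- sim_bug_cohort(phenotype_sim_params(n_bugs_per_group = 300,
                                           fecundity_multiplier = 2,
                                           seed = 77))
  m <- tapply(b$eggs_total, b$group, mean)
  expect_equal(unname(m[["treatment"]] / m[["control"]]), 2,
               tolerance = 0.15)
  cmp <- endpoint_comparison(b, "eggs")
  expect_lt(cmp$p_value, 0.001)
  # daily series accounts for every egg
  daily <- attr(b, "eggs_daily")
  expect_equal(sum(daily$eggs), sum(b$eggs_total))
})
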