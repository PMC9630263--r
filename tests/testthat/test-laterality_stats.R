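# Laterality classification, pairing and the paired statistics.

test_that("IPLAG mapping and dominance-relative side", {
  expect_identical(classify_laterality(1L), "left")
  expect_identical(classify_laterality(2L), "left")
  expect_identical(classify_laterality(4L), "right")
  expect_identical(classify_laterality(5L), "right")
  expect_error(classify_laterality(3L), "unclassifiable")
  expect_error(classify_laterality(0L), "1..5")
  expect_identical(assign_relative_side("right", "right"), "DLL")
  expect_identical(assign_relative_side("left", "right"), "NDLL")
  expect_identical(assign_relative_side("left", "left"), "DLL")
})

test_that("Shapiro-Wilk wrapper enforces preconditions and detects non-normality", {
  normalish <- qnorm(ppoints(20))
  sw <- shapiro_wilk(normalish)
  expect_gt(sw$W, 0.99)
  set.seed(404)
  bimodal <- c(rnorm(25, -4, 0.1), rnorm(25, 4, 0.1))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "\\[3, 5000\\]")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("paired t-test: identities, conventions and the hand-computed example", {
  a <- c(5, 7, 9, 8); b <- c(4, 5, 6, 6)   # d = 1, 2, 3, 2
  tt <- paired_t_test(a, b)
  expect_equal(tt$t, 4.899, tolerance = 1e-3)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-4.898979, 3), tolerance = 1e-5)
  # a = b: t = 0, p = 1
  same <- paired_t_test(a, a)
  expect_identical(c(same$t, same$p), c(0, 1))
  # constant non-zero shift: degenerate, p -> 0 with a warning
  expect_warning(deg <- paired_t_test(a + 2, a), "constant")
  expect_identical(c(deg$t, deg$p), c(Inf, 0))
  expect_error(paired_t_test(1, 2), "2 pairs")
  # invariances: common shift preserves p; swapping negates t
  set.seed(505)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  expect_equal(paired_t_test(x + 7, y + 7)$p, paired_t_test(x, y)$p,
               tolerance = 1e-12)
  expect_equal(paired_t_test(y, x)$t, -paired_t_test(x, y)$t,
               tolerance = 1e-12)
  expect_equal(paired_t_test(y, x)$p, paired_t_test(x, y)$p,
               tolerance = 1e-12)
})

test_that("Cohen's d: closed forms, closed-form and realistic-summary checks and scaling", {
  z <- c(-1, 0, 1)  # sd exactly 1, mean 0
  expect_equal(cohens_d(z, z), 0)
  expect_equal(cohens_d(z, z + 1), 1.0, tolerance = 1e-12)
  # realistic average-velocity group summaries under the two rules: the
  # pooled-SD formula gives 1.70 on these exact means/SDs (other d
  # conventions give slightly different values; only pooled is asserted)
  a <- 2.836 + 0.2 * z
  b <- 3.179 + 0.203 * z
  expect_equal(cohens_d(a, b), 1.70, tolerance = 5e-3)
  # shift invariance and separation scaling at fixed SDs
  expect_equal(cohens_d(a + 3, b + 3), cohens_d(a, b), tolerance = 1e-12)
  expect_equal(cohens_d(z, z + 2), 2 * cohens_d(z, z + 1), tolerance = 1e-12)
  # paired_diff variant
  expect_equal(cohens_d(z + 1, z, method = "paired_diff"), Inf)
  set.seed(606)
  x <- rnorm(8); y <- x + rnorm(8, 1, 0.5)
  expect_equal(cohens_d(x, y, method = "paired_diff"),
               abs(mean(x - y)) / sd(x - y), tolerance = 1e-12)
})

make_results <- function(n_subj = 6, per_cell = 5, effect = 0, seed = 1) {
  # lightweight synthetic variable table (no signal processing): one
  # outcome column is enough to exercise pairing
  set.seed(seed)
  g <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                   rule = c("old", "new"), side = c("left", "right"),
                   rep = seq_len(per_cell), stringsAsFactors = FALSE)
  g$iplag_score <- ifelse(g$subject_id == "S01", 2L, 4L)
  g$APD <- 0.25 + effect * (g$rule == "new") + rnorm(nrow(g), 0, 0.02)
  g$trial_id <- sprintf("%s_%03d", g$subject_id, seq_len(nrow(g)))
  g
}

test_that("pairing: subject means, trial matching and surplus handling", {
  res <- make_results()
  pr <- build_pairs(res, "APD", design = "rule", pairing_mode = "subject_mean")
  expect_length(pr$a, 6)
  expect_identical(c(pr$label_a, pr$label_b), c("OR", "NR"))
  # drop one new-rule trial of one subject: trial_matched drops the surplus
  res1 <- res[res$subject_id == "S02", ]
  res1 <- res1[-which(res1$rule == "new")[1], ]
  pr1 <- build_pairs(res1, "APD", design = "rule", pairing_mode = "trial_matched")
  expect_length(pr1$a, 9)
  expect_identical(pr1$dropped$reason, "surplus_trials")
  expect_equal(pr1$dropped$n_dropped, 1)
  # fewer than 2 pairs is an error
  expect_error(build_pairs(res[res$subject_id == "S01", ], "APD",
                           design = "rule"), "fewer than 2 pairs")
})

test_that("the optional normality gate aborts on non-normal groups", {
  res <- make_results()
  # inject a grossly non-normal outcome: one huge outlier per condition
  res$APD[res$rule == "old"][1] <- 50
  expect_error(run_analysis(res, designs = "rule", variables = "APD",
                            pairing_mode = "trial_matched",
                            shapiro_gate = TRUE),
               "normality gate")
  # default: reported, not gated
  expect_s3_class(run_analysis(res, designs = "rule", variables = "APD",
                               pairing_mode = "trial_matched"),
                  "analysis_report")
})

test_that("the full report has the three-figure structure and detects injected effects", {
  res <- make_results(effect = 0.25)
  rep <- run_analysis(res, variables = "APD")
  expect_equal(nrow(rep), 4)
  expect_identical(sort(unique(rep$design)),
                   sort(c("rule", "laterality", "rule_within_dominant",
                          "rule_within_nondominant")))
  rule_row <- rep[rep$design == "rule", ]
  expect_true(rule_row$significant)
  expect_lt(rule_row$t, 0)  # new rule (group b) larger
  expect_gt(rule_row$mean_b, rule_row$mean_a)
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_identical(rep$significant, rep$p <= 0.05)
})
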