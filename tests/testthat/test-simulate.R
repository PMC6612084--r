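test_that("the default outcome profile matches the reference per-condition rates", {
  prof <- outcome_profile()
  expect_equal(prof$probs, c(7, 6, 10, 10, 16, 9, 11, 12, 5) / 30)
  expect_error(outcome_profile(rep(0.5, 8)), "9")
  expect_error(outcome_profile(c(rep(0.5, 8), 1.2)), "0, 1")
})

test_that("generated runs have the planned shape and seeded reproducibility", {
  plan <- ref_plan()
  runs <- generate_runs(plan, outcome_profile(), seed = 4)
  expect_equal(nrow(runs), 270L)
  expect_equal(as.vector(table(runs$condition)), rep(30L, 9))
  expect_true(all(runs$outcome %in% c("defective", "good")))
  # level columns follow the design row of each condition
  expect_equal(as.matrix(unique(runs[, c("A", "B", "C", "D")])),
               unclass(plan$design), ignore_attr = TRUE)
  expect_identical(generate_runs(plan, seed = 4), runs)
  expect_false(identical(generate_runs(plan, seed = 5), runs))
})

test_that("degenerate profiles propagate as expected", {
  plan <- ref_plan()
  none <- generate_runs(plan, outcome_profile(rep(0, 9)), seed = 1)
  expect_equal(sum(none$outcome == "defective"), 0L)
  all_bad <- generate_runs(plan, outcome_profile(rep(1, 9)), seed = 1)
  expect_true(all(all_bad$outcome == "defective"))
  eff <- accumulate_effects(plan, all_bad)
  sel <- select_optimal_levels(eff)
  expect_error(predict_combination(eff, sel), "strictly in|continuity")
})

test_that("per-condition defective counts are binomial around 30p", {
  plan <- ref_plan()
  prof <- outcome_profile()
  n_rep <- 400
  counts <- matrix(0, n_rep, 9)
  for (r in seq_len(n_rep)) {
    runs <- generate_runs(plan, prof, seed = 10000 + r)
    tab <- runs_to_conditions(runs)
    counts[r, ] <- tab$defective
  }
  for (cc in 1:9) {
    expected <- 30 * prof$probs[cc]
    se <- sqrt(30 * prof$probs[cc] * (1 - prof$probs[cc]) / n_rep)
    expect_lt(abs(mean(counts[, cc]) - expected), 3 * se + 1e-9)
  }
})

test_that("the profile's ground-truth combination matches the analytic argmin", {
  expect_equal(profile_best_combination(outcome_profile()), "A1B3C2D2")
  # a profile tilted toward condition structure favouring level 3 of A
  p <- c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.1, 0.1, 0.1)
  expect_equal(substr(profile_best_combination(outcome_profile(p)), 1, 2), "A3")
})

test_that("patient generation respects categorical weights", {
  prof <- covariate_profile("counts")
  pat <- generate_patients(270, prof, seed = 2)
  expect_equal(nrow(pat), 270L)
  expect_setequal(setdiff(names(pat), "patient_id"), names(prof$weights))
  one <- generate_patients(1, prof, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one))
  # gender frequencies converge to the 127:143 weights over repeated draws
  males <- vapply(1:60, function(s)
    mean(generate_patients(270, prof, seed = s)$gender == "male"), numeric(1))
  p_male <- 127 / 270
  se <- sqrt(p_male * (1 - p_male) / (60 * 270))
  expect_lt(abs(mean(males) - p_male), 4 * se)
})

test_that("the improved physiological profile shifts the normal shares", {
  prof <- covariate_profile("improved")
  w <- prof$weights$hematocrit
  expect_equal(unname(w["normal"]) / sum(w), 0.322, tolerance = 1e-6)
  expect_equal(unname(prof$weights$transferrin_saturation["normal"]) /
                 sum(prof$weights$transferrin_saturation), 0.79)
  # long-run frequency matches the configured share
  hits <- vapply(1:60, function(s)
    mean(generate_patients(270, prof, seed = 100 + s)$hematocrit == "normal"),
    numeric(1))
  se <- sqrt(0.322 * (1 - 0.322) / (60 * 270))
  expect_lt(abs(mean(hits) - 0.322), 4 * se)
})

test_that("fixtures load as typed objects with the published totals", {
  t4 <- load_fixture("table4")
  expect_equal(t4$defective[t4$condition == 5], 16)
  expect_equal(t4$good[t4$condition == 5], 14)
  expect_equal(sum(t4$defective), 86)
  expect_equal(sum(t4$good), 184)
  expect_equal(sum(t4$sample), 270)
  t10 <- load_fixture("table10")
  expect_equal(c(t10$defective, t10$good, t10$total), c(35, 235, 270))
  expect_identical(load_fixture("table3"), unclass(build_l9()),
                   ignore_attr = TRUE)
  f <- load_fixture("table2")
  expect_equal(vapply(f, function(x) x$name, character(1)),
               c(A = "A", B = "B", C = "C", D = "D"))
  expect_equal(f$B$values, c(200, 250, 300))
  t5 <- load_fixture("table5")
  expect_true(all(tapply(t5$count, t5$characteristic, sum) == 270))
  t6 <- load_fixture("table6")
  expect_true(all(tapply(t6$count, t6$characteristic, sum) == 270))
  expect_error(load_fixture("table99"), "unknown fixture")
})

test_that("table4 counts re-aggregate exactly to the published effect counts", {
  eff <- ref_effects()
  expect_equal(eff$defective,
               c(23, 35, 28, 28, 34, 24, 28, 21, 37, 28, 26, 32))
  expect_true(all(eff$total == 90))
})
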