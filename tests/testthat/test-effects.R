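test_that("accumulation reproduces the reference per-level counts and rates", {
  eff <- ref_effects()
  get <- function(f, l, col) eff[eff$factor == f & eff$level == l, col]
  expect_equal(get("A", 1, "defective"), 23)
  expect_equal(get("A", 1, "total"), 90)
  expect_equal(round(get("A", 1, "rate"), 2), 0.26)
  expect_equal(get("C", 2, "defective"), 21)
  expect_equal(get("C", 3, "defective"), 37)
  expect_equal(get("B", 3, "defective"), 24)
  expect_equal(get("D", 2, "defective"), 26)
  expect_equal(attr(eff, "total_defective"), 86)
  expect_equal(attr(eff, "total_sample"), 270)
})

test_that("per-level defectives conserve the overall total for every factor", {
  eff <- ref_effects()
  for (f in unique(eff$factor))
    expect_equal(sum(eff$defective[eff$factor == f]),
                 attr(eff, "total_defective"))
})

test_that("accumulation is invariant to condition order and matches a brute-force tally", {
  plan <- ref_plan()
  set.seed(71)
  for (rep in 1:20) {
    res <- as.data.frame(cbind(condition = 1:9, unclass(plan$design)))
    res$defective <- sample(0:30, 9, replace = TRUE)
    res$sample <- 30L
    res$good <- res$sample - res$defective
    eff <- accumulate_effects(plan, res)
    shuffled <- res[sample(9), ]
    eff2 <- accumulate_effects(plan, shuffled)
    expect_equal(eff, eff2)
    oracle <- tally_oracle(plan$design, res$defective, res$sample)
    for (k in seq_len(nrow(eff))) {
      key <- paste0(eff$factor[k], eff$level[k])
      expect_equal(eff$defective[k], unname(oracle[[key]]["defective"]))
      expect_equal(eff$total[k], unname(oracle[[key]]["total"]))
    }
  }
})

test_that("all-zero defectives give zero rates throughout", {
  plan <- ref_plan()
  res <- as.data.frame(cbind(condition = 1:9, unclass(plan$design)))
  res$defective <- 0L; res$good <- 30L; res$sample <- 30L
  eff <- accumulate_effects(plan, res)
  expect_true(all(eff$rate == 0))
  expect_equal(attr(eff, "overall_rate"), 0)
})

test_that("malformed condition results are rejected", {
  plan <- ref_plan()
  res <- load_fixture("table4")
  expect_error(accumulate_effects(plan, res[-3, ]), "cover conditions")
  dup <- rbind(res, res[1, ])
  expect_error(accumulate_effects(plan, dup), "duplicate")
  bad <- res; bad$A[2] <- 3L
  expect_error(accumulate_effects(plan, bad), "match the design")
  bad2 <- res; bad2$good[1] <- 5L
  expect_error(accumulate_effects(plan, bad2), "sample")
})

test_that("per-run records reduce to the same effect table as counts", {
  runs <- conditions_to_runs(load_fixture("table4"))
  expect_equal(nrow(runs), 270L)
  eff_runs <- accumulate_effects(ref_plan(), runs)
  expect_equal(eff_runs, ref_effects())
})

test_that("smaller-the-better selection picks A1B3C2D2 on the reference data", {
  sel <- select_optimal_levels(ref_effects())
  expect_equal(attr(sel, "combination"), "A1B3C2D2")
  expect_equal(sel$level[sel$factor == "B"], 3L)
})

test_that("larger-the-better selection matches an argmax oracle", {
  eff <- ref_effects()
  sel <- select_optimal_levels(eff, direction = "larger")
  # independent argmax over the published rates
  oracle <- vapply(split(as.data.frame(eff), eff$factor),
                   function(d) d$level[which.max(d$rate)], numeric(1))
  expect_equal(attr(sel, "combination"), "A2B2C3D3")
  expect_equal(sel$level, unname(oracle[sort(names(oracle))]))
})

test_that("ties select the lowest level index", {
  plan <- ref_plan()
  res <- as.data.frame(cbind(condition = 1:9, unclass(plan$design)))
  res$defective <- 6L; res$good <- 24L; res$sample <- 30L
  sel <- select_optimal_levels(accumulate_effects(plan, res))
  expect_equal(attr(sel, "combination"), "A1B1C1D1")
})
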