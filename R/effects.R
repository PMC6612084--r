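#' Collapse per-run binary outcomes to per-condition counts
#'
#' Run-level records (one row per dialyzer, outcome "defective" or "good")
#' are reduced to the per-condition count form consumed by the accumulation
#' analysis.  Level columns must be consistent within each condition.
#'
#' @param runs Data frame with columns `condition`, `A`, `B`, `C`, `D`, and
#'   `outcome` in `c("defective", "good")`.
#' @return Data frame with columns `condition`, `A`-`D`, `defective`,
#'   `good`, `sample`, one row per condition, ordered by condition.
#' @export
runs_to_conditions <- function(runs) {
  need <- c("condition", "A", "B", "C", "D", "outcome")
  miss <- setdiff(need, names(runs))
  if (length(miss))
    stop("per-run records lack columns: ", paste(miss, collapse = ", "))
  if (!all(runs$outcome %in% c("defective", "good")))
    stop("outcome must be 'defective' or 'good'")
  sp <- split(runs, runs$condition)
  out <- lapply(sp, function(d) {
    lev <- unique(d[, c("A", "B", "C", "D")])
    if (nrow(lev) != 1L)
      stop("condition ", d$condition[1L],
           " has inconsistent factor levels across runs")
    data.frame(condition = d$condition[1L], lev,
               defective = sum(d$outcome == "defective"),
               good = sum(d$outcome == "good"),
               sample = nrow(d), row.names = NULL)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_condition_results <- function(plan, results) {
  need <- c("condition", "A", "B", "C", "D", "defective", "good", "sample")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("condition results lack columns: ", paste(miss, collapse = ", "))
  if (nrow(results) == 0L)
    stop("empty condition results")
  if (anyDuplicated(results$condition))
    stop("duplicate condition ids in results")
  if (!setequal(results$condition, seq_len(nrow(plan$design))))
    stop("results must cover conditions 1..", nrow(plan$design),
         " exactly once")
  results <- results[order(results$condition), , drop = FALSE]
  lev <- as.matrix(results[, c("A", "B", "C", "D")])
  if (!all(lev == unclass(plan$design)))
    stop("factor levels in results do not match the design matrix")
  cnt <- as.matrix(results[, c("defective", "good", "sample")])
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (!all(results$defective + results$good == results$sample))
    stop("defective + good must equal sample in every condition")
  results
}

#' Accumulate defective counts per factor level
#'
#' For each factor F and level l, sums the defective counts over the three
#' design rows where F = l; each accumulated total covers 3 x
#' runs-per-condition dialyzers (90 in the reference experiment).  The
#' accumulated defect rate is the per-level defective count over that total.
#' This is the count-value (attribute data) accumulation analysis used in
#' place of a variance-based signal-to-noise ratio.
#'
#' @param plan An `experiment_plan`.
#' @param results Data frame of per-condition counts (columns `condition`,
#'   `A`-`D`, `defective`, `good`, `sample`), one row per design row, or a
#'   per-run data frame accepted by [runs_to_conditions()].
#' @return An `effect_table`: data frame with columns `factor`, `level`,
#'   `defective`, `total`, `rate`, plus attributes `total_defective`,
#'   `total_sample`, `overall_rate`.
#' @examples
#' plan <- make_plan(dialyzer_factors(), 30)
#' eff <- accumulate_effects(plan, load_fixture("table4"))
#' subset(eff, factor == "A")   # 23/35/28 defective of 90
#' @export
accumulate_effects <- function(plan, results) {
  if (!inherits(plan, "experiment_plan")) stop("plan must be an experiment_plan")
  if ("outcome" %in% names(results)) results <- runs_to_conditions(results)
  results <- check_condition_results(plan, results)
  fac <- colnames(plan$design)
  rows <- list()
  for (f in fac) {
    for (l in 1:3) {
      idx <- results[[f]] == l
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, level = l,
        defective = sum(results$defective[idx]),
        total = sum(results$sample[idx]),
        stringsAsFactors = FALSE)
    }
  }
  eff <- do.call(rbind, rows)
  eff$rate <- eff$defective / eff$total
  attr(eff, "total_defective") <- sum(results$defective)
  attr(eff, "total_sample") <- sum(results$sample)
  attr(eff, "overall_rate") <- sum(results$defective) / sum(results$sample)
  class(eff) <- c("effect_table", class(eff))
  eff
}

#' @export
print.effect_table <- function(x, digits = 2, ...) {
  cat("Accumulated factor-level effects (defective counts and rates):\n")
  df <- data.frame(factor = x$factor, level = x$level,
                   defective = x$defective, total = x$total,
                   rate = round(x$rate, digits))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Overall: %d / %d defective (rate %.*f)\n",
              attr(x, "total_defective"), attr(x, "total_sample"),
              digits, attr(x, "overall_rate")))
  invisible(x)
}

#' Select the best level of each factor
#'
#' With the smaller-the-better objective the chosen level of each factor is
#' the one with the lowest accumulated defect rate (argmax for
#' larger-the-better).  Ties are broken toward the lowest level index so the
#' selection is deterministic.
#'
#' @param effects An `effect_table` from [accumulate_effects()].
#' @param direction `"smaller"` (default; minimise the defect rate) or
#'   `"larger"`.
#' @return A `level_selection`: data frame with columns `factor`, `level`,
#'   `rate`, and attribute `combination` (label such as `"A1B3C2D2"`).
#' @examples
#' plan <- make_plan(dialyzer_factors(), 30)
#' sel <- select_optimal_levels(accumulate_effects(plan, load_fixture("table4")))
#' attr(sel, "combination")  # "A1B3C2D2"
#' @export
select_optimal_levels <- function(effects, direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  if (!inherits(effects, "effect_table") || nrow(effects) == 0L)
    stop("effects must be a non-empty effect_table")
  pick <- function(d) {
    i <- if (direction == "smaller") which.min(d$rate) else which.max(d$rate)
    # which.min/max already break ties toward the first (lowest) level
    d[i, c("factor", "level", "rate")]
  }
  sel <- do.call(rbind, lapply(split(effects, effects$factor), pick))
  sel <- sel[order(sel$factor), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "combination") <- paste0(sel$factor, sel$level, collapse = "")
  attr(sel, "direction") <- direction
  class(sel) <- c("level_selection", class(sel))
  sel
}

#' @export
print.level_selection <- function(x, ...) {
  cat(sprintf("Selected combination (%s-the-better): %s\n",
              attr(x, "direction"), attr(x, "combination")))
  print.data.frame(data.frame(factor = x$factor, level = x$level,
                              rate = round(x$rate, 4)), row.names = FALSE)
  invisible(x)
}
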