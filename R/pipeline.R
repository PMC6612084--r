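#' Expand per-condition counts to per-run records
#'
#' Deterministic expansion of count data into run-level rows (defective runs
#' first within each condition), the form consumed by the network encoder.
#' It is the inverse of [runs_to_conditions()] up to run order.
#'
#' @param counts Per-condition data frame (`condition`, `A`-`D`,
#'   `defective`, `good`, `sample`).
#' @return Per-run data frame (`run_id`, `condition`, `A`-`D`, `outcome`).
#' @export
conditions_to_runs <- function(counts) {
  need <- c("condition", "A", "B", "C", "D", "defective", "good")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("condition counts lack columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    data.frame(condition = r$condition, A = r$A, B = r$B, C = r$C, D = r$D,
               outcome = rep(c("defective", "good"), c(r$defective, r$good)),
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, out)
  cbind(run_id = seq_len(nrow(runs)), runs)
}

#' Confirmation-experiment arithmetic
#'
#' Summarises follow-up runs at the selected combination.  The headline
#' percentage is truncated (not rounded) to one decimal, matching the
#' convention under which 35 defective of 270 is reported as 12.9%; the
#' exact proportion is kept alongside.
#'
#' @param defective,total Confirmation counts, or a one-row data frame such
#'   as `load_fixture("table10")` passed as `defective`.
#' @return List with `defective`, `total`, `rate` (exact proportion) and
#'   `percent` (truncated to 1 decimal).
#' @examples
#' confirmation_summary(load_fixture("table10"))  # 12.9
#' @export
confirmation_summary <- function(defective, total = NULL) {
  if (is.data.frame(defective)) {
    total <- defective$total[1L]
    defective <- defective$defective[1L]
  }
  if (defective < 0 || total <= 0 || defective > total)
    stop("need 0 <= defective <= total")
  rate <- defective / total
  list(defective = defective, total = total, rate = rate,
       percent = floor(1000 * rate) / 10)
}

#' Run the full analysis workflow
#'
#' Executes the complete chain: accumulate per-factor-level defective
#' counts, select the smaller-the-better level combination, predict its
#' defect rate through the omega transformation (both rounding modes),
#' train the back-propagation network on the run-level records as a
#' stability check, and — when confirmation counts are supplied — report
#' the confirmation arithmetic.  A non-converged network is reported, not
#' fatal: in the workflow this package reproduces it sends the analyst back
#' to factor selection rather than aborting the analysis.
#'
#' @param results Per-condition counts or per-run records; defaults to the
#'   packaged reference experiment (`load_fixture("table4")`).
#' @param plan An `experiment_plan`.
#' @param confirmation Optional confirmation counts (data frame with
#'   `defective` and `total`, e.g. `load_fixture("table10")`).
#' @param encoding Network target encoding, `"proportion"` or `"binary"`.
#' @param hidden_units,epochs,seed Network settings (see [bpn_config()]).
#' @param run_bpn Set `FALSE` to skip network training (the Taguchi/omega
#'   stages are deterministic and fast; training dominates the runtime).
#' @return A `pipeline_report` list: `effects`, `selection`,
#'   `prediction_paper`, `prediction_full`, `baseline_rate`, `bpn`
#'   (a `bpn_fit` or `NULL`), `confirmation` (or `NULL`).
#' @examples
#' rep <- run_pipeline(run_bpn = FALSE)
#' attr(rep$selection, "combination")       # "A1B3C2D2"
#' rep$prediction_paper$combined_db         # 8.19
#' @export
run_pipeline <- function(results = load_fixture("table4"),
                         plan = make_plan(dialyzer_factors(), 30L),
                         confirmation = NULL,
                         encoding = c("proportion", "binary"),
                         hidden_units = hidden_units_rule(),
                         epochs = 500L, seed = 1L, run_bpn = TRUE) {
  encoding <- match.arg(encoding)
  effects <- tryCatch(accumulate_effects(plan, results),
                      error = function(e) stop("stage effect_analysis: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  selection <- select_optimal_levels(effects)
  pred_paper <- predict_combination(effects, selection, rounding = "paper")
  pred_full <- predict_combination(effects, selection, rounding = "full")

  fit <- NULL
  if (run_bpn) {
    runs <- if ("outcome" %in% names(results)) results
            else conditions_to_runs(results)
    enc <- encode_records(runs, plan, target = encoding)
    sets <- split_data(enc, seed = seed)
    cfg <- bpn_config(n_inputs = enc$n_inputs, hidden_units = hidden_units,
                      epochs = epochs, seed = seed)
    fit <- bpn_train(cfg, sets$train, sets$validation, sets$test)
  }

  conf <- if (!is.null(confirmation)) confirmation_summary(confirmation)

  structure(
    list(effects = effects, selection = selection,
         prediction_paper = pred_paper, prediction_full = pred_full,
         baseline_rate = attr(effects, "overall_rate"),
         bpn = fit, confirmation = conf, seed = seed),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Dialyzer solidification analysis ==\n")
  cat(sprintf("[effect_analysis] 9 conditions, %d runs; baseline defect rate %d/%d = %.0f%%\n",
              attr(x$effects, "total_sample"),
              attr(x$effects, "total_defective"),
              attr(x$effects, "total_sample"), 100 * x$baseline_rate))
  cat(sprintf("[selection] %s\n", attr(x$selection, "combination")))
  cat(sprintf("[omega] paper rounding: %.2f dB -> %.2f%%; full precision: %.4f dB -> %.2f%%\n",
              x$prediction_paper$combined_db,
              100 * x$prediction_paper$predicted_rate,
              x$prediction_full$combined_db,
              100 * x$prediction_full$predicted_rate))
  if (!is.null(x$bpn)) {
    r <- x$bpn$report
    cat(sprintf("[bpn] final training MSE %.3g; %s\n", attr(r, "final_mse"),
                if (attr(r, "converged"))
                  sprintf("converged at epoch %d", attr(r, "convergence_epoch"))
                else "not converged"))
  }
  if (!is.null(x$confirmation))
    cat(sprintf("[confirmation] %d/%d defective = %.1f%%\n",
                x$confirmation$defective, x$confirmation$total,
                x$confirmation$percent))
  invisible(x)
}
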