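#' Omega transformation: defect rate to decibels
#'
#' Maps a defect proportion to the decibel scale via
#' Omega = 10 * log10((1 - P) / P), the logit in decibels.  On this scale
#' factor-level effects combine additively, which is what makes the
#' prediction for an untested level combination possible from the
#' accumulated per-level rates.  Strictly decreasing in P; 0 dB at P = 0.5.
#'
#' @param p Defect proportion(s), strictly inside (0, 1).
#' @return dB value(s).
#' @examples
#' omega_db(0.26)  # 4.54 dB
#' omega_db(0.5)   # 0 dB
#' @export
omega_db <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("defect proportion must lie strictly in (0, 1); ",
         "use a continuity correction for degenerate rates")
  10 * log10((1 - p) / p)
}

#' Inverse omega transformation: decibels to defect rate
#'
#' Back-transforms a dB value to a proportion via P = 1 / (1 + 10^(Omega/10)),
#' the exact inverse of [omega_db()].
#'
#' @param db Finite dB value(s).
#' @return Defect proportion(s) in (0, 1).
#' @examples
#' inverse_omega(8.19)  # 0.1317
#' inverse_omega(0)     # 0.5
#' @export
inverse_omega <- function(db) {
  if (!is.numeric(db) || any(!is.finite(db)))
    stop("dB value must be finite")
  1 / (1 + 10^(db / 10))
}

#' Haldane-style continuity correction for degenerate rates
#'
#' Replaces x/n by (x + 0.5)/(n + 1) so that rates of exactly 0 or 1 become
#' transformable.  Never applied automatically: a silent correction would
#' change reproduced numbers, so callers opt in explicitly.
#'
#' @param x Defective count(s).
#' @param n Total count(s).
#' @return Corrected proportion(s), strictly inside (0, 1).
#' @export
continuity_correct <- function(x, n) {
  if (any(x < 0) || any(n <= 0) || any(x > n)) stop("need 0 <= x <= n, n > 0")
  (x + 0.5) / (n + 1)
}

#' Predict the defect rate of a selected level combination
#'
#' The additive-in-dB estimate for a combination of m selected levels:
#' Omega(comb) = sum of the m selected levels' dB values minus (m - 1) times
#' the dB value of the overall defect rate; the predicted rate is the
#' back-transform of the combined estimate.  Each level's deviation from the
#' overall performance is added on the dB scale, so the overall term is
#' counted once instead of m times.
#'
#' `rounding = "paper"` mirrors a hand calculation carried out on printed
#' 2-decimal intermediates: rates are rounded to 2 decimals before the
#' transformation, dB values to 2 decimals before combining, and the
#' combined dB to 2 decimals before back-transforming.  `rounding = "full"`
#' (recommended for new analyses) keeps full precision throughout.
#'
#' @param effects An `effect_table` from [accumulate_effects()].
#' @param selection A `level_selection` from [select_optimal_levels()].
#' @param rounding `"paper"` or `"full"` (see Details).
#' @return An `omega_prediction`: list with `levels` (data frame of selected
#'   levels, rates as used, dB values), `overall_rate`, `overall_db`,
#'   `combined_db`, `predicted_rate`, `rounding`.
#' @examples
#' plan <- make_plan(dialyzer_factors(), 30)
#' eff <- accumulate_effects(plan, load_fixture("table4"))
#' sel <- select_optimal_levels(eff)
#' predict_combination(eff, sel, rounding = "paper")  # 8.19 dB -> 13.17%
#' @export
predict_combination <- function(effects, selection,
                                rounding = c("paper", "full")) {
  rounding <- match.arg(rounding)
  if (!inherits(effects, "effect_table")) stop("effects must be an effect_table")
  if (!inherits(selection, "level_selection"))
    stop("selection must be a level_selection")
  if (!setequal(selection$factor, unique(effects$factor)))
    stop("selection must cover every factor in the effect table")

  key <- paste(effects$factor, effects$level)
  idx <- match(paste(selection$factor, selection$level), key)
  rates <- effects$rate[idx]
  overall <- attr(effects, "overall_rate")

  rd2 <- function(x) round(x, 2)
  if (rounding == "paper") {
    rates_used <- rd2(rates)
    overall_used <- rd2(overall)
  } else {
    rates_used <- rates
    overall_used <- overall
  }
  if (any(rates_used <= 0 | rates_used >= 1) ||
      overall_used <= 0 || overall_used >= 1)
    stop("a rate is 0 or 1 after rounding; use rounding = 'full' or apply ",
         "continuity_correct() to the counts")

  level_db <- omega_db(rates_used)
  overall_db <- omega_db(overall_used)
  if (rounding == "paper") {
    level_db <- rd2(level_db)
    overall_db <- rd2(overall_db)
  }
  m <- length(level_db)
  combined_db <- sum(level_db) - (m - 1) * overall_db
  if (rounding == "paper") combined_db <- rd2(combined_db)
  predicted <- inverse_omega(combined_db)

  structure(
    list(
      levels = data.frame(factor = selection$factor, level = selection$level,
                          rate = rates_used, db = level_db),
      overall_rate = overall_used, overall_db = overall_db,
      combined_db = combined_db, predicted_rate = predicted,
      rounding = rounding,
      combination = attr(selection, "combination")
    ),
    class = "omega_prediction"
  )
}

#' @export
print.omega_prediction <- function(x, ...) {
  cat(sprintf("Omega prediction for %s (rounding = %s)\n",
              x$combination, x$rounding))
  for (i in seq_len(nrow(x$levels)))
    cat(sprintf("  %s%d: rate %.4g -> %.4g dB\n", x$levels$factor[i],
                x$levels$level[i], x$levels$rate[i], x$levels$db[i]))
  cat(sprintf("  overall: rate %.4g -> %.4g dB\n", x$overall_rate, x$overall_db))
  cat(sprintf("  combined: %.4g dB -> predicted defect rate %.2f%%\n",
              x$combined_db, 100 * x$predicted_rate))
  invisible(x)
}

#' Export an omega prediction as JSON
#'
#' @param x An `omega_prediction`.
#' @param path File path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
omega_prediction_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "omega_prediction"))
  out <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                          dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
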