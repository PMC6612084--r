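#' Per-condition defect-probability profile
#'
#' The outcome model for the run generator: each of the 9 design conditions
#' has a fixed Bernoulli defect probability.  The default profile is the
#' empirical per-condition rate of the reference experiment
#' (7, 6, 10, 10, 16, 9, 11, 12, 5 defective out of 30), so generated data
#' reproduce its marginal structure in expectation.
#'
#' @param probs Numeric vector of 9 probabilities in \[0, 1\].
#' @return An `outcome_profile` object.
#' @export
outcome_profile <- function(probs = c(7, 6, 10, 10, 16, 9, 11, 12, 5) / 30) {
  probs <- as.numeric(probs)
  if (length(probs) != 9L)
    stop("profile must give one probability per design condition (9)")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("defect probabilities must lie in [0, 1]")
  structure(list(probs = probs), class = "outcome_profile")
}

#' Generate run-level outcomes under an experiment plan
#'
#' For each of the 9 design conditions, draws `plan$runs_per_condition`
#' independent Bernoulli outcomes with the condition's profile probability.
#' The random stream is consumed condition by condition in design order,
#' runs in index order, so output is reproducible across platforms for a
#' given seed.
#'
#' @param plan An `experiment_plan`.
#' @param profile An `outcome_profile`.
#' @param seed Integer seed.
#' @return Per-run data frame with columns `run_id`, `condition`, `A`-`D`,
#'   `outcome` ("defective"/"good"), suitable for [accumulate_effects()]
#'   and [encode_records()].
#' @examples
#' plan <- make_plan(dialyzer_factors(), 30)
#' runs <- generate_runs(plan, outcome_profile(), seed = 1)
#' nrow(runs)  # 270
#' @export
generate_runs <- function(plan, profile = outcome_profile(), seed = 1L) {
  stopifnot(inherits(plan, "experiment_plan"),
            inherits(profile, "outcome_profile"))
  design <- unclass(plan$design)
  m <- plan$runs_per_condition
  set.seed(seed)
  out <- vector("list", nrow(design))
  for (cc in seq_len(nrow(design))) {
    defect <- stats::rbinom(m, 1L, profile$probs[cc]) == 1L
    lev <- unname(design[cc, ])
    out[[cc]] <- data.frame(
      condition = cc,
      A = lev[1L], B = lev[2L], C = lev[3L], D = lev[4L],
      outcome = ifelse(defect, "defective", "good"),
      stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, out)
  runs <- cbind(run_id = seq_len(nrow(runs)), runs)
  runs
}

#' The combination a profile actually favours
#'
#' Maps per-condition probabilities through the design to per-factor-level
#' expected defect rates and returns the smaller-the-better argmin
#' combination — the generator's ground truth against which recovery of the
#' analysis pipeline is judged.
#'
#' @param profile An `outcome_profile`.
#' @param plan An `experiment_plan` (level structure only; run counts are
#'   irrelevant).
#' @return Combination label such as `"A1B3C2D2"`.
#' @export
profile_best_combination <- function(profile,
                                     plan = make_plan(dialyzer_factors(), 30L)) {
  stopifnot(inherits(profile, "outcome_profile"))
  design <- unclass(plan$design)
  label <- character(ncol(design))
  for (j in seq_len(ncol(design))) {
    mean_rate <- vapply(1:3, function(l) mean(profile$probs[design[, j] == l]),
                        numeric(1))
    label[j] <- paste0(colnames(design)[j], which.min(mean_rate))
  }
  paste0(label, collapse = "")
}

#' Categorical covariate profile for patient generation
#'
#' Sampling weights for the health-status and physiological covariates of a
#' simulated dialysis cohort.  `mode = "counts"` uses the published cohort
#' counts as weights; `mode = "percent"` uses the published percentages; and
#' `mode = "improved"` replaces the five physiological "normal" shares (BMI
#' 40.3%, serum calcium 59.0%, hematocrit 32.2%, ferritin 76.4%, transferrin
#' saturation 79.0%) with the post-optimisation values, splitting the
#' residual mass across the remaining bands in proportion to the original
#' percentages.  Note the published physiological percentages are not
#' consistent with the published counts; the two modes therefore differ and
#' counts are treated as authoritative for the original cohort.
#'
#' @param mode `"counts"`, `"percent"` or `"improved"`.
#' @return A `covariate_profile`: named list of named weight vectors.
#' @export
covariate_profile <- function(mode = c("counts", "percent", "improved")) {
  mode <- match.arg(mode)
  t5 <- load_fixture("table5")
  t6 <- load_fixture("table6")
  tab <- rbind(t5, t6)
  weights <- lapply(split(tab, tab$characteristic), function(d) {
    w <- if (mode == "counts") d$count else d$percentage
    stats::setNames(as.numeric(w), d$category)
  })
  if (mode == "improved") {
    improved_normal <- c(bmi = 40.3, serum_calcium = 59.0, hematocrit = 32.2,
                         ferritin = 76.4, transferrin_saturation = 79.0)
    for (ch in names(improved_normal)) {
      w <- weights[[ch]]
      others <- setdiff(names(w), "normal")
      residual <- 100 - improved_normal[[ch]]
      w[others] <- residual * w[others] / sum(w[others])
      w["normal"] <- improved_normal[[ch]]
      weights[[ch]] <- w
    }
  }
  structure(list(weights = weights, mode = mode), class = "covariate_profile")
}

#' Generate a synthetic patient covariate table
#'
#' Each covariate is sampled independently from its categorical weight
#' distribution; no covariate-outcome or covariate-covariate dependence is
#' modelled (the covariates are descriptive in the workflow this package
#' reproduces and never enter the defect model).
#'
#' @param n Number of patients (>= 1).
#' @param profile A `covariate_profile`.
#' @param seed Integer seed.
#' @return Data frame with `patient_id` and one column per covariate.
#' @export
generate_patients <- function(n, profile = covariate_profile(), seed = 1L) {
  stopifnot(inherits(profile, "covariate_profile"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  set.seed(seed)
  cols <- lapply(profile$weights, function(w) {
    if (length(w) == 0L) stop("empty category set in covariate profile")
    sample(names(w), n, replace = TRUE, prob = w / sum(w))
  })
  cbind(data.frame(patient_id = seq_len(n)),
        as.data.frame(cols, stringsAsFactors = FALSE))
}
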