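#' Define an experimental factor with three ordered levels
#'
#' A factor in a 3-level Taguchi design: a short name (a column letter of the
#' orthogonal array), a human-readable label, and exactly three ordered level
#' descriptors.  Levels may be numeric (with a unit) or categorical.
#'
#' @param name Short identifier, e.g. `"A"`.
#' @param label Human-readable description, e.g. `"Amount of anticoagulation"`.
#' @param values Vector of exactly 3 distinct level values (numeric or
#'   character), in level order 1..3.
#' @param unit Unit string for numeric factors; `NA` for categorical factors.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("A", "Amount of anticoagulation", c(500, 1000, 1500), "units")
#' @export
factor_spec <- function(name, label, values, unit = NA_character_) {
  if (length(values) != 3L)
    stop("a factor must have exactly 3 levels, got ", length(values))
  if (anyDuplicated(values))
    stop("level values must be distinct within factor '", name, "'")
  structure(
    list(name = as.character(name), label = as.character(label),
         values = values, unit = unit),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  unit <- if (is.na(x$unit) || !nzchar(x$unit)) "" else paste0(" ", x$unit)
  cat(sprintf("Factor %s (%s): levels %s\n", x$name, x$label,
              paste0(x$values, unit, collapse = " / ")))
  invisible(x)
}

#' The four dialyzer process factors
#'
#' The factors studied in the hemodialysis solidification experiment:
#' anticoagulation dose (500/1000/1500 units), blood-flow velocity
#' (200/250/300 ml/min), dehydration volume (1.5/2.5/3.5 kg) and vascular
#' access type (artificial vessel / autologous vessel / temporary duct).
#'
#' @return A list of four `factor_spec` objects named A-D.
#' @export
dialyzer_factors <- function() {
  list(
    A = factor_spec("A", "Amount of anticoagulation", c(500, 1000, 1500), "units"),
    B = factor_spec("B", "Velocity of blood flow", c(200, 250, 300), "ml/min"),
    C = factor_spec("C", "Dehydration volume", c(1.5, 2.5, 3.5), "kg"),
    D = factor_spec("D", "Vascular access type",
                    c("artificial blood vessel", "autologous blood vessel",
                      "temporary duct"))
  )
}

#' Construct the canonical L9(3^4) orthogonal array
#'
#' Nine runs over four 3-level factors; every pair of columns contains each
#' of the nine ordered level pairs exactly once, so each factor's level
#' effects are estimated from a balanced third of the runs.  The array is
#' hard-coded in its canonical form: the design is the standard Taguchi L9,
#' not the output of a general orthogonal-array constructor.
#'
#' @return A 9 x 4 integer matrix of level indices in 1..3 with columns
#'   `A`-`D` and class `c("l9_design", "matrix")`.
#' @examples
#' build_l9()
#' @export
build_l9 <- function() {
  cells <- matrix(
    c(1L, 1L, 1L, 1L,
      1L, 2L, 2L, 2L,
      1L, 3L, 3L, 3L,
      2L, 1L, 2L, 3L,
      2L, 2L, 3L, 1L,
      2L, 3L, 1L, 2L,
      3L, 1L, 3L, 2L,
      3L, 2L, 1L, 3L,
      3L, 3L, 2L, 1L),
    nrow = 9L, ncol = 4L, byrow = TRUE,
    dimnames = list(NULL, c("A", "B", "C", "D"))
  )
  class(cells) <- c("l9_design", class(cells))
  cells
}

#' Check pairwise orthogonality of a 3-level design matrix
#'
#' A design is orthogonal here when every column contains each level the same
#' number of times and, for every pair of columns, each ordered level pair
#' occurs equally often (exactly once for L9).  The check is a brute-force
#' census of level pairs over all rows.
#'
#' @param design Integer matrix of level indices in 1..3 (runs x factors).
#' @return A list with elements `pass` (logical), `violations` (data frame of
#'   offending column pairs, empty when `pass`), of class `orthogonality_report`.
#' @examples
#' validate_orthogonality(build_l9())$pass
#' @export
validate_orthogonality <- function(design) {
  design <- unclass(design)
  if (!is.matrix(design) || nrow(design) < 1L || ncol(design) < 2L)
    stop("design must be a matrix with at least 1 run and 2 columns")
  if (!all(design %in% 1:3))
    stop("design cells must be level indices in 1..3")
  n_runs <- nrow(design)
  n_fac <- ncol(design)
  if (n_runs %% 9L != 0L) {
    # level-pair balance is impossible unless 9 | n_runs
    expected <- NA_real_
  } else {
    expected <- n_runs / 9
  }
  cols <- colnames(design)
  if (is.null(cols)) cols <- paste0("col", seq_len(n_fac))
  viol <- list()
  for (i in seq_len(n_fac - 1L)) {
    for (j in seq((i + 1L), n_fac)) {
      tab <- table(factor(design[, i], levels = 1:3),
                   factor(design[, j], levels = 1:3))
      ok <- !is.na(expected) && all(tab == expected)
      if (!ok) {
        viol[[length(viol) + 1L]] <- data.frame(
          col_i = cols[i], col_j = cols[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(col_i = character(), col_j = character(),
               stringsAsFactors = FALSE)
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "orthogonality_report")
}

#' @export
print.orthogonality_report <- function(x, ...) {
  if (x$pass) cat("Design is pairwise orthogonal.\n")
  else cat("Design is NOT orthogonal; violating column pairs:\n",
           paste(x$violations$col_i, x$violations$col_j,
                 sep = "-", collapse = ", "), "\n")
  invisible(x)
}

#' Bind factors to the L9 array to form an experiment plan
#'
#' Binds factor i to array column i (A to column 1, ..., D to column 4) and
#' records the number of repeated runs per design row (30 in the dialyzer
#' experiment, giving 9 x 30 = 270 planned runs).
#'
#' @param factors List of exactly 4 `factor_spec` objects.
#' @param runs_per_condition Number of repeated runs at each of the 9
#'   conditions; must be >= 1.
#' @return An object of class `experiment_plan` with elements `design`,
#'   `factors`, `runs_per_condition`, `n_runs` (total planned runs).
#' @examples
#' plan <- make_plan(dialyzer_factors(), runs_per_condition = 30)
#' plan$n_runs  # 270
#' @export
make_plan <- function(factors, runs_per_condition = 30L) {
  if (length(factors) != 4L)
    stop("an L9(3^4) plan requires exactly 4 factors, got ", length(factors))
  ok <- vapply(factors, inherits, logical(1), what = "factor_spec")
  if (!all(ok))
    stop("all factors must be factor_spec objects")
  runs_per_condition <- as.integer(runs_per_condition)
  if (is.na(runs_per_condition) || runs_per_condition < 1L)
    stop("runs_per_condition must be >= 1")
  design <- build_l9()
  colnames(design) <- unname(vapply(factors, `[[`, character(1), "name"))
  structure(
    list(design = design, factors = factors,
         runs_per_condition = runs_per_condition,
         n_runs = nrow(design) * runs_per_condition),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("L9(3^4) experiment plan: 9 conditions x %d runs = %d planned runs\n",
              x$runs_per_condition, x$n_runs))
  for (f in x$factors) print(f)
  invisible(x)
}
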