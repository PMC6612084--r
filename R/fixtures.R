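#' Load a packaged reference table
#'
#' The reference experiment's printed tables ship with the package as
#' plain-text fixtures:
#' \describe{
#'   \item{`table2`}{the four factors and their levels, as a list of
#'     `factor_spec` objects (see [dialyzer_factors()]).}
#'   \item{`table3`}{the L9(3^4) orthogonal array, as an integer matrix.}
#'   \item{`table4`}{per-condition defective/good/sample counts of the 270
#'     experimental runs (86 defective in total).}
#'   \item{`table5`}{cohort health-status covariate counts (n = 270).}
#'   \item{`table6`}{cohort physiological covariate counts (n = 270).}
#'   \item{`table10`}{the confirmation experiment at the selected
#'     combination: 35 defective of 270.}
#' }
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"table10"`.
#' @return The typed object described above.
#' @examples
#' load_fixture("table4")
#' @export
load_fixture <- function(name) {
  files <- c(table2 = "table2_factors.csv", table3 = "table3_l9.csv",
             table4 = "table4_results.csv", table5 = "table5_health.csv",
             table6 = "table6_physiology.csv",
             table10 = "table10_confirmation.csv")
  if (length(name) != 1L || !name %in% names(files))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "taguchiomega",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    table2 = {
      sp <- split(raw, raw$factor)
      out <- lapply(sp, function(d) {
        d <- d[order(d$level), ]
        vals <- utils::type.convert(d$value, as.is = TRUE)
        unit <- d$unit[1L]
        if (is.na(unit) || !nzchar(unit)) unit <- NA_character_
        factor_spec(d$factor[1L], d$label[1L], vals, unit)
      })
      out[c("A", "B", "C", "D")]
    },
    table3 = {
      m <- as.matrix(raw[order(raw$run), c("A", "B", "C", "D")])
      storage.mode(m) <- "integer"
      rownames(m) <- NULL
      m
    },
    table4 = raw[order(raw$condition), , drop = FALSE],
    table5 = raw,
    table6 = raw,
    table10 = raw
  )
}
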