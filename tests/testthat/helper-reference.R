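# Shared shortcuts for the reference experiment (9 conditions x 30 runs).

ref_plan <- function() make_plan(dialyzer_factors(), runs_per_condition = 30L)

ref_effects <- function() accumulate_effects(ref_plan(), load_fixture("table4"))

# brute-force per-run tally: expand counts to runs and count defectives per
# factor level without going through accumulate_effects' grouping
tally_oracle <- function(design, defective, sample) {
  out <- list()
  for (f in colnames(design)) {
    for (l in 1:3) {
      idx <- design[, f] == l
      out[[paste0(f, l)]] <- c(defective = sum(defective[idx]),
                               total = sum(sample[idx]))
    }
  }
  out
}
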