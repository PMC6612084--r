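#!/usr/bin/env Rscript
# Stage 1: set up the L9(3^4) experiment plan for the dialyzer
# solidification study and check the array's orthogonality.

library(taguchiomega)

plan <- make_plan(dialyzer_factors(), runs_per_condition = 30L)
print(plan)

check <- validate_orthogonality(plan$design)
print(check)
stopifnot(check$pass)

dir.create("results", showWarnings = FALSE)
design_df <- data.frame(run = 1:9, unclass(plan$design))
write.csv(design_df, "results/design_l9.csv", row.names = FALSE)
cat("Wrote results/design_l9.csv: 9 conditions x 30 runs = 270 planned runs\n")
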