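#!/usr/bin/env Rscript
# Stage 2: accumulate defective counts per factor level from the packaged
# 270-run experiment and select the smaller-the-better level combination.

library(taguchiomega)

plan <- make_plan(dialyzer_factors(), runs_per_condition = 30L)
results <- load_fixture("table4")
effects <- accumulate_effects(plan, results)
print(effects)

selection <- select_optimal_levels(effects)
print(selection)

dir.create("results", showWarnings = FALSE)
eff_df <- data.frame(factor = effects$factor, level = effects$level,
                     defective = effects$defective, total = effects$total,
                     rate = effects$rate)
write.csv(eff_df, "results/effect_table.csv", row.names = FALSE)
write.csv(data.frame(factor = selection$factor, level = selection$level,
                     rate = selection$rate,
                     combination = attr(selection, "combination")),
          "results/selection.csv", row.names = FALSE)
cat(sprintf("Baseline defect rate: %d/%d = %.0f%%\n",
            attr(effects, "total_defective"), attr(effects, "total_sample"),
            100 * attr(effects, "overall_rate")))
cat("Selected combination:", attr(selection, "combination"), "\n")
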