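#!/usr/bin/env Rscript
# Stage 3: predict the defect rate of the selected combination through the
# omega (logit-decibel) transformation, in both rounding modes.

library(taguchiomega)

plan <- make_plan(dialyzer_factors(), runs_per_condition = 30L)
effects <- accumulate_effects(plan, load_fixture("table4"))
selection <- select_optimal_levels(effects)

pred_paper <- predict_combination(effects, selection, rounding = "paper")
pred_full <- predict_combination(effects, selection, rounding = "full")
print(pred_paper)
print(pred_full)

dir.create("results", showWarnings = FALSE)
omega_prediction_json(pred_paper, "results/omega_prediction_paper.json")
omega_prediction_json(pred_full, "results/omega_prediction_full.json")
cat("Hand-calculation (2-dp) chain:",
    sprintf("%.2f dB -> %.2f%% predicted defect rate\n",
            pred_paper$combined_db, 100 * pred_paper$predicted_rate))
cat("Full-precision chain:        ",
    sprintf("%.4f dB -> %.2f%% predicted defect rate\n",
            pred_full$combined_db, 100 * pred_full$predicted_rate))
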