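#!/usr/bin/env Rscript
# Stage 5: confirmation arithmetic — the follow-up experiment at the
# selected combination A1B3C2D2, compared with the omega prediction and
# the baseline.

library(taguchiomega)

rep <- run_pipeline(results = load_fixture("table4"),
                    confirmation = load_fixture("table10"),
                    run_bpn = FALSE)
print(rep)

dir.create("results", showWarnings = FALSE)
conf <- rep$confirmation
write.csv(data.frame(
  combination = attr(rep$selection, "combination"),
  defective = conf$defective, total = conf$total,
  percent = conf$percent,
  predicted_percent = round(100 * rep$prediction_paper$predicted_rate, 2),
  baseline_percent = round(100 * rep$baseline_rate)),
  "results/confirmation.csv", row.names = FALSE)
cat(sprintf("Confirmed %.1f%% vs predicted %.2f%% vs baseline %.0f%%\n",
            conf$percent, 100 * rep$prediction_paper$predicted_rate,
            100 * rep$baseline_rate))
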