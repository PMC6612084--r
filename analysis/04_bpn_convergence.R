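#!/usr/bin/env Rscript
# Stage 4: train the 4-5-1 back-propagation network on the 270 run-level
# records (proportion targets) as a stability check, and export the
# per-epoch error curves.

library(taguchiomega)

seed <- 1L
runs <- conditions_to_runs(load_fixture("table4"))
enc <- encode_records(runs, target = "proportion")
sets <- split_data(enc, seed = seed)
cat(sprintf("Split: %d train / %d validation / %d test\n",
            length(sets$train$y), length(sets$validation$y),
            length(sets$test$y)))

cfg <- bpn_config(seed = seed)  # lr 0.1, momentum 0.1, 500 cycles, 5 hidden
fit <- bpn_train(cfg, sets$train, sets$validation, sets$test)
print(fit)

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(fit$report), "results/convergence.csv",
          row.names = FALSE)
bpn_to_json(fit$network, "results/bpn_weights.json")

net <- fit$network
dev <- gradient_check(net, sets$train$x[1, ], sets$train$y[1])
cat(sprintf("Gradient check (analytic vs central differences): %.2e\n", dev))
cat(sprintf("Final training MSE: %.6f\n", attr(fit$report, "final_mse")))
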