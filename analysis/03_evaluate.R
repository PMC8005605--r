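#!/usr/bin/env Rscript

# Step 3 — model evaluation.
#
# Characterizes parameter uncertainty by sampling importance resampling
# (4 iterations, M = 5000/2000/2000/1000 samples, m = 1000/1000/1000/500
# resamples) and validates the model by normalized prediction distribution
# errors (1000 simulated replicates of the trial design).

library(cefapk)

seed <- 20210330
ds <- read_dataset("results/synthetic_trial.csv")
model <- read_model_yaml("results/final_model.yaml")

fit <- fit_foce(ds, model)
sir <- run_sir(ds, fit, sir_config(), seed = seed)
write.csv(sir$summary, "results/sir_summary.csv", row.names = FALSE)
print(sir)

np <- compute_npde(ds, model, K = 1000, seed = seed + 1)
write.csv(np$table, "results/npde_observations.csv", row.names = FALSE)
yaml::write_yaml(list(mean = np$mean, variance = np$variance,
                      p_mean = np$p_mean, p_wilcoxon = np$p_wilcoxon,
                      p_variance = np$p_variance, p_normal = np$p_normal,
                      p_global = np$p_global, K = np$K, seed = np$seed),
                 "results/npde_summary.yaml")
print(np)
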