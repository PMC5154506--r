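#!/usr/bin/env Rscript
# Step 2: score the six multisensory models against the response table.
#
# Estimates unimodal profiles and matching-rate causal posteriors, predicts
# discretized response counts for each model, and regresses observed on
# predicted counts (OLS) for the pooled, per-modality and per-subject scopes.
# Writes the long fit table and the wide goodness-of-fit analogue.

suppressMessages(library(avdistci))

dat <- read_response_table("results/responses.csv")
fits <- compare_models(dat)

readr::write_csv(fits, "results/model_fits.csv")
readr::write_csv(format_fit_table(fits), "results/fit_table.csv")
write_manifest("results/fit_manifest.json",
               step = "fit", data = "results/responses.csv",
               match_rule = "bin", variance_floor = 1e-4)

cat("goodness of fit (r^2) of each model by scope:\n")
print(as.data.frame(format_fit_table(fits)), digits = 3)
all_scope <- fits[fits$scope == "All", ]
cat("\nbest model (All):", all_scope$model[which.max(all_scope$r_squared)],
    "\n")
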