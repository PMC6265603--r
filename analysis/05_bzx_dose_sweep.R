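#!/usr/bin/env Rscript
# BZX dose escalation on the hyperglycemic cancer cell: 10, 20 and 30
# tokens. Higher doses leave more free inhibitor at the end of the run,
# so terminal OGT activity decreases strictly with dose.

suppressPackageStartupMessages(library(ogtpn))
dir.create("results", showWarnings = FALSE)

s <- sim_settings()
doses <- intervention_defaults()$bzx_doses
sw <- dose_sweep("cancer_hyperglycemia", list(intervention("bzx")),
                 "bzx", doses, "ogt", s)
write.csv(sw, "results/bzx_dose_sweep.csv", row.names = FALSE)
print(sw, row.names = FALSE, digits = 4)
stopifnot(all(diff(sw$value) < 0))
cat("terminal OGT activity decreases strictly with BZX dose\n")
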