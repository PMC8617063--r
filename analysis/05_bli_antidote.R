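#!/usr/bin/env Rscript
# Antidote binding kinetics: global 1:1 fit and steady-state isotherm for
# the antibody dilution series. Run analysis/01_simulate_assays.R first.

suppressPackageStartupMessages(library(dtikin))
dir.create("results", showWarnings = FALSE)

raw <- read_assay_csv("results/sim/sensorgrams.csv", "sensorgram")
panel <- lapply(split(as.data.frame(raw), raw$conc_nM), function(d)
  structure(d[order(d$time_s), ], class = c("sensorgram", "data.frame")))

kin <- fit_1to1(panel)
cat(sprintf("1:1 global fit: kon = %.2e /M/s, koff = %.2e /s, KD = %.2f nM, Rmax = %.2f nm\n",
            kin$kon, kin$koff, kin$KD_kinetic_nM, kin$Rmax_nm))

reqs <- vapply(panel, function(s) extract_req(s)$Req_nm, numeric(1))
conc <- vapply(panel, function(s) s$conc_nM[1], numeric(1))
ss <- fit_steady_state(conc, reqs)
cat(sprintf("steady-state isotherm: KD = %.2f nM, Rmax = %.2f nm\n",
            ss$KD_eq_nM, ss$Rmax_nm))
cat(sprintf("dissociation half-life: %.0f s\n", log(2) / kin$koff))

write.csv(data.frame(route = c("kinetic", "steady_state"),
                     KD_nM = c(kin$KD_kinetic_nM, ss$KD_eq_nM),
                     Rmax_nm = c(kin$Rmax_nm, ss$Rmax_nm)),
          "results/bli_affinity.csv", row.names = FALSE)
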