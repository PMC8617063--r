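#!/usr/bin/env Rscript
# Generate every synthetic assay read-out the downstream analyses consume,
# with known ground truth, and write them as CSVs under results/sim/.

suppressPackageStartupMessages(library(dtikin))
outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260921L

# -- chromogenic progress curves: thrombin 0.8 nM, Ki' 50 pM titration ------
pc <- gen_progress_curves(sim_spec("progress_curve",
  truth = list(v0_AU_per_min = 0.02, Et_nM = 0.8, Ki_prime_pM = 50),
  design = list(It_nM = c(0, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1.0, 1.2, 1.6),
                S_uM = 100, duration_s = 600, dt_s = 5),
  noise_sd = 0.002, seed = seed))
write_assay_csv(pc, file.path(outdir, "progress_curves.csv"))

# -- substrate series for the competitive-Ki regression (Ki 4 pM, Km 100 uM)
for (S in c(100, 150, 200, 300, 400)) {
  pcs <- gen_progress_curves(sim_spec("progress_curve",
    truth = list(v0_AU_per_min = 0.02, Et_nM = 0.8, Ki_pM = 4, Km_uM = 100,
                 mode = "competitive"),
    design = list(It_nM = c(0, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1.0, 1.2, 1.6),
                  S_uM = S, duration_s = 600, dt_s = 5),
    noise_sd = 0.002, seed = seed + S))
  write_assay_csv(pcs, file.path(outdir, sprintf("progress_S%03d.csv", S)))
}

# -- clot waveform and thrombogram traces -----------------------------------
cwa <- gen_cwa_trace(sim_spec("cwa_trace",
  truth = list(baseline_pct = 100, drop_pct = 55, midpoint_s = 45,
               scale_s = 3),
  design = list(duration_s = 120, dt_s = 0.1), noise_sd = 0.2, seed = seed))
write_assay_csv(cwa, file.path(outdir, "cwa_trace.csv"))

tgt <- gen_thrombogram(sim_spec("thrombogram",
  truth = list(LT_min = 3, TTpeak_min = 6, peak_nM = 250, shape = 3),
  design = list(duration_min = 60, dt_min = 0.1), noise_sd = 2, seed = seed))
write_assay_csv(tgt, file.path(outdir, "thrombogram.csv"))

# -- rodent dose-response (occlusion + tail bleeding, TI truth 3.8) ---------
occ <- gen_invivo_doseresponse(sim_spec("invivo_doseresponse",
  truth = list(baseline_min = 8.82, cap_min = 60, rt50 = 2, hill = 2,
               sigma_log = 0.2),
  design = list(doses = c(1, 1.4, 2, 3, 5), n_per_dose = 6), seed = seed))
write_assay_csv(occ, file.path(outdir, "occlusion_records.csv"))
bld <- gen_invivo_doseresponse(sim_spec("invivo_doseresponse",
  truth = list(baseline_min = 4.25, cap_min = 60, rt50 = 7.6, hill = 2,
               sigma_log = 0.2),
  design = list(doses = c(2, 4, 7.6, 15), n_per_dose = 7), seed = seed + 1L))
write_assay_csv(bld, file.path(outdir, "tail_bleed_records.csv"))

# -- BLI dilution series (KD truth 1.25 nM) ---------------------------------
panel <- gen_sensorgrams(sim_spec("sensorgram",
  truth = list(kon = 8e5, koff = 1e-3, Rmax_nm = 2),
  design = list(conc_nM = c(20, 6.7, 2.2, 0.74, 0.25, 0.082, 0.027),
                t_assoc_s = 2400, t_dissoc_s = 3600, dt_s = 5),
  noise_sd = 0.005, seed = seed))
write_assay_csv(do.call(rbind, lapply(panel, as.data.frame)),
                file.path(outdir, "sensorgrams.csv"))

cat("simulated assay tables written to", outdir, "\n")
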