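#!/usr/bin/env Rscript
# Generate one example synthetic experiment and write its raw artefacts:
# the event schedule (TSV), the multi-electrode EEG record (delimited text
# matrix + JSON metadata), and an MR-ARFI phase-image pair (NIfTI + JSON
# sidecar). Downstream drivers re-simulate internally; these files document
# the exchange formats.

library(tusvep)
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# one LGN-sonication experiment, shortened blocks (4 sections = 4 min per
# sonication block) so the files stay small
cfg <- sim_config(seed = 101, suppression = c(LGN1 = 0.5))
events <- make_event_table(c("Baseline", "LGN1"), n_sections = 4,
                           baseline_min = 2)
raw <- simulate_eeg(events, cfg)

write_event_table(events, file.path(out, "events.tsv"))
write_eeg_matrix(raw, file.path(out, "eeg.tsv"))

enc <- encoding_params(tau_s = 3e-3)         # G = 0.04 T/m
field <- gaussian_focus(dim = c(25, 25, 25), spacing_mm = 1,
                        center_mm = c(12, 12, 12), fwhm_mm = 4, peak = 2)
pair <- simulate_arfi_pair(field, enc, noise_sd_rad = 0.005, seed = 102)
write_arfi_pair(pair, file.path(out, "arfi"))

cat(sprintf("events: %d rows (%d light-only)\n",
            nrow(events), sum(events$condition == "light")))
cat(sprintf("EEG: %d channels x %d samples @ %g Hz\n",
            nrow(raw$data), ncol(raw$data), raw$fs_hz))
cat(sprintf("ARFI pair written with peak displacement %.1f um\n",
            field$peak))
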