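#!/usr/bin/env Rscript
# Sonication dose arithmetic for the study protocol and a bioheat estimate
# of the temperature rise from a focal heat source. The solver is a
# free-field simplification (no skull attenuation), validated against
# closed forms; it is not a transcranial prediction.

library(tusvep)
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

proto <- sonication_protocol()
dc <- duty_cycles(proto)
isppa <- c(19.3, 46.6, 63.8)
dose <- data.frame(
  i_sppa_W_cm2 = isppa,
  i_spta_W_cm2 = vapply(isppa, ispta_from_isppa, numeric(1), p = proto))
write.csv(dose, file.path(out, "dose_table.csv"), row.names = FALSE)
cat(sprintf("duty cycles: within-train %.0f%%, train %.0f%%, total %.0f%%\n",
            100 * dc$within_train, 100 * dc$train, 100 * dc$total))
print(dose)
cat(sprintf("plane-wave intensity at 1.0 MPa: %.1f W/cm2 (nominal mapping)\n",
            intensity_from_pressure(1.0)))

# focal heat source: duty-averaged Q = 2 alpha I over a 4 mm FWHM focus
focus <- gaussian_focus(c(31, 31, 31), 1, c(15, 15, 15), fwhm_mm = 4,
                        peak = 46.6)
Q <- heat_source_from_intensity(focus$field, alpha_Np_m = 4,
                                protocol = proto)
bp <- bioheat_params(Q_W_m3 = Q, dim = c(31, 31, 31))
res <- simulate_bioheat(bp, duration_s = 300)
cat(sprintf("max temperature rise after 300 s sonication: %.2f K (dt = %.3g s)\n",
            res$max_dT, res$dt_s))
write.csv(data.frame(duration_s = 300, max_dT_K = res$max_dT,
                     dt_s = res$dt_s, n_steps = res$n_steps),
          file.path(out, "bioheat_summary.csv"), row.names = FALSE)
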