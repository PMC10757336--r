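#!/usr/bin/env Rscript
# Pre-culture validation arithmetic: comparing model predictions with the
# bench measurements for the fabricated design.
#
# Finds: the dye-front timestamps give a measured 2.36 mm/s, inside the
# predicted 2-3 mm/s band for that region; the 1D layered model of the
# 10-mm validation cell predicts a uniform 0.095 V/m medium field; the
# measured 24.3 uA versus the predicted 32.1 uA terminal current is a 24%
# relative difference, and back-calculating the field from the measured
# current gives 0.072 V/m; accounting for the 21.89 kOhm measurement
# resistor would lower the prediction to 31.8 uA and 0.094 V/m.

library(perfustim)
dir.create("results", showWarnings = FALSE)

rows <- list()

# perfusion: dye-front velocity from the recorded timestamps
rec <- data.frame(time = c(13.042, 16.005), position = c(0, 7e-3))
v_meas <- dye_front_velocity(rec)
cat(sprintf("dye-front velocity: %.3g m/s (predicted band 2-3 mm/s)\n", v_meas))
rows$dye <- data.frame(quantity = "dye front velocity (m/s)",
                       predicted = 2.5e-3, measured = v_meas,
                       rel_diff = abs(2.5e-3 - v_meas) / 2.5e-3)

# field: 1D layered prediction for the validation cell
lay <- list(list(thickness = 175e-6, material = "PET"),
            list(thickness = 10e-3, material = "medium"),
            list(thickness = 175e-6, material = "PET"))
o <- layered_1d_oracle(lay, V_amp = 5, f = 60e3)
cat(sprintf("validation-cell medium field: %.4g V/m (uniform)\n", o$E_mag[2]))

# current: reported 3D prediction vs bench measurement
I_pred <- 3.21e-5
I_meas <- 2.43e-5
vr <- compare_prediction(I_pred, I_meas, "terminal current (A)")
print(vr)
rows$current <- data.frame(quantity = vr$quantity, predicted = vr$predicted,
                           measured = vr$measured, rel_diff = vr$rel_diff)

# current-to-field back-calculation and series-resistor correction
E_back <- field_from_measured_current(o$E_mag[2], I_pred, I_meas)
sr <- apply_series_resistor(5, I_pred, 21.89e3)
cat(sprintf("field at measured current: %.3g V/m\n", E_back))
cat(sprintf("with the 21.89 kOhm resistor: I = %.3g A, field = %.3g V/m\n",
            sr$I, o$E_mag[2] * sr$scale))
rows$resistor <- data.frame(
  quantity = "terminal current with series resistor (A)",
  predicted = sr$I, measured = I_meas,
  rel_diff = abs(sr$I - I_meas) / sr$I)

# estimator behaviour on synthetic recordings (two-point vs least squares)
err2 <- errls <- numeric(100)
for (s in 1:100) {
  r <- synthetic_dye_recording(v_meas, 7e-3, frame_rate = 30,
                               noise_sd = 2e-4, seed = s)
  err2[s] <- dye_front_velocity(r) - v_meas
  errls[s] <- dye_front_velocity(r, "least_squares") - v_meas
}
cat(sprintf("estimator RMS error over 100 synthetic recordings: two-point %.3g, least-squares %.3g m/s\n",
            sqrt(mean(err2^2)), sqrt(mean(errls^2))))

tab <- do.call(rbind, rows)
write.csv(tab, "results/06_validation.csv", row.names = FALSE)
cat("wrote results/06_validation.csv\n")
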