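#!/usr/bin/env Rscript
# Synthetic dosimeter stage standing in for the physical measurements:
# dual-radius multi-angle point readings with 3 per cent multiplicative
# noise averaged over three repeats, a dose-response linearity fit over the
# 3-120 Gy design range, and the measurement-versus-simulation agreement
# summary.
#
# Finding: the noise model is unbiased (mean reading/simulation ratio ~ 1,
# ~95 per cent of points within 2 combined sigma), the linearity fit
# recovers R^2 > 0.999 at 1 per cent reading noise, and water readings
# compared against a bone simulation diverge with depth, as the radial dose
# functions do.

library(irbrachy)
dir.create("results", showWarnings = FALSE)

src <- source_spec()
tw <- run_simulation(src, phantom_preset("water"), 1e6, seed = 21)
tbn <- run_simulation(src, phantom_preset("bone"), 1e6, seed = 22)

pts <- default_measurement_points(radii = c(3, 5))
ms <- generate_readings(tw, pts, noise_cv = 0.03, n_repeats = 3, seed = 100)
readings <- cbind(pts[rep(seq_len(nrow(pts)), 3), ],
                  repeat_index = rep(1:3, each = nrow(pts)),
                  reading = as.vector(ms$repeats))
write.csv(readings, "results/synthetic_readings.csv", row.names = FALSE)

rep_w <- agreement_report(ms, tw)
write.csv(rep_w$per_point, "results/agreement_water.csv", row.names = FALSE)
print(rep_w)

# cross-media comparison: water "measurements" against the bone simulation
ms2 <- generate_readings(tw, data.frame(r_cm = c(1, 5, 10), theta_deg = 90),
                         noise_cv = 0, seed = 101)
rep_x <- agreement_report(ms2, tbn)
write.csv(rep_x$per_point, "results/agreement_water_vs_bone.csv",
          row.names = FALSE)
cat("water/bone deviation grows with depth:\n")
print(rep_x$per_point[, c("r_cm", "ratio")])

# dose-response linearity over the dosimeter design range
doses <- c(3, 15, 30, 60, 120)
set.seed(7)
fit <- linearity_fit(doses, doses * exp(rnorm(5, 0, 0.01)))
cat(sprintf("linearity: slope %.4f, intercept %.4f, R^2 %.5f\n",
            fit$slope, fit$intercept, fit$r_squared))
write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                     r_squared = fit$r_squared),
          "results/linearity_fit.csv", row.names = FALSE)
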