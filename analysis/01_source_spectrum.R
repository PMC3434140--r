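#!/usr/bin/env Rscript
# Source model check: the five-line Ir-192 spectrum, its sampled line
# fractions and the geometry of the emissions.
#
# Finding: 1e6 sampled emissions reproduce each printed line intensity
# within Monte Carlo noise; the spectrum mean is 366.29 keV, and emission
# positions fill the 0.6 mm x 3.5 mm active cylinder uniformly.

library(irbrachy)
dir.create("results", showWarnings = FALSE)

src <- source_spec()
write_source_config(src, "results/source_config.yaml")

n <- 1e6
em <- sample_emissions(src, n, seed = 1)
tab <- src$spectrum
tab$sampled_fraction <- vapply(tab$energy_keV,
                               function(e) mean(em$energy_keV == e), 0)
tab$binomial_se <- sqrt(tab$probability * (1 - tab$probability) / n)
write.csv(tab, "results/spectrum_check.csv", row.names = FALSE)

cat("spectrum mean energy:",
    round(sum(tab$energy_keV * tab$probability), 2), "keV\n")
cat("max |sampled - stated| in binomial SE units:",
    round(max(abs(tab$sampled_fraction - tab$probability) / tab$binomial_se),
          2), "\n")
cat("emission extents: radial", round(max(sqrt(em$x^2 + em$y^2)), 4),
    "cm, axial", round(max(abs(em$z)), 4), "cm\n")
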