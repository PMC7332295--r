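#!/usr/bin/env Rscript
# Stage 4: figures and efficiency-band summary.
#
# Draws the per-flight Strouhal chart (one point +/- propagated sd per
# flight, grouped by species, over the 0.2-0.4 optimal-propulsion band and
# the 0.12-0.47 literature cruising band) and tabulates how many flights
# fall in each band.

suppressPackageStartupMessages(library(alcidkin))

kin <- read_results_table("results/kinematics.csv")
st_flights <- kin[is.finite(kin$st), ]

fig <- plot_strouhal_by_flight(st_flights)
ggplot2::ggsave("results/fig_strouhal.pdf", fig, width = 9, height = 5)
cat("wrote results/fig_strouhal.pdf\n")

st_flights$band <- classify_st_efficiency(st_flights$st)
tab <- table(st_flights$flight_class, st_flights$band)
print(tab)
write.csv(as.data.frame(tab), "results/st_bands.csv", row.names = FALSE)
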