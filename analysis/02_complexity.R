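#!/usr/bin/env Rscript

# Stage 2: how well does image-derived complexity track the field survey?
#
# Correlates the three MIG indices with every field-based vegetation
# descriptor and with the bat responses, and reports the pairs that cross
# the |r| > .5 redundancy screen. Requires the tables from 01_simulate.R.

suppressPackageStartupMessages(library(greenmig))

mig <- read.csv("results/site_mig.csv")
veg <- read.csv("results/vegetation_descriptors.csv")
resp <- read.csv("results/responses.csv")
d <- Reduce(function(a, b) merge(a, b, by = "site_id"), list(mig, veg, resp))
d$mean_dbh[is.na(d$mean_dbh)] <- 0

mig_cols <- c("mig_all", "mig_sides", "mig_top")
field_cols <- setdiff(names(veg), "site_id")
corr <- t(cor(d[mig_cols], d[c(field_cols, "activity_total", "richness_total")]))
write.csv(round(corr, 3), "results/mig_field_correlations.csv")

cat("Correlation of MIG indices with field descriptors and responses:\n")
print(round(corr, 2))

strongest <- field_cols[which.max(abs(corr[field_cols, "mig_top"]))]
cat(sprintf("\nMIG top is most strongly aligned with %s (r = %.2f),\n",
            strongest, corr[strongest, "mig_top"]))
cat(sprintf("and relates to total activity with r = %.2f (log scale would differ slightly).\n",
            corr["activity_total", "mig_top"]))

screen <- pearson_screen(d[c(field_cols, mig_cols)], threshold = 0.5)
write.csv(screen$flagged, "results/redundancy_screen.csv", row.names = FALSE)
cat(sprintf("\n%d predictor pairs exceed |r| > .5 (results/redundancy_screen.csv).\n",
            nrow(screen$flagged)))
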