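#!/usr/bin/env Rscript
# Stage 7: applicability-domain check.
#
# PCA of the standardized six-descriptor space of the reference set; the
# ellipse covering 99% of the reference compounds on PC1/PC2 bounds the
# chemical space in which predictions are trusted. Sunscreens are ranked by
# their radial ellipse coordinate (1 = boundary); the very bulky, flexible
# triazines (ET, DOBT) are expected to fall furthest out, flagging their
# very high predicted potencies as extrapolations.

library(bcheqsar)

ref <- read_compound_table("results/reference_synthetic.csv")
ad <- fit_ad(ref, coverage = 0.99)
print(ad)

v <- ad_classify(ad, sunscreen_descriptors())
v <- v[order(-v$distance), ]
print(v)

cat(sprintf(
  "\nFurthest from the reference space: %s and %s\n",
  v$id[1], v$id[2]
))

write.csv(as.data.frame(v), "results/ad_verdicts.csv", row.names = FALSE)
pdf("results/ad_plot.pdf", width = 7, height = 6)
plot(ad, query = sunscreen_descriptors(), main = "Applicability domain (PC1/PC2)")
dev.off()
cat("written: results/ad_verdicts.csv, results/ad_plot.pdf\n")
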