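#!/usr/bin/env Rscript
# Stage 1: build the synthetic reference-inhibitor set.
#
# The literature IC50 compilation behind the published models is not public,
# but its descriptor correlation matrix, the fitted equation and its error
# scale are. The generator draws 121 compounds with that structure; every
# later stage runs against this set. Toy SMILES are attached so the
# fingerprint stage has structures to work with.

library(bcheqsar)

seed <- 20
dir.create("results", showWarnings = FALSE)

ref <- synthetic_reference(n = 121, sigma = 0.59, seed = seed,
                           smiles_library = toy_smiles_library())
write_compound_table(ref, "results/reference_synthetic.csv")

cat("Synthetic reference set: n =", nrow(ref), "(seed", seed, ")\n")
cat(sprintf(
  "pIC50 range %.2f .. %.2f (mean %.2f)\n",
  min(ref$pic50), max(ref$pic50), mean(ref$pic50)
))
print(summary(as.data.frame(ref)[, modeling_descriptors()]))
cat("written: results/reference_synthetic.csv\n")
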