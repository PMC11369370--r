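#!/usr/bin/env Rscript
# Derive landmark/slope candidate features from the class mean spectra,
# evaluate them on every labeled measurement, and rank them with ReliefF.
# (Inside the evaluation loop this derivation is redone per training split;
# here it is run once on the full labeled set for inspection.)

suppressPackageStartupMessages(library(drsclassify))

set <- read_spectra_table("results/cohort_spectra.csv")
norm <- snv_set(labeled_subset(set))

spec <- derive_feature_spec(norm)
cat(sprintf("Candidate features: %d landmarks + %d slopes = %d\n",
            nrow(spec$landmarks), nrow(spec$pairs), length(spec$names)))
write_feature_spec(spec, "results/feature_spec_full.txt")

ft <- compute_features(norm, spec)
write.csv(ft, "results/feature_table.csv", row.names = FALSE)

ranked <- relieff_rank(ft[, spec$names], ft$label)
write_ranked_features(ranked, "results/relieff_weights.tsv")
sel <- select_top_k(ranked, min(20, length(spec$names)))
cat("Top-ranked features (first 10 of the selected 20):\n")
for (f in head(ranked$order[ranked$order %in% sel], 10)) {
  cat(sprintf("  %-14s W = %+.4f\n", f, ranked$weights[[f]]))
}
cat("Wrote results/feature_table.csv and results/relieff_weights.tsv\n")
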