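#!/usr/bin/env Rscript
# SNV-normalize the labeled cohort and compute tumor/healthy mean +/- SD
# spectra (the landmark-discovery input and the mean-spectra figure data).

suppressPackageStartupMessages(library(drsclassify))

set <- read_spectra_table("results/cohort_spectra.csv")
norm <- snv_set(labeled_subset(set))
profs <- class_profiles(norm)
write_class_profiles(profs, "results/class_profiles.csv")

for (p in profs) {
  cat(sprintf("%-8s n = %3d, mean SNV range [%.2f, %.2f], max SD %.2f\n",
              p$label, p$n, min(p$mean_spectrum), max(p$mean_spectrum),
              max(p$sd_spectrum)))
}
cat("Wrote results/class_profiles.csv\n")
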