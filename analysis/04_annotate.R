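#!/usr/bin/env Rscript
# Step 4 -- annotate the prioritized candidates.
#
# Suspect-list matching at 5 ppm, CF2 homologous-series detection, spectral
# cosine scoring against the library, diagnostic-fragment counting, RT
# checks against authentic standards, branched-isomer tagging, and
# confidence-level assignment (1 = standard-confirmed ... 5 = mass only).

suppressPackageStartupMessages(library(pfasnta))

sc <- import_scenario("results/scenario")
samples <- read_sample_table("results/collapsed_samples.tsv")
cand <- read_feature_table("results/candidates.tsv", samples)

ann <- annotate_candidates(cand, sc$suspects, sc$spectra,
                           sc$spectral_library)
write.table(ann, "results/annotations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cl <- table(factor(ann$confidence_level, levels = 1:5))
cat("confidence levels:",
    paste(sprintf("CL%s=%d", names(cl), as.integer(cl)), collapse = "  "),
    "\n")
cat(sprintf("homologous series detected: %d (covering %d features)\n",
            length(unique(na.omit(ann$series_id))),
            sum(!is.na(ann$series_id))))
iso <- ann[!is.na(ann$isomer_tag),
           c("feature_id", "suspect_formula", "rt", "isomer_tag")]
if (nrow(iso)) {
  cat("isomer calls (same formula, RT vs authentic standard):\n")
  print(iso, row.names = FALSE)
}
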