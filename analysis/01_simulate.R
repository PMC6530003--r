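#!/usr/bin/env Rscript
# Stage 1 — simulate the study-sized phantom cohort.
#
# Generates 71 benign and 61 malignant lymph-node phantoms with the
# default class profiles (geometry, HU texture, EBUS prevalences and SUV
# distributions parameterized from the published cohort summaries) and
# writes images, masks, records and a manifest under results/cohort/.

library(nodetex)

seed <- 20190522
out <- file.path("results", "cohort")

cohort <- generate_cohort(n_benign = 71, n_malignant = 61, seed = seed)
write_cohort(cohort, out)

rec <- cohort$records
cat("simulated", nrow(rec), "nodes ->", out, "\n")
by_class <- split(rec, rec$label)
for (cl in names(by_class)) {
  r <- by_class[[cl]]
  cat(sprintf(
    "  %-9s n=%2d  short axis %.1f +/- %.1f mm  SUVmax %.1f +/- %.1f  size>=1cm %.1f%%\n",
    cl, nrow(r), mean(r$short_axis_mm), sd(r$short_axis_mm),
    mean(r$suv_max), sd(r$suv_max), 100 * mean(r$size_ge_1cm)))
}
cat("findings: the malignant class draws larger, FDG-avid nodes;\n")
cat("          class-level moments sit near their configured targets\n")
cat("          at this sample size (binomial/SE noise applies per run).\n")
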