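#!/usr/bin/env Rscript
# Generate the synthetic benchmark dataset: a p >> n two-class expression
# matrix with a known ground truth (10 planted genes separated by 2 noise-SD,
# the rest pure noise), written as one combined TSV with a label column so
# the downstream stages exercise the plain-text interface.

suppressPackageStartupMessages(library(selstab))
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(
  n_samples = 60, n_genes = 500, n_classes = 2,
  class_proportions = c(0.5, 0.5), n_relevant = 10, effect_size = 2,
  n_redundant_per_relevant = 0, seed = 20240101)
gen <- generate_dataset(spec)

tab <- data.frame(gen$dataset$expression, check.names = FALSE)
tab$class <- as.character(gen$dataset$labels)
write.table(tab, "results/data.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(gen$truth[c("relevant_ids", "redundant_ids",
                                 "noise_ids")],
                     "results/truth.json", pretty = TRUE)

print(gen$dataset)
cat("planted relevant genes:", gen$truth$relevant_ids, "\n")
cat("wrote results/data.tsv and results/truth.json\n")
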