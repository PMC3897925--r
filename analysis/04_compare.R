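#!/usr/bin/env Rscript
# Compare post-selection classification errors across methods: every method
# was validated on the same bootstrap out-of-bag sets, so per-iteration
# errors are paired and the worse-than-best question is answered by a
# paired one-sided signed-rank test with Holm correction.

suppressPackageStartupMessages(library(selstab))

files <- list.files("results/run", pattern = "^errors_.*\\.json$",
                    full.names = TRUE)
errors <- lapply(files, function(f) {
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  structure(list(method_id = j$method_id, rates = j$rates,
                 test_sizes = j$test_sizes), class = "ErrorVector")
})

cmp <- compare_methods(errors, alpha = 0.01)
print(cmp)
write.table(cmp$table, "results/comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

long <- do.call(rbind, lapply(errors, function(e)
  data.frame(method = e$method_id, iteration = seq_along(e$rates),
             error = e$rates)))
write.table(long, "results/errors_long.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/comparison.tsv and results/errors_long.tsv\n")
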