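#!/usr/bin/env Rscript
# Run the full selection-stability benchmark on the simulated dataset:
# one shared 15-iteration bootstrap plan, four selection methods (Boruta at
# fern depths 1 and 5, the shadow t-test selector, recursive feature
# elimination, and the regularised random forest), each producing a
# selection matrix, a self-consistency report and a post-selection error
# vector under results/run/.

suppressPackageStartupMessages(library(selstab))

data <- read_expression("results/data.tsv", "class")
print(data)

grid <- list(
  list(method = "boruta", importance = importance_ferns(1, 2000),
       max_iterations = 100),
  list(method = "boruta", importance = importance_ferns(5, 2000),
       max_iterations = 100),
  list(method = "ace", importance = importance_ferns(5, 2000),
       n_iterations = 20),
  list(method = "rfe", importance = importance_ferns(5, 2000),
       n_boot = 10, n_trees_eval = 200),
  list(method = "rrf", lambda = 0.8, n_trees = 100))

bench <- run_benchmark(data, grid, B = 15L, seed = 20240102,
                       out_dir = "results/run", n_trees_validation = 500)

for (id in names(bench$scs)) print(bench$scs[[id]])
cat("artifacts in results/run/\n")
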