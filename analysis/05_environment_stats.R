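#!/usr/bin/env Rscript
# Step 5 -- cross-environment statistics.
#
# Over the screened environments of a random-pair population: Jaccard
# distances within and between competitive and cooperative environments,
# per-compound appearance bias against the random-assignment binomial
# null, and metabolic-complexity terciles of the model population.

suppressMessages(library(pairfba))
dir.create("results", showWarnings = FALSE)
seed <- 20260924
set.seed(seed)

n_pairs <- 20
models <- list()
env_sets <- list(); env_labels <- c()
attempts <- 0
while (attempts < 10 * n_pairs && length(models) < 2 * n_pairs) {
  attempts <- attempts + 1
  sp <- random_toy_pair(n_private = sample(1:2, 1), n_shared = sample(0:2, 1),
                        n_crossfeed = sample(1:3, 1), depth = sample(1:2, 1),
                        yield = runif(1, 0.5, 2))
  pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
  sets <- tryCatch(find_essential_compounds(pair), error = function(e) NULL)
  if (is.null(sets) || length(sets$substitutable) < 4) next
  models <- c(models, sp$models)
  sr <- screen_pair(pair, n_viable_target = 20,
                    n_additional = max(1, ceiling(0.3 * length(sets$substitutable))),
                    sets = sets, seed = sample.int(2^31 - 1, 1))
  for (r in Filter(function(x) x$viable, sr$environments)) {
    lab <- r$assessment$label
    cls <- if (lab == "COMPETITIVE") "competitive" else if
    (lab %in% c("FACULTATIVE_COOP", "ONEWAY_OBLIGATE", "TWOWAY_OBLIGATE"))
      "cooperative" else NA
    if (is.na(cls)) next
    env_sets[[length(env_sets) + 1]] <- r$compounds
    env_labels <- c(env_labels, cls)
  }
}

if (length(unique(env_labels)) == 2) {
  bias <- compound_bias(env_sets, env_labels)
  write.csv(bias, "results/compound_bias.csv", row.names = FALSE)
  cat(sprintf("Compound bias over %d labeled environments, %d compounds; median |bias| %.3f\n",
              length(env_labels), nrow(bias), stats::median(abs(bias$bias))))
  jd_within <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(apply(utils::combn(idx, 2), 2, function(ij)
      jaccard_distance(env_sets[[ij[1]]], env_sets[[ij[2]]])))
  }
  comp <- which(env_labels == "competitive"); coop <- which(env_labels == "cooperative")
  jd_between <- mean(outer(comp, coop, Vectorize(function(i, j)
    jaccard_distance(env_sets[[i]], env_sets[[j]]))))
  cat(sprintf("Mean Jaccard distance: comp-comp %.2f, coop-coop %.2f, comp-coop %.2f\n",
              jd_within(comp), jd_within(coop), jd_between))
} else {
  cat("Too few labeled environments of one class for the bias analysis.\n")
}

cx <- complexity_terciles(models, metric = "n_usable_metabolites")
write.csv(cx, "results/complexity_terciles.csv", row.names = FALSE)
cat("Complexity tercile sizes:\n"); print(table(cx$category))
cat("Wrote results/complexity_terciles.csv\n")
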