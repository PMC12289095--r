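#!/usr/bin/env Rscript
# Step 2 -- environment screening across random toy pairs.
#
# For a population of random cross-feeding toy pairs, samples random
# fixed-size environments (all essential compounds plus a fixed number of
# substitutable ones at supply -1000) until a target number of viable
# environments per pair, classifies each, and summarizes how often pairs
# can compete and/or cooperate and which cooperation subtype dominates.
# Two environment sizes (30% and 60% of each pair's substitutable pool,
# the toy-scale analogue of 50- vs 100-compound environments) probe how
# resource diversity shifts the interaction spectrum.

suppressMessages(library(pairfba))
dir.create("results", showWarnings = FALSE)
seed <- 20260924
set.seed(seed)

n_pairs <- 30
summaries <- list()
attempts <- 0
while (length(summaries) < 2 * n_pairs && attempts < 10 * n_pairs) {
  attempts <- attempts + 1
  sp <- random_toy_pair(n_private = sample(1:2, 1), n_shared = sample(0:2, 1),
                        n_crossfeed = sample(1:3, 1), depth = sample(1:2, 1),
                        yield = runif(1, 0.5, 2))
  pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
  sets <- tryCatch(find_essential_compounds(pair), error = function(e) NULL)
  if (is.null(sets) || length(sets$substitutable) < 4) next
  for (frac in c(0.3, 0.6)) {
    n_add <- max(1, ceiling(frac * length(sets$substitutable)))
    sr <- screen_pair(pair, n_viable_target = 25, n_additional = n_add,
                      sets = sets, seed = sample.int(2^31 - 1, 1))
    sr$summary$size_class <- if (frac == 0.3) "small" else "large"
    summaries[[length(summaries) + 1]] <- sr
  }
}
tab <- do.call(rbind, lapply(summaries, `[[`, "summary"))
write.csv(tab, "results/screen_summary.csv", row.names = FALSE)

for (cls in c("small", "large")) {
  sub <- tab[tab$size_class == cls & tab$n_viable > 0, ]
  cat(sprintf(
    "%s environments (%d pairs): mean shares comp %.2f / coop %.2f / other %.2f\n",
    cls, nrow(sub), mean(sub$prop_competitive), mean(sub$prop_cooperative),
    mean(sub$prop_other)))
}
agg <- aggregate_screens(summaries)
write.csv(agg$pairs, "results/screen_pairs.csv", row.names = FALSE)
cat("Across all screens: ",
    sprintf("%.0f%% pair-screens found cooperation, %.0f%% found competition, %.0f%% both.\n",
            100 * mean(agg$pairs$any_cooperative),
            100 * mean(agg$pairs$any_competitive),
            100 * mean(agg$pairs$both)))
if (length(agg$modal_subtype_shares)) {
  cat("Modal cooperation subtypes:\n"); print(agg$modal_subtype_shares)
}
cat("Wrote results/screen_summary.csv and results/screen_pairs.csv\n")
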