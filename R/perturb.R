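# Environment perturbation: single-compound-removal stability scans,
# reduction to used compounds, and sequential environment degradation.

.OBLIGATE_LABELS <- c("ONEWAY_OBLIGATE", "TWOWAY_OBLIGATE", "OBLIGATE_COMMENSAL")

#' Transition class between two interaction labels
#'
#' Buckets a before/after label pair: `same` when unchanged, otherwise by
#' the destination: `to_competitive`, `to_facultative`, `to_obligate`
#' (covering one-way, two-way, and obligate-commensal destinations),
#' `to_no_growth`, and `to_other` for neutral/commensal destinations.
#'
#' @param before,after interaction labels.
#' @return Character transition class.
#' @export
transition_class <- function(before, after) {
  stopifnot(before %in% INTERACTION_LABELS, after %in% INTERACTION_LABELS)
  if (before == after) return("same")
  if (after == "COMPETITIVE") return("to_competitive")
  if (after == "FACULTATIVE_COOP") return("to_facultative")
  if (after %in% .OBLIGATE_LABELS) return("to_obligate")
  if (after == "NO_GROWTH") return("to_no_growth")
  "to_other"
}

#' Single-compound-removal stability scan
#'
#' For each non-essential present compound, re-classifies the pair with
#' that compound alone removed (lower bound to zero, everything else
#' intact). Removals are independent: each starts from the full starting
#' environment. Essential compounds are skipped; removing one is already
#' known to abolish growth.
#'
#' @param pair a [build_pair_model()] result.
#' @param env the starting [growth_env()].
#' @param sets a [find_essential_compounds()] result for the pair.
#' @param tol a [tolerance_config()].
#' @return A data.frame with columns `compound`, `label_before`,
#'   `label_after`, `transition`.
#' @export
single_removal_scan <- function(pair, env, sets, tol = tolerance_config()) {
  stopifnot(inherits(pair, "pair_model"), inherits(sets, "pair_compound_sets"))
  before <- assess_pair(pair, env = env, tol = tol)$label
  scan <- setdiff(env_compounds(env), sets$essential)
  rows <- lapply(scan, function(k) {
    after <- assess_pair(pair, env = env_remove(env, k), tol = tol)$label
    data.frame(compound = k, label_before = before, label_after = after,
               transition = transition_class(before, after),
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(compound = character(), label_before = character(),
               label_after = character(), transition = character(),
               stringsAsFactors = FALSE)
  }
}

# directed no-harm solve followed by an L1 uptake-minimizing solve at the
# (near-)fixed optimum; returns per-compound uptake magnitudes
.min_uptake_pattern <- function(pair, env, focal, partner_floor, lambda_star,
                                tol) {
  partner <- setdiff(c("A", "B"), focal)
  ext <- pair$compartment == "extracellular"
  ids <- rownames(pair$S)[ext]
  present <- intersect(env_compounds(env), ids)
  nv <- ncol(pair$S); nt <- length(present)
  rows <- .fba_rows(pair$S, pair$compartment, env)
  Sx <- as.matrix(pair$S)
  A <- cbind(Sx, matrix(0, nrow(Sx), nt))
  rl <- rows$rl; ru <- rows$ru
  # uptake slack rows: t_k + (S_E v)_k >= 0 so t_k >= uptake magnitude
  for (i in seq_len(nt)) {
    row <- numeric(nv + nt)
    ridx <- which(rownames(pair$S) == present[i])
    row[seq_len(nv)] <- Sx[ridx, ]
    row[nv + i] <- 1
    A <- rbind(A, row)
    rl <- c(rl, 0); ru <- c(ru, Inf)
  }
  # hold both organisms at their achieved rates (within eps_class)
  frow <- c(as.numeric(colnames(pair$S) == pair$biomass[[focal]]), numeric(nt))
  prow <- c(as.numeric(colnames(pair$S) == pair$biomass[[partner]]), numeric(nt))
  A <- rbind(A, frow, prow)
  rl <- c(rl, max(0, lambda_star - tol$eps_class), max(0, partner_floor - tol$eps_class))
  ru <- c(ru, Inf, Inf)
  obj <- c(numeric(nv), rep(-1, nt))   # maximize -sum(t) = minimize uptake
  sol <- lp_solve(obj, A, rl, ru,
                  lb = c(pair$lb, numeric(nt)),
                  ub = c(pair$ub, rep(Inf, nt)))
  if (sol$status != "optimal") {
    stop(".min_uptake_pattern: secondary LP not optimal (", sol$status, ")")
  }
  stats::setNames(sol$x[nv + seq_len(nt)], present)
}

#' Reduce an environment to its used compounds
#'
#' Optimal flux vectors are not unique, so "used" is made deterministic by
#' a secondary objective: after each directed no-harm solve, both growth
#' rates are held at their optima (within `eps_class`) and the total
#' absolute environmental uptake is minimized. A compound is used when it
#' has net uptake above `use_tol` in either directed solution; the reduced
#' environment keeps used plus essential compounds and must classify
#' identically to the original.
#'
#' @param pair a [build_pair_model()] result.
#' @param env a viable starting [growth_env()].
#' @param sets a [find_essential_compounds()] result.
#' @param tol a [tolerance_config()].
#' @param use_tol numeric uptake threshold for counting a compound as used.
#' @return A [growth_env()] containing only used and essential compounds.
#' @export
reduce_to_used_compounds <- function(pair, env, sets,
                                     tol = tolerance_config(),
                                     use_tol = 1e-6) {
  before <- assess_pair(pair, env = env, tol = tol)
  la <- before$lambda_alone
  used <- character()
  for (k in 1:2) {
    focal <- c("A", "B")[k]; partner_floor <- la[3 - k]
    uptake <- .min_uptake_pattern(pair, env, focal, partner_floor,
                                  before$lambda_together[k], tol)
    used <- union(used, names(uptake)[uptake > use_tol])
  }
  keep <- intersect(env_compounds(env), union(used, sets$essential))
  reduced <- growth_env(lower = env$lower[names(env$lower) %in% keep],
                        upper = env$upper)
  after <- assess_pair(pair, env = reduced, tol = tol)
  if (after$label != before$label) {
    stop("reduce_to_used_compounds: reduction changed the label from ",
         before$label, " to ", after$label,
         "; tolerance configuration is inconsistent")
  }
  reduced
}

# viability-first label used along degradation paths: the walk stops when
# at least one organism can no longer grow, so that state is NO_GROWTH
# whatever the symbols say
.degrade_label <- function(pair, env, tol) {
  jv <- joint_viability(pair, env, tol)
  if (!jv$viable) return("NO_GROWTH")
  classify_interaction(jv$lambda_alone, jv$lambda_together, tol)$label
}

#' Degrade an environment along one removal ordering
#'
#' Removes the given compounds one at a time, re-classifying after each,
#' stopping as soon as at least one organism's no-harm growth rate falls
#' below `eps_grow` (terminal `NO_GROWTH`) or the ordering is exhausted.
#'
#' @param pair a [build_pair_model()] result.
#' @param env the starting [growth_env()] (already reduced).
#' @param ordering character vector of compounds to remove, in order.
#' @param tol a [tolerance_config()].
#' @return An object of class `degradation_path`: `removal_order` (the
#'   removals actually performed), `labels` (length removals + 1, starting
#'   label first) and `terminal_reason` (`"no_growth"` or `"exhausted"`).
#' @export
degrade_ordering <- function(pair, env, ordering, tol = tolerance_config()) {
  labels <- .degrade_label(pair, env, tol)
  performed <- character()
  cur <- env
  for (k in ordering) {
    cur <- env_remove(cur, k)
    performed <- c(performed, k)
    lab <- .degrade_label(pair, cur, tol)
    labels <- c(labels, lab)
    if (lab == "NO_GROWTH") break
  }
  structure(list(pair_ids = pair$organism_ids,
                 removal_order = performed,
                 labels = labels,
                 terminal_reason = if (labels[length(labels)] == "NO_GROWTH")
                   "no_growth" else "exhausted"),
            class = "degradation_path")
}

#' @export
print.degradation_path <- function(x, ...) {
  cat("<degradation_path> ", length(x$removal_order), " removals, ",
      x$labels[1], " -> ", x$labels[length(x$labels)],
      " (", x$terminal_reason, ")\n", sep = "")
  invisible(x)
}

#' Sequentially degrade an environment under random removal orderings
#'
#' First reduces the environment to its used compounds (see
#' [reduce_to_used_compounds()]), then, for each of `n_orderings` uniform
#' random permutations of the non-essential present compounds, removes
#' compounds one at a time until at least one organism can no longer grow
#' or the removable compounds are exhausted. Essential compounds are never
#' removed.
#'
#' @param pair a [build_pair_model()] result.
#' @param env a viable starting [growth_env()].
#' @param sets a [find_essential_compounds()] result.
#' @param n_orderings number of random removal orderings.
#' @param tol a [tolerance_config()].
#' @param seed optional integer seed.
#' @param reduce set `FALSE` to skip the used-compound reduction.
#' @return List of `degradation_path` objects, one per ordering.
#' @export
degrade_environment <- function(pair, env, sets, n_orderings = 50,
                                tol = tolerance_config(), seed = NULL,
                                reduce = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (reduce) env <- reduce_to_used_compounds(pair, env, sets, tol)
  removable <- setdiff(env_compounds(env), sets$essential)
  lapply(seq_len(n_orderings), function(i) {
    ordering <- if (length(removable)) sample(removable) else character()
    degrade_ordering(pair, env, ordering, tol)
  })
}

#' Summarize degradation paths
#'
#' Computes (i) per-path removals before the first label change (paths
#' with no change are censored at their full length and flagged), (ii) the
#' tally of transition sequences with consecutive duplicate labels
#' collapsed, and (iii) the share of no-growth-terminated paths whose last
#' label before `NO_GROWTH` was obligate.
#'
#' @param paths list of `degradation_path` objects.
#' @return A list with `paths` (per-path data.frame: `n_removals`,
#'   `first_change`, `censored`, `terminal_label`, `terminal_reason`),
#'   `sequences` (collapsed label sequences with counts and proportions)
#'   and `share_obligate_before_no_growth`.
#' @export
summarize_paths <- function(paths) {
  per <- lapply(paths, function(p) {
    labs <- p$labels
    nrem <- length(p$removal_order)
    change_at <- which(labs[-1] != labs[-length(labs)])
    censored <- length(change_at) == 0
    first_change <- if (censored) nrem else change_at[1]
    collapsed <- rle(labs)$values
    last_before_ng <- if (labs[length(labs)] == "NO_GROWTH" &&
                          length(collapsed) >= 2) {
      collapsed[length(collapsed) - 1]
    } else NA_character_
    list(row = data.frame(n_removals = nrem, first_change = first_change,
                          censored = censored,
                          terminal_label = labs[length(labs)],
                          terminal_reason = p$terminal_reason,
                          stringsAsFactors = FALSE),
         seq = paste(collapsed, collapse = ">"),
         last_before_ng = last_before_ng)
  })
  df <- do.call(rbind, lapply(per, `[[`, "row"))
  seqs <- vapply(per, `[[`, character(1), "seq")
  tab <- sort(table(seqs), decreasing = TRUE)
  sequences <- data.frame(sequence = names(tab), count = as.integer(tab),
                          proportion = as.numeric(tab) / length(seqs),
                          stringsAsFactors = FALSE)
  lbng <- vapply(per, `[[`, character(1), "last_before_ng")
  ended_ng <- !is.na(lbng)
  share_obl <- if (any(ended_ng)) {
    mean(lbng[ended_ng] %in% .OBLIGATE_LABELS)
  } else NA_real_
  list(paths = df, sequences = sequences,
       share_obligate_before_no_growth = share_obl)
}
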