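# Environment screening: sample random environments for a pair until a
# target number of viable ones is found, classify each, and aggregate.

.COOP_LABELS <- c("FACULTATIVE_COOP", "ONEWAY_OBLIGATE", "TWOWAY_OBLIGATE")
.OTHER_LABELS <- c("NEUTRAL", "COMMENSAL", "OBLIGATE_COMMENSAL")

#' Cooperation subtype of an assessment
#'
#' Cooperative interactions split by whether each partner is viable alone:
#' facultative (both are), one-way obligate (one is), two-way obligate
#' (neither is). Everything else is `not_cooperative`.
#'
#' @param assessment an `interaction_assessment` (or a label string).
#' @return One of `"facultative"`, `"one_way_obligate"`,
#'   `"two_way_obligate"`, `"not_cooperative"`.
#' @export
subtype_cooperation <- function(assessment) {
  label <- if (inherits(assessment, "interaction_assessment")) {
    assessment$label
  } else as.character(assessment)
  switch(label,
         FACULTATIVE_COOP = "facultative",
         ONEWAY_OBLIGATE = "one_way_obligate",
         TWOWAY_OBLIGATE = "two_way_obligate",
         "not_cooperative")
}

#' Screen random environments for a pair
#'
#' Repeatedly generates random fixed-size environments (essential
#' compounds plus `n_additional` sampled substitutable compounds, each
#' supplied at `-supply`) and assesses the pair in each, until
#' `n_viable_target` viable environments are found or `max_attempts` is
#' reached. An environment is viable when both organisms' no-harm growth
#' rates are at least `eps_grow`.
#'
#' @param a,b [metabolic_model()] objects (or `a` a prebuilt pair model and
#'   `b = NULL`).
#' @param n_viable_target viable environments to collect.
#' @param n_additional substitutable compounds per environment.
#' @param supply supply magnitude for present compounds.
#' @param max_attempts sampling cap (default 10 x target).
#' @param sets optional precomputed [find_essential_compounds()] result.
#' @param tol a [tolerance_config()].
#' @param seed optional integer seed for the sampling stream.
#' @return An object of class `screen_result`: `summary` (a one-row
#'   data.frame with counts, triangle proportions competitive/cooperative/
#'   other, cooperation-subtype proportions and the modal subtype, plus a
#'   `partial` flag) and `environments` (a list of records with the
#'   sampled compound set, the assessment, and the viability flag).
#' @export
screen_pair <- function(a, b = NULL, n_viable_target = 100, n_additional,
                        supply = 1000, max_attempts = 10 * n_viable_target,
                        sets = NULL, tol = tolerance_config(), seed = NULL) {
  pair <- if (inherits(a, "pair_model")) a else build_pair_model(a, b)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sets)) sets <- find_essential_compounds(pair, tol, supply)
  records <- vector("list", max_attempts)
  n_viable <- 0L; attempt <- 0L
  while (n_viable < n_viable_target && attempt < max_attempts) {
    attempt <- attempt + 1L
    env <- generate_random_environment(sets, n_additional, supply,
                                       pair$default_env)
    asmt <- assess_pair(pair, env = env, tol = tol)
    viable <- all(asmt$lambda_together >= tol$eps_grow)
    if (viable) n_viable <- n_viable + 1L
    records[[attempt]] <- list(compounds = env_compounds(env), env = env,
                               assessment = asmt, viable = viable)
  }
  records <- records[seq_len(attempt)]
  viable_labels <- vapply(Filter(function(r) r$viable, records),
                          function(r) r$assessment$label, character(1))
  counts <- table(factor(viable_labels, levels = INTERACTION_LABELS))
  n_comp <- sum(counts["COMPETITIVE"])
  n_coop <- sum(counts[.COOP_LABELS])
  n_other <- sum(counts[.OTHER_LABELS])
  subtype_counts <- c(
    facultative = unname(counts["FACULTATIVE_COOP"]),
    one_way_obligate = unname(counts["ONEWAY_OBLIGATE"]),
    two_way_obligate = unname(counts["TWOWAY_OBLIGATE"]))
  summary <- data.frame(
    pair_a = pair$organism_ids[["A"]], pair_b = pair$organism_ids[["B"]],
    n_additional = n_additional, n_attempted = attempt, n_viable = n_viable,
    partial = n_viable < n_viable_target,
    prop_competitive = if (n_viable) n_comp / n_viable else NA_real_,
    prop_cooperative = if (n_viable) n_coop / n_viable else NA_real_,
    prop_other = if (n_viable) n_other / n_viable else NA_real_,
    prop_facultative = if (n_coop) subtype_counts[["facultative"]] / n_coop else NA_real_,
    prop_one_way = if (n_coop) subtype_counts[["one_way_obligate"]] / n_coop else NA_real_,
    prop_two_way = if (n_coop) subtype_counts[["two_way_obligate"]] / n_coop else NA_real_,
    modal_subtype = if (n_coop) {
      names(subtype_counts)[which.max(subtype_counts)]
    } else NA_character_,
    stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 label_counts = counts,
                 environments = records),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat("<screen_result> ", s$pair_a, " + ", s$pair_b, ": ", s$n_viable,
      " viable / ", s$n_attempted, " attempted",
      if (s$partial) " (PARTIAL)", "\n", sep = "")
  if (!is.na(s$prop_competitive)) {
    cat(sprintf("  triangle (comp, coop, other) = (%.2f, %.2f, %.2f)\n",
                s$prop_competitive, s$prop_cooperative, s$prop_other))
  }
  invisible(x)
}

#' Aggregate screen summaries across pairs
#'
#' Per pair: whether at least one competitive and/or at least one
#' cooperative viable environment was found; population shares of
#' pairs finding competition-only, cooperation-only, both, or neither;
#' and modal cooperation-subtype shares.
#'
#' @param screens list of [screen_pair()] results (or their `summary` rows).
#' @return A list with `pairs` (per-pair data.frame), `shares` and
#'   `modal_subtype_shares` (named numeric vectors). Empty input gives
#'   empty tables.
#' @export
aggregate_screens <- function(screens) {
  if (length(screens) == 0) {
    return(list(pairs = data.frame(), shares = numeric(),
                modal_subtype_shares = numeric()))
  }
  rows <- lapply(screens, function(s) {
    if (inherits(s, "screen_result")) s <- s$summary
    data.frame(pair_a = s$pair_a, pair_b = s$pair_b,
               any_competitive = isTRUE(s$prop_competitive > 0),
               any_cooperative = isTRUE(s$prop_cooperative > 0),
               modal_subtype = s$modal_subtype,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$both <- pairs$any_competitive & pairs$any_cooperative
  n <- nrow(pairs)
  shares <- c(
    both = sum(pairs$both) / n,
    competitive_only = sum(pairs$any_competitive & !pairs$any_cooperative) / n,
    cooperative_only = sum(!pairs$any_competitive & pairs$any_cooperative) / n,
    neither = sum(!pairs$any_competitive & !pairs$any_cooperative) / n)
  modal <- pairs$modal_subtype[!is.na(pairs$modal_subtype)]
  modal_shares <- if (length(modal)) {
    tab <- table(factor(modal, levels = c("facultative", "one_way_obligate",
                                          "two_way_obligate")))
    as.numeric(tab) / length(modal) -> v
    stats::setNames(v, names(tab))
  } else numeric()
  list(pairs = pairs, shares = shares, modal_subtype_shares = modal_shares)
}
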