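# Flux balance analysis: individual growth, coupled pair growth with the
# partner no-harm constraint, and interaction classification.

#' Interaction labels
#'
#' The taxonomy of pairwise interaction labels, derived from comparing each
#' organism's growth rate alone (lambda) and together (lambda*): any loser
#' makes the pair competitive; both winners is cooperation, subtyped by
#' whether each partner is viable alone.
#' @format Character vector of the eight labels.
#' @export
INTERACTION_LABELS <- c("COMPETITIVE", "NEUTRAL", "COMMENSAL",
                        "FACULTATIVE_COOP", "ONEWAY_OBLIGATE",
                        "TWOWAY_OBLIGATE", "OBLIGATE_COMMENSAL", "NO_GROWTH")

# assemble LP rows for a model/pair matrix
.fba_rows <- function(S, compartment, env) {
  ids <- rownames(S)
  ext <- compartment == "extracellular"
  rl <- numeric(length(ids)); ru <- numeric(length(ids))
  rl[ext] <- env_lower_for(env, ids[ext])
  ru[ext] <- env_upper_for(env, ids[ext])
  list(rl = rl, ru = ru)
}

.growth_result <- function(sol, S, compartment, biomass_idx, eps_grow) {
  ext <- compartment == "extracellular"
  if (sol$status != "optimal") {
    return(structure(list(lambda = if (sol$status == "unbounded") Inf else NA_real_,
                          status = sol$status, flux = NULL, env_net = NULL),
                     class = "growth_result"))
  }
  v <- stats::setNames(sol$x, colnames(S))
  lambda <- max(0, sol$objective)
  structure(list(
    lambda = lambda,
    status = if (lambda < eps_grow) "no_growth" else "optimal",
    flux = v,
    env_net = stats::setNames(as.numeric(S[ext, , drop = FALSE] %*% sol$x),
                              rownames(S)[ext])
  ), class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("<growth_result> status = ", x$status, ", lambda = ",
      format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Maximal growth rate of a single organism in an environment
#'
#' Solves the flux balance program: maximize biomass flux subject to
#' steady-state mass balance, flux bounds, and environment bounds on the
#' extracellular net-change vector (intracellular net change fixed at
#' zero). Extracellular compounds the environment does not list get zero
#' bounds (no net uptake, no net export).
#'
#' @param model a [metabolic_model()] (canonicalized: no exchange columns).
#' @param env a [growth_env()].
#' @param tol a [tolerance_config()].
#' @return A `growth_result` with fields `lambda` (growth rate), `status`
#'   (`"optimal"`, `"no_growth"` when the optimum is below `eps_grow`,
#'   `"infeasible"`, `"unbounded"`), `flux` (named flux vector) and
#'   `env_net` (realized extracellular net change).
#' @export
solve_individual_growth <- function(model, env, tol = tolerance_config()) {
  stopifnot(inherits(model, "metabolic_model"), inherits(env, "growth_env"))
  rows <- .fba_rows(model$S, model$compartment, env)
  obj <- as.numeric(colnames(model$S) == model$biomass_id)
  sol <- lp_solve(obj, model$S, rows$rl, rows$ru, model$lb, model$ub)
  .growth_result(sol, model$S, model$compartment,
                 which(colnames(model$S) == model$biomass_id), tol$eps_grow)
}

#' Combine two metabolic models into a pair model
#'
#' Builds the combined stoichiometric matrix of a pair: extracellular rows
#' are shared (the union of both extracellular compound sets, identified by
#' compound id), intracellular rows (cytoplasm and periplasm) are kept
#' strictly per organism, and reaction columns are concatenated with
#' organism qualifiers. The pair's combined default environment (the
#' per-compound sum of the two default environments) is attached.
#'
#' @param a,b [metabolic_model()] objects sharing a compound-id namespace.
#' @return An object of class `pair_model`.
#' @export
build_pair_model <- function(a, b) {
  stopifnot(inherits(a, "metabolic_model"), inherits(b, "metabolic_model"))
  ext_a <- rownames(a$S)[is_extracellular(a)]
  ext_b <- rownames(b$S)[is_extracellular(b)]
  int_a <- setdiff(rownames(a$S), ext_a)
  int_b <- setdiff(rownames(b$S), ext_b)
  clash <- union(intersect(ext_a, int_b), intersect(ext_b, int_a))
  if (length(clash)) {
    stop("build_pair_model: compound ", paste(clash, collapse = ", "),
         " is extracellular in one model and intracellular in the other")
  }
  ext <- union(ext_a, ext_b)
  rows <- c(ext, paste0("A#", int_a), paste0("B#", int_b))
  cols <- c(paste0("A#", colnames(a$S)), paste0("B#", colnames(b$S)))
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(rows), length(cols)),
                            dimnames = list(rows, cols))
  S <- as(S, "CsparseMatrix")
  S[ext_a, paste0("A#", colnames(a$S))] <- a$S[ext_a, , drop = FALSE]
  S[paste0("A#", int_a), paste0("A#", colnames(a$S))] <- a$S[int_a, , drop = FALSE]
  S[ext_b, paste0("B#", colnames(b$S))] <- b$S[ext_b, , drop = FALSE]
  S[paste0("B#", int_b), paste0("B#", colnames(b$S))] <- b$S[int_b, , drop = FALSE]
  structure(list(
    organism_ids = c(A = a$model_id, B = b$model_id),
    S = S,
    lb = stats::setNames(c(a$lb, b$lb), cols),
    ub = stats::setNames(c(a$ub, b$ub), cols),
    compartment = stats::setNames(
      c(rep("extracellular", length(ext)),
        a$compartment[int_a], b$compartment[int_b]), rows),
    organism = stats::setNames(rep(c("A", "B"), c(ncol(a$S), ncol(b$S))), cols),
    biomass = c(A = paste0("A#", a$biomass_id), B = paste0("B#", b$biomass_id)),
    default_env = combine_default_environments(a, b)
  ), class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat("<pair_model> ", x$organism_ids[["A"]], " + ", x$organism_ids[["B"]],
      ": ", sum(x$compartment == "extracellular"), " shared extracellular rows, ",
      nrow(x$S), " rows, ", ncol(x$S), " reactions\n", sep = "")
  invisible(x)
}

# growth of one organism of a pair on its own (partner fluxes clamped to 0);
# identical to solve_individual_growth on the single model in the same env.
pair_solo_growth <- function(pair, env, org, tol = tolerance_config()) {
  lb <- pair$lb; ub <- pair$ub
  other <- pair$organism != org
  lb[other] <- 0; ub[other] <- 0
  rows <- .fba_rows(pair$S, pair$compartment, env)
  obj <- as.numeric(colnames(pair$S) == pair$biomass[[org]])
  sol <- lp_solve(obj, pair$S, rows$rl, rows$ru, lb, ub)
  .growth_result(sol, pair$S, pair$compartment, NULL, tol$eps_grow)
}

#' Maximal growth of one organism with a partner no-harm floor
#'
#' Solves the coupled pair program: maximize the focal organism's biomass
#' flux over the combined system (shared extracellular net change bounded by
#' the environment, both intracellular blocks balanced at zero), subject to
#' the partner's biomass flux being no worse than its solo growth rate minus
#' `eps_class`. The floor is clamped at zero, so a partner unable to grow
#' alone imposes no constraint.
#'
#' @param pair a [build_pair_model()] result.
#' @param env a [growth_env()].
#' @param focal `"A"` or `"B"` (or an organism id of the pair).
#' @param partner_floor the partner's solo growth rate in `env`.
#' @param tol a [tolerance_config()].
#' @return A `growth_result` for the focal organism (`lambda` is lambda*).
#' @export
solve_pair_growth <- function(pair, env, focal, partner_floor,
                              tol = tolerance_config()) {
  stopifnot(inherits(pair, "pair_model"))
  focal <- .resolve_org(pair, focal)
  partner <- setdiff(c("A", "B"), focal)
  rows <- .fba_rows(pair$S, pair$compartment, env)
  # partner no-harm constraint as an extra row
  floor_row <- as.numeric(colnames(pair$S) == pair$biomass[[partner]])
  A <- rbind(as.matrix(pair$S), floor_row)
  rl <- c(rows$rl, max(0, partner_floor - tol$eps_class))
  ru <- c(rows$ru, Inf)
  obj <- as.numeric(colnames(pair$S) == pair$biomass[[focal]])
  sol <- lp_solve(obj, A, rl, ru, pair$lb, pair$ub)
  if (sol$status == "infeasible" && partner_floor > 0) {
    # the partner's solo solution plus zero focal flux is always feasible,
    # so this can only be a bug or a numerically inconsistent floor
    retry <- lp_solve(obj, A, c(rows$rl, 0), ru, pair$lb, pair$ub)
    if (retry$status == "optimal") {
      stop("solve_pair_growth: pair LP infeasible with partner floor ",
           partner_floor, " but feasible without; inconsistent inputs")
    }
  }
  .growth_result(sol, pair$S, pair$compartment, NULL, tol$eps_grow)
}

.resolve_org <- function(pair, org) {
  if (org %in% c("A", "B")) return(org)
  hit <- names(pair$organism_ids)[pair$organism_ids == org]
  if (length(hit) != 1) stop("unknown or ambiguous organism: ", org)
  hit
}

#' Classify a pairwise interaction from growth rates
#'
#' Compares each organism's growth rate alone and together, with tolerance
#' `eps_class`: a symbol of `minus` (worse together), `equal`, or `plus`
#' (better together) per organism; `plus`/`equal` is upgraded to `cross`
#' when the organism is non-viable alone (`lambda < eps_grow`) but viable
#' together. Labels: any `minus` makes the pair `COMPETITIVE`; otherwise an
#' organism left non-viable together gives `NO_GROWTH`; otherwise the
#' symbol pair maps to `NEUTRAL` (=/=), `COMMENSAL` (+/=),
#' `FACULTATIVE_COOP` (+/+), `ONEWAY_OBLIGATE` (x/+), `TWOWAY_OBLIGATE`
#' (x/x) or `OBLIGATE_COMMENSAL` (x/=). The exploitative combinations
#' (+/-) and (-/+) cannot occur under the no-harm optimization.
#'
#' @param lambda_alone,lambda_together numeric length-2 vectors (organism
#'   A, organism B), all non-negative.
#' @param tol a [tolerance_config()].
#' @return An object of class `interaction_assessment` with fields
#'   `lambda_alone`, `lambda_together`, `symbols`, `label`.
#' @export
classify_interaction <- function(lambda_alone, lambda_together,
                                 tol = tolerance_config()) {
  stopifnot(length(lambda_alone) == 2, length(lambda_together) == 2)
  if (any(c(lambda_alone, lambda_together) < 0)) {
    stop("classify_interaction: growth rates must be non-negative")
  }
  eps <- tol$eps_class
  sym <- character(2)
  for (k in 1:2) {
    d <- lambda_together[k] - lambda_alone[k]
    sym[k] <- if (d < -eps) "minus" else if (d > eps) "plus" else "equal"
    if (lambda_alone[k] < tol$eps_grow && lambda_together[k] >= tol$eps_grow) {
      sym[k] <- "cross"
    }
  }
  if (("plus" %in% sym && "minus" %in% sym)) {
    stop("classify_interaction: exploitation symbols (+/-) are impossible ",
         "under the no-harm scheme; inputs are inconsistent")
  }
  label <- if ("minus" %in% sym) {
    "COMPETITIVE"
  } else if (any(lambda_together < tol$eps_grow)) {
    "NO_GROWTH"
  } else {
    key <- paste(sort(sym), collapse = "/")
    switch(key,
           "equal/equal" = "NEUTRAL",
           "equal/plus"  = "COMMENSAL",
           "plus/plus"   = "FACULTATIVE_COOP",
           "cross/plus"  = "ONEWAY_OBLIGATE",
           "cross/cross" = "TWOWAY_OBLIGATE",
           "cross/equal" = "OBLIGATE_COMMENSAL",
           stop("classify_interaction: unreachable symbol pair ", key))
  }
  structure(list(lambda_alone = as.numeric(lambda_alone),
                 lambda_together = as.numeric(lambda_together),
                 symbols = sym, label = label),
            class = "interaction_assessment")
}

#' @export
print.interaction_assessment <- function(x, ...) {
  symch <- c(minus = "-", equal = "=", plus = "+", cross = "x")
  cat("<interaction_assessment> ", x$label, " (",
      symch[x$symbols[1]], "/", symch[x$symbols[2]], ")  lambda alone = (",
      format(x$lambda_alone[1]), ", ", format(x$lambda_alone[2]),
      "), together = (", format(x$lambda_together[1]), ", ",
      format(x$lambda_together[2]), ")\n", sep = "")
  invisible(x)
}

#' Assess the interaction of a pair in an environment
#'
#' Composes the full assessment: each organism's solo growth rate, each
#' organism's maximal growth with the partner floored at its solo rate, and
#' the interaction classification.
#'
#' @param a a [metabolic_model()] or a prebuilt [build_pair_model()] (in
#'   which case `b` must be `NULL`).
#' @param b a [metabolic_model()] or `NULL`.
#' @param env a [growth_env()].
#' @param tol a [tolerance_config()].
#' @return An `interaction_assessment` with the four growth rates, symbols
#'   and label.
#' @export
assess_pair <- function(a, b = NULL, env, tol = tolerance_config()) {
  pair <- if (inherits(a, "pair_model")) a else build_pair_model(a, b)
  solo_a <- pair_solo_growth(pair, env, "A", tol)
  solo_b <- pair_solo_growth(pair, env, "B", tol)
  la <- solo_a$lambda; lb_ <- solo_b$lambda
  if (is.na(la) || is.na(lb_)) {
    stop("assess_pair: solo growth LP not optimal (status ",
         solo_a$status, "/", solo_b$status, ")")
  }
  tog_a <- solve_pair_growth(pair, env, "A", lb_, tol)
  tog_b <- solve_pair_growth(pair, env, "B", la, tol)
  out <- classify_interaction(c(la, lb_), c(tog_a$lambda, tog_b$lambda), tol)
  out$organism_ids <- pair$organism_ids
  out
}
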