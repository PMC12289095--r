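#' Growth environment: bounds on the extracellular net-change vector
#'
#' An environment is the set of extracellular compounds a microbe (or pair)
#' can draw from, encoded as bounds on the net-change (right-hand-side)
#' vector of the stoichiometric system. A compound is *present* when its
#' lower bound is negative (net uptake allowed); upper bounds cap how much
#' of a compound may accumulate extracellularly (net export). Compounds
#' absent from either map have that bound at zero. Units are
#' mmol gDW^-1 h^-1 throughout.
#'
#' @param lower named numeric vector of lower bounds, all <= 0.
#' @param upper named numeric vector of upper bounds, all >= 0.
#' @return An object of class `growth_env`.
#' @examples
#' growth_env(lower = c(glc = -10), upper = c(glc = 1000, ac = 1000))
#' @export
growth_env <- function(lower = numeric(), upper = numeric()) {
  lower <- unlist(lower); upper <- unlist(upper)
  if (length(lower) && (is.null(names(lower)) || any(!nzchar(names(lower)))))
    stop("growth_env: lower bounds must be named by compound id")
  if (length(upper) && (is.null(names(upper)) || any(!nzchar(names(upper)))))
    stop("growth_env: upper bounds must be named by compound id")
  if (any(lower > 0)) {
    stop("growth_env: positive lower bound for ",
         paste(names(lower)[lower > 0], collapse = ", "))
  }
  if (any(upper < 0)) {
    stop("growth_env: negative upper bound for ",
         paste(names(upper)[upper < 0], collapse = ", "))
  }
  # zero bounds equal the default for unlisted compounds; drop them so
  # environments have a canonical representation
  lower <- lower[lower < 0]
  upper <- upper[upper > 0]
  structure(list(lower = lower, upper = upper), class = "growth_env")
}

#' @export
print.growth_env <- function(x, ...) {
  cat("<growth_env> ", sum(x$lower < 0), " compounds present, ",
      length(x$upper), " with export capacity\n", sep = "")
  invisible(x)
}

#' Compounds present in an environment
#'
#' Present means a strictly negative lower bound (net uptake allowed).
#'
#' @param env a [growth_env()].
#' @return Character vector of compound ids.
#' @export
env_compounds <- function(env) {
  stopifnot(inherits(env, "growth_env"))
  names(env$lower)[env$lower < 0]
}

# bound lookup with 0 default for unlisted compounds
env_lower_for <- function(env, ids) {
  out <- stats::setNames(numeric(length(ids)), ids)
  hit <- intersect(ids, names(env$lower))
  out[hit] <- env$lower[hit]
  out
}

env_upper_for <- function(env, ids) {
  out <- stats::setNames(numeric(length(ids)), ids)
  hit <- intersect(ids, names(env$upper))
  out[hit] <- env$upper[hit]
  out
}

#' Remove a compound from an environment
#'
#' Sets the compound's lower bound to zero (no net uptake). The export
#' (upper) bound is left untouched, so the compound can still be secreted.
#'
#' @param env a [growth_env()].
#' @param compound compound id(s) to remove.
#' @return A new `growth_env`.
#' @export
env_remove <- function(env, compound) {
  lo <- env$lower[setdiff(names(env$lower), compound)]
  growth_env(lower = lo, upper = env$upper)
}

.COMPARTMENTS <- c("extracellular", "cytoplasm", "periplasm")

#' Construct a metabolic model
#'
#' A metabolic model is a stoichiometric matrix (rows = compounds, columns =
#' reactions), flux bounds, a designated biomass reaction whose flux is the
#' growth rate, a compartment label per compound, and a default environment.
#' Exchange is represented only through environment bounds on the
#' extracellular net-change vector; models must not contain exchange
#' reaction columns (see [canonicalize_model()]).
#'
#' @param model_id character scalar.
#' @param S stoichiometric matrix with compound ids as rownames and reaction
#'   ids as colnames (coerced to a sparse `Matrix`).
#' @param lb,ub numeric flux bounds, one per reaction (mmol gDW^-1 h^-1).
#' @param compartment character vector, one of `"extracellular"`,
#'   `"cytoplasm"`, `"periplasm"` per compound. Periplasm is treated as
#'   intracellular by all downstream code.
#' @param biomass_id id of the biomass reaction.
#' @param default_env a [growth_env()] guaranteeing solo growth.
#' @param compound_names optional display names, one per compound.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, S, lb, ub, compartment, biomass_id,
                            default_env = growth_env(),
                            compound_names = NULL) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("metabolic_model: S needs compound rownames and reaction colnames")
  if (anyDuplicated(rownames(S))) stop("metabolic_model: duplicate compound id")
  if (anyDuplicated(colnames(S))) stop("metabolic_model: duplicate reaction id")
  nr <- ncol(S)
  stopifnot(length(lb) == nr, length(ub) == nr,
            length(compartment) == nrow(S))
  if (any(lb > ub)) stop("metabolic_model: flux lower bound exceeds upper bound")
  if (!all(compartment %in% .COMPARTMENTS)) {
    stop("metabolic_model: unknown compartment: ",
         paste(setdiff(compartment, .COMPARTMENTS), collapse = ", "))
  }
  if (!biomass_id %in% colnames(S))
    stop("metabolic_model: biomass reaction '", biomass_id, "' not found")
  stopifnot(inherits(default_env, "growth_env"))
  if (is.null(compound_names)) compound_names <- rownames(S)
  structure(list(
    model_id = model_id,
    S = S,
    lb = stats::setNames(as.numeric(lb), colnames(S)),
    ub = stats::setNames(as.numeric(ub), colnames(S)),
    compartment = stats::setNames(compartment, rownames(S)),
    compound_names = stats::setNames(compound_names, rownames(S)),
    biomass_id = biomass_id,
    default_env = default_env
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$model_id, ": ", nrow(x$S), " compounds (",
      sum(is_extracellular(x)), " extracellular), ", ncol(x$S),
      " reactions, biomass = ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' @keywords internal
is_extracellular <- function(model) {
  model$compartment == "extracellular"
}

#' Build a model from a reaction list
#'
#' Convenience constructor used by the synthetic generator and the SBML
#' reader: reactions are given as sparse stoichiometry maps.
#'
#' @param model_id character scalar.
#' @param compounds data.frame with columns `id`, `compartment` and
#'   optionally `name`.
#' @param reactions named list; each element is a list with `stoich` (named
#'   numeric, compound id -> signed coefficient), `lb`, `ub`.
#' @param biomass_id biomass reaction id.
#' @param default_env a [growth_env()].
#' @return A [metabolic_model()].
#' @export
model_from_reactions <- function(model_id, compounds, reactions, biomass_id,
                                 default_env = growth_env()) {
  stopifnot(is.data.frame(compounds), all(c("id", "compartment") %in% names(compounds)))
  cids <- as.character(compounds$id)
  rids <- names(reactions)
  if (is.null(rids)) stop("model_from_reactions: reactions must be named")
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(cids), length(rids)),
                            dimnames = list(cids, rids))
  S <- as(S, "CsparseMatrix")
  for (r in rids) {
    st <- reactions[[r]]$stoich
    miss <- setdiff(names(st), cids)
    if (length(miss)) {
      stop("model_from_reactions: reaction ", r,
           " references unknown compound ", paste(miss, collapse = ", "))
    }
    S[names(st), r] <- st
  }
  metabolic_model(
    model_id = model_id, S = S,
    lb = vapply(reactions, function(x) x$lb, numeric(1)),
    ub = vapply(reactions, function(x) x$ub, numeric(1)),
    compartment = as.character(compounds$compartment),
    biomass_id = biomass_id,
    default_env = default_env,
    compound_names = if ("name" %in% names(compounds)) as.character(compounds$name) else NULL
  )
}

#' Interaction classification tolerances
#'
#' `eps_class` is the tolerance on growth-rate comparisons (two rates within
#' `eps_class` count as equal, and the partner no-harm floor is
#' `lambda_alone - eps_class`). `eps_grow` is the viability threshold: an
#' organism with growth rate below it counts as unable to grow, both for
#' obligacy subtyping and for deciding whether an environment is viable.
#'
#' @param eps_class dimensionless growth-rate comparison tolerance.
#' @param eps_grow growth-viability threshold.
#' @return An object of class `tolerance_config`.
#' @export
tolerance_config <- function(eps_class = 0.001, eps_grow = 0.1) {
  if (!(eps_class > 0 && eps_class < eps_grow))
    stop("tolerance_config: need 0 < eps_class < eps_grow")
  structure(list(eps_class = eps_class, eps_grow = eps_grow),
            class = "tolerance_config")
}
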