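# In-silico media design for a pair: usable and essential compounds,
# combined default environments, and random fixed-size environments.

#' Sum the default environments of two models
#'
#' The pair's combined default environment takes, per extracellular
#' compound, the sum of the two models' default lower bounds and the sum of
#' their default upper bounds (a compound absent from a default contributes
#' zero). Supplying both defaults guarantees each organism can grow alone.
#'
#' @param a,b [metabolic_model()] objects.
#' @return A [growth_env()].
#' @export
combine_default_environments <- function(a, b) {
  sum_maps <- function(x, y) {
    ids <- union(names(x), names(y))
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(x)] <- out[names(x)] + x
    out[names(y)] <- out[names(y)] + y
    out
  }
  growth_env(lower = sum_maps(a$default_env$lower, b$default_env$lower),
             upper = sum_maps(a$default_env$upper, b$default_env$upper))
}

#' Extracellular compounds usable by a pair
#'
#' A compound is usable when it carries a nonzero stoichiometric
#' coefficient in at least one reaction of the combined matrix, i.e. at
#' least one organism can touch it. Extracellular compounds listed in a
#' model but appearing in no reaction are excluded.
#'
#' @param pair a [build_pair_model()] result.
#' @return Character vector of compound ids.
#' @export
find_usable_compounds <- function(pair) {
  stopifnot(inherits(pair, "pair_model"))
  ext <- pair$compartment == "extracellular"
  touched <- Matrix::rowSums(abs(pair$S[ext, , drop = FALSE])) > 0
  rownames(pair$S)[ext][touched]
}

#' Replete environment for a pair
#'
#' All usable compounds supplied at `-supply`; upper (export) bounds taken
#' from the pair's combined default environment.
#'
#' @param pair a [build_pair_model()] result.
#' @param supply supply magnitude (mmol gDW^-1 h^-1).
#' @return A [growth_env()].
#' @export
replete_environment <- function(pair, supply = 1000) {
  usable <- find_usable_compounds(pair)
  growth_env(lower = stats::setNames(rep(-supply, length(usable)), usable),
             upper = pair$default_env$upper)
}

# both lambda* strictly above eps_grow under directed no-harm solves
joint_viability <- function(pair, env, tol = tolerance_config()) {
  la <- pair_solo_growth(pair, env, "A", tol)$lambda
  lb_ <- pair_solo_growth(pair, env, "B", tol)$lambda
  ta <- solve_pair_growth(pair, env, "A", lb_, tol)$lambda
  tb <- solve_pair_growth(pair, env, "B", la, tol)$lambda
  list(viable = ta > tol$eps_grow && tb > tol$eps_grow,
       lambda_alone = c(la, lb_), lambda_together = c(ta, tb))
}

#' Essential and substitutable compounds for a pair
#'
#' Grows the pair in the replete environment (every usable compound
#' supplied), then removes each usable compound singly and tests whether
#' both organisms can still grow together (both lambda* above `eps_grow`
#' under the directed no-harm solves). A compound whose single removal
#' abolishes joint growth has no possible substitute and is essential.
#'
#' @param pair a [build_pair_model()] result.
#' @param tol a [tolerance_config()].
#' @param supply supply magnitude for the replete screen.
#' @return An object of class `pair_compound_sets` with fields `usable`,
#'   `essential`, `substitutable` and the `replete` environment used.
#' @export
find_essential_compounds <- function(pair, tol = tolerance_config(),
                                     supply = 1000) {
  usable <- find_usable_compounds(pair)
  replete <- replete_environment(pair, supply)
  if (!joint_viability(pair, replete, tol)$viable) {
    stop("find_essential_compounds: pair cannot grow together even in the ",
         "replete environment")
  }
  essential <- usable[vapply(usable, function(k) {
    !joint_viability(pair, env_remove(replete, k), tol)$viable
  }, logical(1))]
  structure(list(usable = usable,
                 essential = essential,
                 substitutable = setdiff(usable, essential),
                 supply = supply,
                 replete = replete),
            class = "pair_compound_sets")
}

#' @export
print.pair_compound_sets <- function(x, ...) {
  cat("<pair_compound_sets> ", length(x$usable), " usable, ",
      length(x$essential), " essential, ", length(x$substitutable),
      " substitutable\n", sep = "")
  invisible(x)
}

#' Generate a random fixed-size environment for a pair
#'
#' The environment contains all essential compounds plus `n_additional`
#' substitutable compounds sampled uniformly without replacement. Every
#' present compound is supplied at `-supply`; upper (export) bounds are
#' taken from `defaults` (the pair's combined default environment), zero
#' where absent. Randomness comes from R's RNG stream, so callers seed with
#' `set.seed()` for reproducibility.
#'
#' @param sets a [find_essential_compounds()] result.
#' @param n_additional number of substitutable compounds to add.
#' @param supply supply magnitude (mmol gDW^-1 h^-1).
#' @param defaults a [growth_env()] providing the upper bounds.
#' @return A [growth_env()].
#' @export
generate_random_environment <- function(sets, n_additional, supply = 1000,
                                        defaults) {
  stopifnot(inherits(sets, "pair_compound_sets"))
  if (n_additional > length(sets$substitutable)) {
    stop("generate_random_environment: n_additional (", n_additional,
         ") exceeds the ", length(sets$substitutable),
         " substitutable compounds")
  }
  extra <- if (n_additional > 0) {
    sample(sets$substitutable, n_additional, replace = FALSE)
  } else character()
  present <- c(sets$essential, extra)
  growth_env(lower = stats::setNames(rep(-supply, length(present)), present),
             upper = defaults$upper)
}
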