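# Synthetic toy metabolisms with designed, hand-checkable interaction
# topologies. These stand in for genome-scale model collections so that
# every pipeline stage is testable offline; they are deliberately minimal
# (single linear pathways, unit yields, supply -10 so optima are small
# integers) and are labelled synthetic throughout.

.toy <- function(id, compounds, reactions, biomass, env_lower, env_upper) {
  model_from_reactions(
    model_id = id,
    compounds = compounds,
    reactions = reactions,
    biomass_id = biomass,
    default_env = growth_env(lower = env_lower, upper = env_upper)
  )
}

.cmp <- function(ids, compartments) data.frame(id = ids, compartment = compartments)

# single-substrate consumer: transport X then burn it for biomass
.consumer <- function(id, resource = "X") {
  rc <- paste0(resource, "_c")
  .toy(id,
       .cmp(c(resource, rc), c("extracellular", "cytoplasm")),
       stats::setNames(list(
         list(stoich = stats::setNames(c(-1, 1), c(resource, rc)), lb = 0, ub = 1000),
         list(stoich = stats::setNames(-1, rc), lb = 0, ub = 1000)
       ), c(paste0("TXP_", resource), "BIOMASS")),
       "BIOMASS",
       env_lower = stats::setNames(-10, resource),
       env_upper = stats::setNames(1000, resource))
}

# resource-with-byproduct organism: private substrate R catabolized to a
# biomass precursor while co-secreting `out`; can also catabolize `inn`
.crossfeeder <- function(id, resource, out, inn) {
  rc <- paste0(resource, "_c"); ic <- paste0(inn, "_c")
  .toy(id,
       .cmp(c(resource, out, inn, rc, ic, "P_c"),
            c("extracellular", "extracellular", "extracellular",
              "cytoplasm", "cytoplasm", "cytoplasm")),
       stats::setNames(list(
         list(stoich = stats::setNames(c(-1, 1), c(resource, rc)), lb = 0, ub = 1000),
         list(stoich = stats::setNames(c(-1, 1, 1), c(rc, "P_c", out)), lb = 0, ub = 1000),
         list(stoich = stats::setNames(c(-1, 1), c(inn, ic)), lb = 0, ub = 1000),
         list(stoich = stats::setNames(c(-1, 1), c(ic, "P_c")), lb = 0, ub = 1000),
         list(stoich = c(P_c = -1), lb = 0, ub = 1000)
       ), c(paste0("TXP_", resource), paste0("CAT_", resource),
            paste0("TXP_", inn), paste0("CAT_", inn), "BIOMASS")),
       "BIOMASS",
       env_lower = stats::setNames(-10, resource),
       env_upper = stats::setNames(c(1000, 1000, 1000), c(resource, out, inn)))
}

#' Construct a named synthetic fixture
#'
#' Deterministic toy metabolisms whose interaction label is known by
#' construction:
#' * `CONS` — a single organism consuming one substrate X (used for
#'   individual-growth checks; no pair, no ground-truth label).
#' * `COMP` — two single-substrate consumers of shared X; in `{X: -10}`
#'   each grows at 10 alone but the no-harm floor leaves the focal organism
#'   only the classification tolerance, so the pair is `COMPETITIVE`.
#' * `FAC` — private substrates X (A) and V (B); A's X-catabolism secretes
#'   Y which B can burn, B's V-catabolism secretes Z which A can burn; in
#'   `{X: -10, V: -10}` each grows at 10 alone and 20 together
#'   (`FACULTATIVE_COOP`).
#' * `OBL1` — A grows on X and secretes Y; B needs Y and secretes Z which A
#'   can additionally burn; in `{X: -10}` B cannot grow alone
#'   (`ONEWAY_OBLIGATE`, lambda* = (20, 10)).
#' * `OBL2` — A's biomass consumes X and Z and produces Y; B's consumes V
#'   and Y and produces Z; in `{X: -10, V: -10}` neither grows alone and
#'   both grow at 10 together (`TWOWAY_OBLIGATE`).
#' * `DISJOINT` — private substrates, no secretion links (`NEUTRAL`).
#'
#' The fixture environment's upper bounds come from the pair's combined
#' default environment.
#'
#' @param name one of `"CONS"`, `"COMP"`, `"FAC"`, `"OBL1"`, `"OBL2"`,
#'   `"DISJOINT"`.
#' @return An object of class `synthetic_pair_spec` with fields `name`,
#'   `models` (list of 1 or 2 [metabolic_model()]s), `env`, `ground_truth`
#'   (interaction label, `NA` for `CONS`) and `notes`.
#' @export
make_fixture <- function(name) {
  name <- match.arg(name, c("CONS", "COMP", "FAC", "OBL1", "OBL2", "DISJOINT"))
  env_for <- function(models, lower) {
    defaults <- if (length(models) == 2) {
      combine_default_environments(models[[1]], models[[2]])
    } else models[[1]]$default_env
    growth_env(lower = lower, upper = defaults$upper)
  }
  out <- switch(name,
    CONS = {
      m <- list(.consumer("cons"))
      list(models = m, env = env_for(m, c(X = -10)), truth = NA_character_,
           notes = "single substrate consumer, lambda = 10 in {X: -10}")
    },
    COMP = {
      m <- list(.consumer("compA"), .consumer("compB"))
      list(models = m, env = env_for(m, c(X = -10)), truth = "COMPETITIVE",
           notes = "shared single substrate; no-harm floor leaves the focal organism ~eps_class")
    },
    FAC = {
      m <- list(.crossfeeder("facA", "X", out = "Y", inn = "Z"),
                .crossfeeder("facB", "V", out = "Z", inn = "Y"))
      list(models = m, env = env_for(m, c(X = -10, V = -10)),
           truth = "FACULTATIVE_COOP",
           notes = "reciprocal byproduct cross-feeding on private substrates")
    },
    OBL1 = {
      b <- .toy("obl1B",
                .cmp(c("Y", "Z", "Y_c", "Q_c"),
                     c("extracellular", "extracellular", "cytoplasm", "cytoplasm")),
                list(TXP_Y = list(stoich = c(Y = -1, Y_c = 1), lb = 0, ub = 1000),
                     CAT_Y = list(stoich = c(Y_c = -1, Q_c = 1, Z = 1), lb = 0, ub = 1000),
                     BIOMASS = list(stoich = c(Q_c = -1), lb = 0, ub = 1000)),
                "BIOMASS",
                env_lower = c(Y = -10), env_upper = c(Y = 1000, Z = 1000))
      m <- list(.crossfeeder("obl1A", "X", out = "Y", inn = "Z"), b)
      list(models = m, env = env_for(m, c(X = -10)), truth = "ONEWAY_OBLIGATE",
           notes = "B depends on A's byproduct Y; A additionally burns B's byproduct Z")
    },
    OBL2 = {
      a <- .toy("obl2A",
                .cmp(c("X", "Z", "Y", "X_c", "Z_c"),
                     c("extracellular", "extracellular", "extracellular",
                       "cytoplasm", "cytoplasm")),
                list(TXP_X = list(stoich = c(X = -1, X_c = 1), lb = 0, ub = 1000),
                     TXP_Z = list(stoich = c(Z = -1, Z_c = 1), lb = 0, ub = 1000),
                     BIOMASS = list(stoich = c(X_c = -1, Z_c = -1, Y = 1), lb = 0, ub = 1000)),
                "BIOMASS",
                env_lower = c(X = -10, Z = -10),
                env_upper = c(X = 1000, Y = 1000, Z = 1000))
      b <- .toy("obl2B",
                .cmp(c("V", "Y", "Z", "V_c", "Y_c"),
                     c("extracellular", "extracellular", "extracellular",
                       "cytoplasm", "cytoplasm")),
                list(TXP_V = list(stoich = c(V = -1, V_c = 1), lb = 0, ub = 1000),
                     TXP_Y = list(stoich = c(Y = -1, Y_c = 1), lb = 0, ub = 1000),
                     BIOMASS = list(stoich = c(V_c = -1, Y_c = -1, Z = 1), lb = 0, ub = 1000)),
                "BIOMASS",
                env_lower = c(V = -10, Y = -10),
                env_upper = c(V = 1000, Y = 1000, Z = 1000))
      m <- list(a, b)
      list(models = m, env = env_for(m, c(X = -10, V = -10)),
           truth = "TWOWAY_OBLIGATE",
           notes = "mutually obligate biomass coupling through Y and Z")
    },
    DISJOINT = {
      m <- list(.consumer("disA", "X"), .consumer("disB", "W"))
      list(models = m, env = env_for(m, c(X = -10, W = -10)), truth = "NEUTRAL",
           notes = "private substrates, no secretion links")
    })
  structure(list(name = name, models = out$models, env = out$env,
                 ground_truth = out$truth, notes = out$notes),
            class = "synthetic_pair_spec")
}

#' @export
print.synthetic_pair_spec <- function(x, ...) {
  cat("<synthetic_pair_spec> ", x$name, " (", length(x$models),
      " model(s), ground truth ", x$ground_truth, ")\n  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Random toy metabolism pair
#'
#' Builds two linear-pathway metabolisms over a shared extracellular
#' namespace for property testing. Each organism gets `n_private` private
#' resources plus `n_shared` resources both can use; every resource feeds a
#' transport step and a catabolism chain of length `depth` into a biomass
#' precursor, with `yield` units of precursor per unit resource.
#' `n_crossfeed` links add byproduct secretion (co-produced with the first
#' catabolic step of a randomly chosen resource of the donor) consumed by
#' the partner through its own transport + catabolism chain; link direction
#' is random. Ground-truth labels are intentionally not assigned: these
#' pairs exercise invariants, not label expectations.
#'
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @param n_private private resources per organism.
#' @param n_shared resources usable by both.
#' @param n_crossfeed number of byproduct links.
#' @param depth catabolism chain length (>= 1).
#' @param yield precursor units per resource unit (> 0).
#' @param supply default-environment supply magnitude.
#' @return A `synthetic_pair_spec` whose `env` is the pair's combined
#'   default environment and whose `ground_truth` is `NA`.
#' @export
random_toy_pair <- function(seed = NULL, n_private = 1, n_shared = 1,
                            n_crossfeed = 1, depth = 1, yield = 1,
                            supply = 10) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_private >= 0, n_shared >= 0, n_crossfeed >= 0,
            depth >= 1, yield > 0)
  if (n_private == 0 && n_shared == 0) {
    stop("random_toy_pair: no resources at all; the models would be degenerate")
  }
  shared <- if (n_shared) paste0("S", seq_len(n_shared)) else character()
  priv <- list(A = if (n_private) paste0("PA", seq_len(n_private)) else character(),
               B = if (n_private) paste0("PB", seq_len(n_private)) else character())
  # crossfeed links: donor secretes byproduct C<k>, receiver burns it
  links <- lapply(seq_len(n_crossfeed), function(k) {
    donor <- sample(c("A", "B"), 1)
    list(donor = donor, receiver = setdiff(c("A", "B"), donor),
         compound = paste0("C", k))
  })

  build_org <- function(org) {
    resources <- c(priv[[org]], shared)
    secreted <- vapply(Filter(function(l) l$donor == org, links),
                       function(l) l$compound, character(1))
    consumed <- vapply(Filter(function(l) l$receiver == org, links),
                       function(l) l$compound, character(1))
    # which resource co-secretes each byproduct
    secrete_via <- if (length(secreted)) {
      stats::setNames(sample(resources, length(secreted), replace = TRUE), secreted)
    } else stats::setNames(character(), character())

    cmps <- data.frame(id = "P_c", compartment = "cytoplasm")
    # reaction capacity far above any feasible nutrient throughput: in the
    # toy networks the environment, never the enzyme cap, must be limiting
    cap <- 1e6
    rxns <- list(BIOMASS = list(stoich = c(P_c = -1), lb = 0, ub = cap))
    add_chain <- function(res, byproducts) {
      ids <- c(paste0(res, "_c"),
               if (depth > 1) paste0(res, "_i", seq_len(depth - 1)))
      cmps <<- rbind(cmps,
                     data.frame(id = c(res, ids),
                                compartment = c("extracellular",
                                                rep("cytoplasm", length(ids)))))
      rxns[[paste0("TXP_", res)]] <<- list(
        stoich = stats::setNames(c(-1, 1), c(res, ids[1])), lb = 0, ub = cap)
      chain <- c(ids, "P_c")
      for (s in seq_len(depth)) {
        st <- stats::setNames(c(-1, if (s == depth) yield else 1),
                              c(chain[s], chain[s + 1]))
        if (s == 1 && length(byproducts)) {
          st <- c(st, stats::setNames(rep(1, length(byproducts)), byproducts))
          cmps <<- rbind(cmps, data.frame(id = byproducts,
                                          compartment = "extracellular"))
        }
        rxns[[paste0("CAT_", res, "_", s)]] <<- list(stoich = st, lb = 0, ub = cap)
      }
    }
    for (res in resources) {
      add_chain(res, names(secrete_via)[secrete_via == res])
    }
    for (cc in consumed) add_chain(cc, character())
    cmps <- cmps[!duplicated(cmps$id), ]
    ext <- cmps$id[cmps$compartment == "extracellular"]
    model_from_reactions(
      model_id = paste0("toy", org),
      compounds = cmps, reactions = rxns, biomass_id = "BIOMASS",
      default_env = growth_env(
        lower = stats::setNames(rep(-supply, length(resources)), resources),
        upper = stats::setNames(rep(cap, length(ext)), ext)))
  }

  models <- list(build_org("A"), build_org("B"))
  structure(list(name = "RANDOM", models = models,
                 env = combine_default_environments(models[[1]], models[[2]]),
                 ground_truth = NA_character_,
                 notes = sprintf("random toy pair (%d private, %d shared, %d links, depth %d, yield %g)",
                                 n_private, n_shared, n_crossfeed, depth, yield)),
            class = "synthetic_pair_spec")
}
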