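# Cross-environment statistics: Jaccard distances, compound-appearance
# bias against a random-assignment null, switch frequencies against an
# equal-likelihood null, and metabolic-complexity terciles.

#' Jaccard distance between two compound sets
#'
#' `1 - |A intersect B| / |A union B|`; the distance between two empty
#' sets is defined as 0.
#'
#' @param a,b character vectors of compound ids (treated as sets).
#' @return Numeric distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Compound-appearance bias between competitive and cooperative environments
#'
#' For each compound appearing in at least one environment: its share of
#' competitive appearances versus the global competitive share, with a
#' p-value under the null that environment labels are assigned
#' independently at random with probability equal to the global share.
#' The default is the exact two-sided binomial test; `method =
#' "montecarlo"` instead resamples labels `n_null` times.
#'
#' @param env_sets list of character vectors (compound sets, one per
#'   environment).
#' @param labels character vector, `"competitive"` or `"cooperative"`, one
#'   per environment (cooperative includes all cooperation subtypes).
#' @param method `"binomial"` (exact, default) or `"montecarlo"`.
#' @param n_null Monte-Carlo resamples when `method = "montecarlo"`.
#' @return A data.frame with columns `compound`, `n_competitive`,
#'   `n_cooperative`, `share_competitive`, `bias` (share minus global
#'   share), `p_value`, `p_adj_bh`.
#' @export
compound_bias <- function(env_sets, labels, method = c("binomial", "montecarlo"),
                          n_null = 10000) {
  method <- match.arg(method)
  stopifnot(length(env_sets) == length(labels),
            all(labels %in% c("competitive", "cooperative")))
  if (length(unique(labels)) < 2) {
    stop("compound_bias: need at least one environment of each label")
  }
  is_comp <- labels == "competitive"
  p_global <- mean(is_comp)
  compounds <- sort(unique(unlist(env_sets)))
  appears <- vapply(compounds, function(k) {
    vapply(env_sets, function(e) k %in% e, logical(1))
  }, logical(length(env_sets)))
  n_k <- colSums(appears)
  x_k <- colSums(appears & is_comp)
  p_value <- if (method == "binomial") {
    vapply(seq_along(compounds), function(i) {
      stats::binom.test(x_k[i], n_k[i], p_global)$p.value
    }, numeric(1))
  } else {
    null_x <- matrix(0L, n_null, length(compounds))
    for (r in seq_len(n_null)) {
      lab <- stats::runif(length(env_sets)) < p_global
      null_x[r, ] <- colSums(appears & lab)
    }
    vapply(seq_along(compounds), function(i) {
      dev <- abs(null_x[, i] - n_k[i] * p_global)
      obs <- abs(x_k[i] - n_k[i] * p_global)
      (1 + sum(dev >= obs - 1e-12)) / (1 + n_null)
    }, numeric(1))
  }
  out <- data.frame(compound = compounds,
                    n_competitive = as.integer(x_k),
                    n_cooperative = as.integer(n_k - x_k),
                    share_competitive = x_k / n_k,
                    bias = x_k / n_k - p_global,
                    p_value = p_value,
                    stringsAsFactors = FALSE)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-compound switch frequency with an equal-likelihood null
#'
#' Given single-removal scans over many environments, counts how often
#' removing each compound produced a given transition class, against the
#' null expectation that every removable compound in an environment was
#' equally likely to have caused that environment's switches. Significance
#' comes from Monte-Carlo reassignment: in each resample, each
#' environment's switches are reassigned to a uniform random subset of its
#' removable compounds.
#'
#' @param scans list of scan records; each has `removable` (character
#'   vector) and `outcomes` (a [single_removal_scan()] data.frame).
#' @param transition a transition class (see [transition_class()]).
#' @param n_null Monte-Carlo resamples (0 skips p-values).
#' @return A data.frame with columns `compound`, `observed`, `expected`,
#'   `p_value` (upper tail, observed >= null).
#' @export
switch_frequency <- function(scans, transition, n_null = 1000) {
  stopifnot(length(scans) > 0)
  compounds <- sort(unique(unlist(lapply(scans, `[[`, "removable"))))
  observed <- stats::setNames(numeric(length(compounds)), compounds)
  expected <- observed
  causes <- lapply(scans, function(sc) {
    hit <- sc$outcomes$compound[sc$outcomes$transition == transition]
    s_e <- length(hit)
    if (s_e > 0) {
      observed[hit] <<- observed[hit] + 1
      expected[sc$removable] <<- expected[sc$removable] +
        s_e / length(sc$removable)
    }
    s_e
  })
  p_value <- rep(NA_real_, length(compounds))
  if (n_null > 0) {
    exceed <- stats::setNames(numeric(length(compounds)), compounds)
    for (r in seq_len(n_null)) {
      null_obs <- stats::setNames(numeric(length(compounds)), compounds)
      for (i in seq_along(scans)) {
        s_e <- causes[[i]]
        if (s_e > 0) {
          pick <- sample(scans[[i]]$removable, s_e, replace = FALSE)
          null_obs[pick] <- null_obs[pick] + 1
        }
      }
      exceed <- exceed + (null_obs >= observed - 1e-12)
    }
    p_value <- (1 + exceed) / (1 + n_null)
  }
  data.frame(compound = compounds, observed = as.numeric(observed),
             expected = as.numeric(expected), p_value = as.numeric(p_value),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Metabolic-complexity terciles
#'
#' Scores each model by a complexity metric (number of usable
#' extracellular metabolites, or number of reactions) and assigns
#' low/medium/high categories at the 33.3rd and 66.7th percentiles.
#' Boundary ties all fall on the lower category, which makes assignment
#' deterministic (models with identical metrics always share a category).
#'
#' @param models list of [metabolic_model()] objects (at least 3).
#' @param metric `"n_usable_metabolites"` or `"n_reactions"`.
#' @return A data.frame with columns `model_id`, `metric`, `value`,
#'   `category`.
#' @export
complexity_terciles <- function(models,
                                metric = c("n_usable_metabolites", "n_reactions")) {
  metric <- match.arg(metric)
  stopifnot(length(models) >= 3)
  value <- vapply(models, function(m) {
    if (metric == "n_reactions") return(ncol(m$S))
    ext <- is_extracellular(m)
    sum(Matrix::rowSums(abs(m$S[ext, , drop = FALSE])) > 0)
  }, numeric(1))
  q <- stats::quantile(value, c(1, 2) / 3, names = FALSE)
  category <- ifelse(value <= q[1], "low",
                     ifelse(value <= q[2], "medium", "high"))
  data.frame(model_id = vapply(models, `[[`, character(1), "model_id"),
             metric = metric, value = value, category = category,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate pair complexity categories
#'
#' Labels each pair by the unordered combination of its two models'
#' complexity categories (low-low, low-medium, ..., high-high).
#'
#' @param categories a [complexity_terciles()] result.
#' @param pairs data.frame (or 2-column matrix) of model id pairs.
#' @return The input pairs with a `pair_category` column.
#' @export
complexity_pair_table <- function(categories, pairs) {
  pairs <- as.data.frame(pairs)
  lookup <- stats::setNames(categories$category, categories$model_id)
  lv <- c("low", "medium", "high")
  pair_category <- apply(pairs, 1, function(p) {
    cats <- lookup[as.character(p)]
    if (any(is.na(cats))) stop("complexity_pair_table: unknown model id")
    paste(lv[sort(match(cats, lv))], collapse = "-")
  })
  cbind(pairs, pair_category = pair_category)
}
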