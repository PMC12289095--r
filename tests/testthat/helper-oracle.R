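# Independent growth-rate oracle.
#
# Assembles each flux balance program from scratch (its own constraint
# layout over raw fluxes, no variable shifting) and solves batches with
# scipy's HiGHS via the lp-oracle.py helper -- an entirely different
# solver backend from the boot-based simplex inside the package. Used to
# cross-check individual and no-harm pair growth rates.

.oracle_big <- 1e30

# build one LP (maximize biomass of models[[focal]]) as a plain list
oracle_build_lp <- function(models, env, focal = 1, floor_partner = NULL,
                            eps_class = 0.001) {
  nv <- 0L
  lb <- c(); ub <- c(); biomass_col <- integer(length(models))
  col_of <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    col_of[[k]] <- stats::setNames(nv + seq_len(ncol(m$S)), colnames(m$S))
    biomass_col[k] <- col_of[[k]][[m$biomass_id]]
    lb <- c(lb, unname(m$lb)); ub <- c(ub, unname(m$ub))
    nv <- nv + ncol(m$S)
  }
  row_for <- function(k, cid) {
    r <- numeric(nv)
    m <- models[[k]]
    if (cid %in% rownames(m$S)) r[col_of[[k]]] <- as.numeric(m$S[cid, ])
    r
  }
  rows <- NULL; rl <- c(); ru <- c()
  for (k in seq_along(models)) {
    m <- models[[k]]
    for (cid in rownames(m$S)[m$compartment != "extracellular"]) {
      rows <- rbind(rows, row_for(k, cid)); rl <- c(rl, 0); ru <- c(ru, 0)
    }
  }
  ext_ids <- sort(unique(unlist(lapply(models, function(m)
    rownames(m$S)[m$compartment == "extracellular"]))))
  for (cid in ext_ids) {
    r <- Reduce(`+`, lapply(seq_along(models), function(k) row_for(k, cid)))
    rows <- rbind(rows, r)
    rl <- c(rl, if (cid %in% names(env$lower)) env$lower[[cid]] else 0)
    ru <- c(ru, if (cid %in% names(env$upper)) env$upper[[cid]] else 0)
  }
  if (!is.null(floor_partner)) {
    partner <- setdiff(seq_along(models), focal)
    r <- numeric(nv); r[biomass_col[partner]] <- 1
    rows <- rbind(rows, r)
    rl <- c(rl, max(0, floor_partner - eps_class)); ru <- c(ru, .oracle_big)
  }
  obj <- numeric(nv); obj[biomass_col[focal]] <- 1
  list(obj = obj, rows = as.numeric(t(rows)), rl = rl, ru = ru,
       lb = pmax(lb, -.oracle_big), ub = pmin(ub, .oracle_big))
}

# solve a list of LPs in one python call; returns objectives (NA if not optimal)
oracle_lp_batch <- function(problems) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(problems, fin, auto_unbox = FALSE, digits = NA)
  script <- if (file.exists("lp-oracle.py")) "lp-oracle.py" else {
    testthat::test_path("lp-oracle.py")
  }
  status <- system2("python", c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  vapply(res, function(r) {
    if (identical(r$status, "optimal")) as.numeric(r$objective) else NA_real_
  }, numeric(1))
}

# four-rate oracle assessments for a list of cases (each: list(a, b, env));
# two batched python calls (solo rates first, then floored pair solves)
oracle_assess_many <- function(cases, eps_class = 0.001) {
  solo <- list()
  for (cs in cases) {
    solo <- c(solo, list(oracle_build_lp(list(cs$a), cs$env),
                         oracle_build_lp(list(cs$b), cs$env)))
  }
  solo_rates <- oracle_lp_batch(solo)
  paired <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    la <- solo_rates[2 * i - 1]; lb_ <- solo_rates[2 * i]
    paired <- c(paired, list(
      oracle_build_lp(list(cs$a, cs$b), cs$env, focal = 1,
                      floor_partner = lb_, eps_class = eps_class),
      oracle_build_lp(list(cs$a, cs$b), cs$env, focal = 2,
                      floor_partner = la, eps_class = eps_class)))
  }
  pair_rates <- oracle_lp_batch(paired)
  t(vapply(seq_along(cases), function(i) {
    c(alone_a = solo_rates[2 * i - 1], alone_b = solo_rates[2 * i],
      together_a = pair_rates[2 * i - 1], together_b = pair_rates[2 * i])
  }, numeric(4)))
}

oracle_assess <- function(a, b, env, eps_class = 0.001) {
  oracle_assess_many(list(list(a = a, b = b, env = env)), eps_class)[1, ]
}
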