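# Single-removal scans, used-compound reduction, and environment
# degradation.

fac_env4 <- function(pair) {
  growth_env(lower = c(X = -10, V = -10, Y = -10, Z = -10),
             upper = pair$default_env$upper)
}

test_that("transition classes bucket label changes by destination", {
  expect_identical(transition_class("COMPETITIVE", "COMPETITIVE"), "same")
  expect_identical(transition_class("COMPETITIVE", "FACULTATIVE_COOP"),
                   "to_facultative")
  expect_identical(transition_class("FACULTATIVE_COOP", "COMPETITIVE"),
                   "to_competitive")
  for (obl in c("ONEWAY_OBLIGATE", "TWOWAY_OBLIGATE", "OBLIGATE_COMMENSAL")) {
    expect_identical(transition_class("FACULTATIVE_COOP", obl), "to_obligate")
  }
  expect_identical(transition_class("COMPETITIVE", "NO_GROWTH"), "to_no_growth")
  expect_identical(transition_class("FACULTATIVE_COOP", "NEUTRAL"), "to_other")
})

test_that("single removals reclassify independently from the full environment", {
  fc <- fixture_pair("FAC")
  sets <- find_essential_compounds(fc$pair)
  # in {X, V}: removing V strands B on A's byproduct (obligate commensal),
  # removing X symmetrically strands A
  scan <- single_removal_scan(fc$pair, fc$fx$env, sets)
  expect_setequal(scan$compound, c("X", "V"))
  expect_true(all(scan$label_before == "FACULTATIVE_COOP"))
  expect_identical(scan$label_after[scan$compound == "V"], "OBLIGATE_COMMENSAL")
  expect_identical(scan$transition[scan$compound == "V"], "to_obligate")
  # essential compounds never appear in the outcome list
  ob <- fixture_pair("OBL2")
  sets_ob <- find_essential_compounds(ob$pair)
  env4 <- growth_env(lower = c(X = -10, V = -10, Y = -10, Z = -10),
                     upper = ob$pair$default_env$upper)
  scan_ob <- single_removal_scan(ob$pair, env4, sets_ob)
  expect_setequal(scan_ob$compound, c("Y", "Z"))
  # an unused compound's removal is always "same"
  fc_env_u <- growth_env(lower = c(X = -10, V = -10, U = -10),
                         upper = c(fc$pair$default_env$upper, U = 5))
  scan_u <- single_removal_scan(fc$pair, fc_env_u, sets)
  expect_identical(scan_u$transition[scan_u$compound == "U"], "same")
})

test_that("reduction keeps used and essential compounds and preserves the label", {
  fc <- fixture_pair("FAC")
  sets <- find_essential_compounds(fc$pair)
  env_u <- growth_env(lower = c(X = -10, V = -10, U = -10),
                      upper = c(fc$pair$default_env$upper, U = 5))
  red <- reduce_to_used_compounds(fc$pair, env_u, sets)
  expect_setequal(env_compounds(red), c("X", "V"))
  expect_identical(assess_pair(fc$pair, env = red)$label, "FACULTATIVE_COOP")
  # an environment where everything is imported is unchanged
  ob <- fixture_pair("OBL2")
  sets_ob <- find_essential_compounds(ob$pair)
  red_ob <- reduce_to_used_compounds(ob$pair, ob$fx$env, sets_ob)
  expect_setequal(env_compounds(red_ob), c("X", "V"))
  # reduced classification equals the original on all viable fixtures
  for (name in c("FAC", "OBL1", "OBL2", "DISJOINT")) {
    fp <- fixture_pair(name)
    sets_f <- find_essential_compounds(fp$pair)
    before <- assess_pair(fp$pair, env = fp$fx$env)$label
    red_f <- reduce_to_used_compounds(fp$pair, fp$fx$env, sets_f)
    expect_identical(assess_pair(fp$pair, env = red_f)$label, before,
                     label = paste("reduction preserves label for", name))
  }
})

test_that("a fixed degradation ordering walks the derived label sequence", {
  fc <- fixture_pair("FAC")
  path <- degrade_ordering(fc$pair, fac_env4(fc$pair), c("Y", "Z", "V", "X"))
  expect_identical(path$labels,
                   c("FACULTATIVE_COOP", "FACULTATIVE_COOP", "FACULTATIVE_COOP",
                     "OBLIGATE_COMMENSAL", "NO_GROWTH"))
  expect_identical(path$terminal_reason, "no_growth")
  expect_identical(path$removal_order, c("Y", "Z", "V", "X"))
})

test_that("an essential-only environment yields zero-length paths", {
  ob <- fixture_pair("OBL2")
  sets <- find_essential_compounds(ob$pair)
  paths <- degrade_environment(ob$pair, ob$fx$env, sets, n_orderings = 5,
                               seed = 1)
  expect_length(paths, 5)
  for (p in paths) {
    expect_length(p$removal_order, 0)
    expect_identical(p$labels, "TWOWAY_OBLIGATE")
    expect_identical(p$terminal_reason, "exhausted")
  }
})

test_that("degradation paths satisfy their structural invariants", {
  fc <- fixture_pair("FAC")
  sets <- find_essential_compounds(fc$pair)
  paths <- degrade_environment(fc$pair, fac_env4(fc$pair), sets,
                               n_orderings = 50, seed = 7)
  expect_length(paths, 50)
  for (p in paths) {
    expect_length(p$labels, length(p$removal_order) + 1)
    expect_length(intersect(p$removal_order, sets$essential), 0)
    terminal <- p$labels[length(p$labels)]
    expect_identical(terminal == "NO_GROWTH", p$terminal_reason == "no_growth")
  }
  # same seed, bit-identical paths
  paths2 <- degrade_environment(fc$pair, fac_env4(fc$pair), sets,
                                n_orderings = 50, seed = 7)
  expect_identical(lapply(paths, `[[`, "removal_order"),
                   lapply(paths2, `[[`, "removal_order"))
  expect_identical(lapply(paths, `[[`, "labels"),
                   lapply(paths2, `[[`, "labels"))
})

test_that("solo growth only shrinks as compounds are removed", {
  set.seed(303)
  for (i in 1:10) {
    sp <- draw_random_pair()
    pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
    env <- sp$env
    ordering <- sample(env_compounds(env))
    prev <- c(pairfba:::pair_solo_growth(pair, env, "A")$lambda,
              pairfba:::pair_solo_growth(pair, env, "B")$lambda)
    for (k in ordering) {
      env <- env_remove(env, k)
      cur <- c(pairfba:::pair_solo_growth(pair, env, "A")$lambda,
               pairfba:::pair_solo_growth(pair, env, "B")$lambda)
      expect_true(all(cur <= prev + 1e-6))
      prev <- cur
    }
  }
})

test_that("path summaries count first changes and collapse sequences", {
  mk_path <- function(labels, nrem = length(labels) - 1) {
    structure(list(pair_ids = c(A = "a", B = "b"),
                   removal_order = paste0("k", seq_len(nrem)),
                   labels = labels,
                   terminal_reason = if (labels[length(labels)] == "NO_GROWTH")
                     "no_growth" else "exhausted"),
              class = "degradation_path")
  }
  paths <- list(
    mk_path(c("COMPETITIVE", "COMPETITIVE", "FACULTATIVE_COOP", "NO_GROWTH")),
    mk_path(c("COMPETITIVE", "FACULTATIVE_COOP", "NO_GROWTH")),
    mk_path(c("COMPETITIVE", "FACULTATIVE_COOP", "NO_GROWTH")))
  s <- summarize_paths(paths)
  expect_equal(nrow(s$sequences), 1)
  expect_identical(s$sequences$sequence,
                   "COMPETITIVE>FACULTATIVE_COOP>NO_GROWTH")
  expect_equal(s$sequences$proportion, 1)
  expect_equal(s$paths$first_change, c(2, 1, 1))
  expect_false(any(s$paths$censored))
  # last label before no growth was facultative in all three paths
  expect_equal(s$share_obligate_before_no_growth, 0)

  mixed <- list(
    mk_path(c("COMPETITIVE", "ONEWAY_OBLIGATE", "NO_GROWTH")),
    mk_path(c("COMPETITIVE", "FACULTATIVE_COOP", "NO_GROWTH")))
  expect_equal(summarize_paths(mixed)$share_obligate_before_no_growth, 0.5)

  # a path with no label change is censored at its full length
  censored <- summarize_paths(list(mk_path(rep("NEUTRAL", 4), nrem = 3)))
  expect_true(censored$paths$censored)
  expect_equal(censored$paths$first_change, 3)
})
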