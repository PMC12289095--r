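# Individual and coupled-pair growth programs and interaction
# classification.

test_that("individual growth solves the single-consumer program", {
  cons <- make_fixture("CONS")
  m <- cons$models[[1]]
  # supply 10 of the sole substrate -> growth 10
  r <- solve_individual_growth(m, cons$env)
  expect_identical(r$status, "optimal")
  expect_equal(r$lambda, 10, tolerance = 1e-9)
  expect_equal(unname(r$env_net["X"]), -10, tolerance = 1e-9)
  # nothing supplied -> zero flux is the only feasible point
  r0 <- solve_individual_growth(m, growth_env())
  expect_identical(r0$status, "no_growth")
  expect_equal(r0$lambda, 0)
  # a forced biomass flux without substrate is infeasible
  forced <- m; forced$lb["BIOMASS"] <- 1
  rf <- solve_individual_growth(forced, growth_env())
  expect_identical(rf$status, "infeasible")
  expect_true(is.na(rf$lambda))
})

test_that("pair models have shared extracellular and private intracellular rows", {
  cp <- fixture_pair("COMP")
  expect_equal(sum(cp$pair$compartment == "extracellular"), 1)
  expect_equal(nrow(cp$pair$S), 3)
  expect_equal(ncol(cp$pair$S), 4)
  # disjoint extracellular sets: union, no merged rows
  dj <- fixture_pair("DISJOINT")
  expect_setequal(rownames(dj$pair$S)[dj$pair$compartment == "extracellular"],
                  c("X", "W"))
  # self-pair: shared extracellular row, duplicated qualified intracellular rows
  m <- make_fixture("CONS")$models[[1]]
  self <- build_pair_model(m, m)
  expect_equal(sum(self$compartment == "extracellular"), 1)
  expect_true(all(c("A#X_c", "B#X_c") %in% rownames(self$S)))
  # extracellular-vs-intracellular id clash is refused
  clash <- model_from_reactions(
    "clash",
    data.frame(id = c("X_c", "Q"), compartment = c("extracellular", "cytoplasm")),
    list(T = list(stoich = c(X_c = -1, Q = 1), lb = 0, ub = 10),
         BIOMASS = list(stoich = c(Q = -1), lb = 0, ub = 10)),
    "BIOMASS")
  expect_error(build_pair_model(m, clash), "extracellular in one model")
})

test_that("no-harm pair solves reproduce the hand-derived optima", {
  tol <- tolerance_config()
  # shared-substrate competition: floor leaves the focal organism eps_class
  cp <- fixture_pair("COMP")
  ra <- solve_pair_growth(cp$pair, cp$fx$env, "A", partner_floor = 10)
  expect_equal(ra$lambda, 0.001, tolerance = 1e-9)
  # two-way obligate loop sustains 10 each from nothing alone
  ob <- fixture_pair("OBL2")
  expect_equal(solve_pair_growth(ob$pair, ob$fx$env, "A", 0)$lambda, 10,
               tolerance = 1e-9)
  # facultative cross-feeding doubles both growth rates
  fc <- fixture_pair("FAC")
  expect_equal(solve_pair_growth(fc$pair, fc$fx$env, "A", 10)$lambda, 20,
               tolerance = 1e-9)
  expect_equal(solve_pair_growth(fc$pair, fc$fx$env, "B", 10)$lambda, 20,
               tolerance = 1e-9)
})

test_that("classification follows the growth-rate comparison table", {
  expect_identical(classify_interaction(c(10, 10), c(0.001, 0.001))$label,
                   "COMPETITIVE")
  expect_identical(classify_interaction(c(10, 10), c(0.001, 0.001))$symbols,
                   c("minus", "minus"))
  # within the eps_class band counts as equal
  expect_identical(classify_interaction(c(10, 10), c(10.0005, 10))$label,
                   "NEUTRAL")
  expect_identical(classify_interaction(c(0, 0), c(10, 10))$label,
                   "TWOWAY_OBLIGATE")
  expect_identical(classify_interaction(c(10, 10), c(15, 10))$label,
                   "COMMENSAL")
  expect_identical(classify_interaction(c(10, 10), c(15, 12))$label,
                   "FACULTATIVE_COOP")
  expect_identical(classify_interaction(c(10, 0), c(12, 5))$label,
                   "ONEWAY_OBLIGATE")
  expect_identical(classify_interaction(c(10, 0), c(10, 5))$label,
                   "OBLIGATE_COMMENSAL")
  # an organism left non-viable (and no loser) is no growth
  expect_identical(classify_interaction(c(0, 10), c(0.05, 10))$label,
                   "NO_GROWTH")
  expect_error(classify_interaction(c(-1, 0), c(0, 0)), "non-negative")
})

test_that("assess_pair composes solves and classification for each fixture", {
  for (name in c("COMP", "FAC", "OBL2")) {
    fx <- make_fixture(name)
    asmt <- assess_pair(fx$models[[1]], fx$models[[2]], fx$env)
    expect_identical(asmt$label, fx$ground_truth)
  }
})

test_that("the floored pair program is feasible whenever the solo programs are", {
  set.seed(101)
  for (i in 1:25) {
    sp <- draw_random_pair()
    pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
    env <- thin_env(sp$env)
    la <- pairfba:::pair_solo_growth(pair, env, "A")$lambda
    lb_ <- pairfba:::pair_solo_growth(pair, env, "B")$lambda
    ra <- solve_pair_growth(pair, env, "A", lb_)
    rb <- solve_pair_growth(pair, env, "B", la)
    expect_true(ra$status %in% c("optimal", "no_growth"))
    expect_true(rb$status %in% c("optimal", "no_growth"))
    # the focal organism never harms the partner relative to eps_class
    expect_gte(ra$lambda, -1e-9)
    expect_gte(rb$lambda, -1e-9)
  }
})

test_that("growth rates are monotone in nutrient supply", {
  set.seed(77)
  for (i in 1:10) {
    sp <- draw_random_pair()
    pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
    env1 <- sp$env
    env2 <- growth_env(lower = env1$lower * 2, upper = env1$upper)
    a1 <- assess_pair(pair, env = env1)
    a2 <- assess_pair(pair, env = env2)
    expect_true(all(a2$lambda_alone >= a1$lambda_alone - 1e-6))
    expect_true(all(a2$lambda_together >= a1$lambda_together - 1e-6))
  }
})

test_that("pure shared-resource competition conserves the substrate yield", {
  tol <- tolerance_config()
  set.seed(55)
  for (i in 1:20) {
    y <- stats::runif(1, 0.5, 2)
    sp <- random_toy_pair(n_private = 0, n_shared = 1, n_crossfeed = 0,
                          depth = 1, yield = y)
    pair <- build_pair_model(sp$models[[1]], sp$models[[2]])
    supply_total <- -sum(sp$env$lower)
    asmt <- assess_pair(pair, env = sp$env)
    expect_lte(sum(asmt$lambda_together),
               y * supply_total + 2 * tol$eps_class + 1e-9)
  }
})
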