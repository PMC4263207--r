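# every distribution returned in these tests is also checked against the
# FluxDistribution invariants (steady state, bounds, ratio rows)
expect_valid_distribution <- function(model, ec, sol, tol = 1e-6) {
  v <- fluxes(sol)
  S <- as.matrix(stoichiometricMatrix(model, "internal_only"))
  expect_lt(max(abs(S %*% v)), tol)
  b <- reactionBounds(ec)
  expect_true(all(v >= b[, 1] - tol & v <= b[, 2] + tol))
  E <- as.matrix(ec@equalityCoef)
  if (nrow(E))
    expect_lt(max(abs(E %*% v - ec@equalityRhs)), tol)
  invisible(v)
}

test_that("FBA reproduces hand-computable optima and honours knockouts", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, env = envdf("U", 0, 10))
  sol <- suppressMessages(fba(br, ec, objective = "E1"))
  expect_equal(sol@objectiveValue, 10, tolerance = 1e-9)
  expect_valid_distribution(br, ec, sol)

  # removing the only route to B zeroes the objective
  ko <- mergeConstraints(br, env = envdf("U", 0, 10),
                         knockouts = knockoutSet(reactions = "R1"))
  sol2 <- suppressMessages(fba(br, ko, objective = "E1"))
  expect_equal(sol2@objectiveValue, 0, tolerance = 1e-9)
  expect_valid_distribution(br, ko, sol2)

  expect_message(fba(br, ec, objective = "E1"), "non-unique")
  expect_error(suppressMessages(fba(br, ec, objective = "nope")),
               class = "validationError")
})

test_that("FBA matches the vertex-enumeration oracle on the toy fixtures", {
  for (name in c("TOY-LIN", "TOY-BR", "TOY-CYC")) {
    m <- makeFixture(name)
    first <- reactionIds(m)[1]
    last <- reactionIds(m)[3]
    ec <- mergeConstraints(m, env = envdf(first, 0, 10))
    sol <- suppressMessages(fba(m, ec, objective = last))
    lp <- fluxkit:::lpData(m, ec)
    oracle <- vertexOptimumLP(
      replace(numeric(nReactions(m)), 3, 1),
      lp$Aeq, lp$beq, lp$lower, pmin(lp$upper, 1e4), maximize = TRUE)
    expect_equal(sol@objectiveValue, oracle, tolerance = 1e-7)
  }
})

test_that("pFBA keeps the optimum, minimizes total flux and kills futile cycles", {
  # futile pair: any flux on F, G inflates the L1 norm without gaining E
  cyc <- makeFixture("TOY-CYC")
  ec <- mergeConstraints(cyc, measurements = meas("U", 10))
  p <- pfba(cyc, ec, objective = "E")
  expect_equal(unname(fluxes(p)[c("F", "G")]), c(0, 0), tolerance = 1e-9)
  expect_equal(p@objectiveValue, 10, tolerance = 1e-9)
  expect_valid_distribution(cyc, ec, p)

  # forced chain: L1 norm is exactly 3 x 10
  lin <- makeFixture("TOY-LIN")
  ecl <- mergeConstraints(lin, measurements = meas("U", 10))
  pl <- pfba(lin, ecl, objective = "E")
  expect_equal(sum(abs(fluxes(pl))), 30, tolerance = 1e-9)

  # dominance on every fixture: same objective, no larger L1 than FBA
  for (name in c("TOY-LIN", "TOY-BR", "TOY-CYC")) {
    m <- makeFixture(name)
    ec2 <- mergeConstraints(m, env = envdf(reactionIds(m)[1], 0, 10))
    obj <- reactionIds(m)[3]
    f <- suppressMessages(fba(m, ec2, objective = obj))
    p2 <- pfba(m, ec2, objective = obj)
    expect_equal(p2@objectiveValue, f@objectiveValue, tolerance = 1e-6)
    expect_lte(sum(abs(fluxes(p2))), sum(abs(fluxes(f))) + 1e-6)
  }
})

test_that("QP measurement fitting matches Lagrange and grid-search oracles", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, env = envdf("U", 10, 10),
                         measurements = meas(c("E1", "E2"), c(7, 2)),
                         measurement_mode = "as_fitting_targets")
  fit <- qpFitMeasurements(br, ec)
  # minimize (E1-7)^2 + (E2-2)^2 s.t. E1 + E2 = 10: shift the misfit equally
  expect_equal(unname(fluxes(fit)[c("E1", "E2")]), c(7.5, 2.5),
               tolerance = 1e-8)
  expect_equal(fit@objectiveValue, 2 * 0.5^2, tolerance = 1e-8)
  expect_valid_distribution(br, ec, fit)

  # inverse-variance weights, checked against brute-force grid search
  ecw <- mergeConstraints(br, env = envdf("U", 10, 10),
                          measurements = meas(c("E1", "E2"), c(7, 2),
                                              sd = c(1, 2)),
                          measurement_mode = "as_fitting_targets")
  fitw <- qpFitMeasurements(br, ecw)
  e1_grid <- gridFitBranch(7, 2, w1 = 1, w2 = 1 / 4)
  expect_equal(unname(fluxes(fitw)["E1"]), e1_grid, tolerance = 1e-3)
  expect_equal(unname(fluxes(fitw)["E1"]), 7.2, tolerance = 1e-8)

  # exactly feasible targets: zero misfit, measured values reproduced
  ec0 <- mergeConstraints(br, env = envdf("U", 10, 10),
                          measurements = meas(c("E1", "E2"), c(6, 4)),
                          measurement_mode = "as_fitting_targets")
  fit0 <- qpFitMeasurements(br, ec0)
  expect_lt(fit0@objectiveValue, 1e-9)
  expect_equal(unname(fluxes(fit0)[c("E1", "E2")]), c(6, 4), tolerance = 1e-7)

  # hard-applied measurements are rejected for fitting
  echard <- mergeConstraints(br, measurements = meas("U", 10))
  expect_error(qpFitMeasurements(br, echard),
               class = "methodNotApplicableError")
  expect_error(qpFitMeasurements(br, mergeConstraints(br)),
               class = "methodNotApplicableError")
})

test_that("QP fitting respects inequality bounds when targets are unreachable", {
  br <- makeFixture("TOY-BR")
  m2 <- makeModel("capped", list(
    list(id = "U", stoich = c(A = 1), lower = 10, upper = 10),
    list(id = "R1", stoich = c(A = -1, B = 1), lower = 0, upper = 3),
    list(id = "R2", stoich = c(A = -1, C = 1), lower = 0, upper = 1000),
    list(id = "E1", stoich = c(B = -1), lower = 0, upper = 1000),
    list(id = "E2", stoich = c(C = -1), lower = 0, upper = 1000)))
  ec <- mergeConstraints(m2, measurements = meas("E1", 8),
                         measurement_mode = "as_fitting_targets")
  fit <- qpFitMeasurements(m2, ec)
  # E1 = R1 <= 3, so the closest admissible value saturates the cap
  expect_equal(unname(fluxes(fit)["E1"]), 3, tolerance = 1e-7)
  expect_valid_distribution(m2, ec, fit)
})

test_that("tight bounds collapse fixed fluxes and bracket free ones", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, measurements = meas("U", 10))
  tb <- tightBounds(br, ec)
  r <- ranges(tb)
  expect_equal(unname(r["U", ]), c(10, 10))         # measured: collapsed
  expect_equal(unname(r["R1", ]), c(0, 10))
  expect_equal(unname(r["R2", ]), c(0, 10))

  lin <- makeFixture("TOY-LIN")
  rl <- ranges(tightBounds(lin, mergeConstraints(lin, measurements = meas("U", 10))))
  expect_equal(unname(rl["R", ]), c(10, 10))        # determined flux

  # an isolated unconstrained reaction spans its declared bounds
  iso <- makeModel("iso", list(
    list(id = "X", stoich = c(A = 1), lower = 0, upper = 400),
    list(id = "Y", stoich = c(A = -1), lower = 0, upper = 1000)))
  ri <- ranges(tightBounds(iso))
  expect_equal(unname(ri["X", ]), c(0, 400))

  # knockouts are reported at their fixed zero
  ko <- mergeConstraints(br, measurements = meas("U", 10),
                         knockouts = knockoutSet(reactions = "R2"))
  expect_equal(unname(ranges(tightBounds(br, ko))["R2", ]), c(0, 0))
})

test_that("FVA under optimality brackets optima and relaxes with the fraction", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, measurements = meas("U", 10))
  fva1 <- fvaUnderOptimality(br, ec, objective = "E1")
  r1 <- ranges(fva1)
  expect_equal(unname(r1["E2", ]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(r1["R1", ]), c(10, 10), tolerance = 1e-9)
  expect_equal(fva1@objectiveFixedAt, 10)

  rhalf <- ranges(fvaUnderOptimality(br, ec, objective = "E1", fraction = 0.5))
  expect_equal(unname(rhalf["E1", ]), c(5, 10), tolerance = 1e-9)
  expect_equal(unname(rhalf["E2", ]), c(0, 5), tolerance = 1e-9)

  # bracketing: FBA and pFBA optima lie inside the fraction-1 ranges
  for (name in c("TOY-BR", "TOY-CYC")) {
    m <- makeFixture(name)
    ecm <- mergeConstraints(m, env = envdf(reactionIds(m)[1], 0, 10))
    obj <- reactionIds(m)[3]
    rr <- ranges(fvaUnderOptimality(m, ecm, objective = obj))
    for (sol in list(suppressMessages(fba(m, ecm, objective = obj)),
                     pfba(m, ecm, objective = obj))) {
      v <- fluxes(sol)
      expect_true(all(v >= rr[, 1] - 1e-6 & v <= rr[, 2] + 1e-6))
    }
  }
})

test_that("robustness profiles scan the objective over fixed-flux grids", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, env = envdf("U", 0, 10))
  pr <- robustnessAnalysis(br, ec, objective = "E1", varied_reactions = "U",
                           percentages = c(0, 50, 100))
  g <- pr[[1]]@grid
  expect_equal(g$objective, c(0, 5, 10), tolerance = 1e-9)
  expect_true(all(g$feasible))
  expect_equal(g$fixed_flux, g$percentage / 100 * pr[[1]]@referenceValue)

  # fixing at 100% of the prior value returns the original optimum
  full <- robustnessAnalysis(br, ec, objective = "E1",
                             varied_reactions = "R1", percentages = 100)
  expect_equal(full[[1]]@grid$objective, 10, tolerance = 1e-9)

  # a flux pinned by other constraints (here the branch ratio) has no slack:
  # only the 100% point is feasible
  fix <- toyBRDetermined()
  flat <- robustnessAnalysis(fix$model, fix$ec, objective = "E1",
                             varied_reactions = "R1",
                             percentages = c(50, 100))
  expect_true(is.na(flat[[1]]@grid$objective[1]))
  expect_equal(flat[[1]]@grid$objective[2], 6, tolerance = 1e-9)

  # a zero prior value degenerates to a flat grid, with a warning
  expect_warning(
    deg <- robustnessAnalysis(br, mergeConstraints(br, measurements = meas("U", 10)),
                              objective = "E1", varied_reactions = "E2",
                              percentages = c(0, 50, 100)),
    "degenerate")
  expect_equal(unique(deg[[1]]@grid$fixed_flux), 0)
})

test_that("knockout analysis equals pre-merged knockouts and handles GPRs", {
  br <- makeFixture("TOY-BR")
  ec <- mergeConstraints(br, env = envdf("U", 0, 10))

  # empty knockout set is a no-op
  plain <- suppressMessages(fba(br, ec, objective = "E1"))
  noop <- suppressMessages(knockoutAnalysis(br, ec, knockoutSet(), "fba",
                                            objective = "E1"))
  expect_equal(fluxes(noop), fluxes(plain))

  # knocking out the objective forces it to zero
  koObj <- suppressMessages(knockoutAnalysis(br, ec, knockoutSet("E1"), "fba",
                                             objective = "E1"))
  expect_equal(koObj@objectiveValue, 0, tolerance = 1e-9)

  # gene knockout propagates through the GPR before solving
  mg <- makeModel("gpr", list(
    list(id = "U", stoich = c(A = 1), lower = 0, upper = 10),
    list(id = "R1", stoich = c(A = -1, B = 1), lower = 0, upper = 1000,
         gpr = "fum1"),
    list(id = "R2", stoich = c(A = -1, B = 1), lower = 0, upper = 1000),
    list(id = "E", stoich = c(B = -1), lower = 0, upper = 1000)))
  sol <- suppressMessages(knockoutAnalysis(mg, NULL, knockoutSet(genes = "fum1"),
                                           "fba", objective = "E"))
  expect_equal(unname(fluxes(sol)["R1"]), 0, tolerance = 1e-9)
  expect_equal(sol@objectiveValue, 10, tolerance = 1e-9)  # isoenzyme carries it

  # identical to merging the KO up front
  pre <- mergeConstraints(mg, knockouts = knockoutSet(genes = "fum1"))
  sol2 <- suppressMessages(fba(mg, pre, objective = "E"))
  expect_equal(fluxes(sol2), fluxes(sol))
})

test_that("infeasible constraint sets raise diagnostic errors", {
  br <- makeFixture("TOY-BR")
  # U forced to 10 but both exits knocked out
  ec <- mergeConstraints(br, measurements = meas("U", 10),
                         knockouts = knockoutSet(reactions = c("E1", "E2")))
  expect_error(suppressMessages(fba(br, ec, objective = "E1")),
               class = "infeasibleError")
  expect_error(tightBounds(br, ec), class = "infeasibleError")
  err <- tryCatch(suppressMessages(fba(br, ec, objective = "E1")),
                  error = identity)
  expect_match(conditionMessage(err), "knockout")

  # unbounded objective on a free cycle
  free <- makeModel("free", list(
    list(id = "F", stoich = c(A = -1, B = 1), lower = 0, upper = Inf),
    list(id = "G", stoich = c(B = -1, A = 1), lower = 0, upper = Inf)))
  expect_error(suppressMessages(fba(free, NULL, objective = "F")),
               class = "unboundedError")
})
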