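test_that("ratio linearization produces kappa_i - tau*kappa_j rows", {
  lin <- linearizeRatio(fluxRatio(c(R1 = 1), c(U = 1), 0.6))
  expect_equal(lin$coefficients[c("R1", "U")], c(R1 = 1, U = -0.6))
  expect_equal(lin$rhs, 0)
  expect_false(lin$degenerate)

  lin2 <- linearizeRatio(fluxRatio(c(R2 = 1, R3 = 0.5), c(U = 1), 1))
  expect_equal(lin2$coefficients[c("R2", "R3", "U")],
               c(R2 = 1, R3 = 0.5, U = -1))

  # v/v = 1 cancels to the zero row and is flagged
  expect_true(linearizeRatio(fluxRatio(c(R1 = 1), c(R1 = 1), 1))$degenerate)
  expect_error(fluxRatio(c(R1 = 1), c(U = 1), 0), "tau")
})

test_that("linearization is equivalent to the ratio away from zero denominators", {
  # property: random vectors satisfying the ratio satisfy the row and back
  set.seed(41)
  for (rep in 1:50) {
    ids <- c("a", "b", "c", "d")
    num <- setNames(round(runif(2, -2, 2), 2), ids[1:2])
    den <- setNames(round(runif(2, 0.5, 2), 2), ids[3:4])
    tau <- round(runif(1, 0.2, 3), 2)
    lin <- linearizeRatio(fluxRatio(num, den, tau))
    v <- setNames(runif(4, 0.5, 5), ids)
    # force v onto the ratio by rescaling the numerator fluxes
    denv <- sum(den * v[names(den)])
    numv <- sum(num * v[names(num)])
    if (abs(numv) < 1e-9) next
    v[names(num)] <- v[names(num)] * tau * denv / numv
    row <- sum(lin$coefficients * v[names(lin$coefficients)])
    expect_lt(abs(row), 1e-8)
    # and conversely, any vector on the row with nonzero denominator is on the ratio
    expect_equal(sum(num * v[names(num)]) / sum(den * v[names(den)]), tau,
                 tolerance = 1e-8)
  }
})

test_that("ratio expression grammar parses coefficients, signs and defaults", {
  r <- parseRatioExpression("R_PPC / R_PPC + R_PCK = 0.4")
  expect_equal(r@numerator, c(R_PPC = 1))
  expect_equal(r@denominator, c(R_PPC = 1, R_PCK = 1))
  expect_equal(r@tau, 0.4)

  r2 <- parseRatioExpression("2*R1 - 0.5*R2 / U = 1.5")
  expect_equal(r2@numerator, c(R1 = 2, R2 = -0.5))
  expect_error(parseRatioExpression("R1 / = 2"), class = "parseError")
  expect_error(parseRatioExpression("R1 + / U = 2"), class = "parseError")
})

test_that("gene knockouts expand through GPR rules", {
  m <- makeModel("gprtoy", list(
    list(id = "U", stoich = c(A = 1), lower = 0, upper = 10),
    list(id = "R", stoich = c(A = -1, B = 1), lower = 0, upper = 10,
         gpr = "g1 and (g2 or g3)"),
    list(id = "E", stoich = c(B = -1), lower = 0, upper = 10)),
    genes = c("g1", "g2", "g3", "gX"))

  # one isozyme down: rule survives
  expect_identical(expandGeneKnockouts(m, knockoutSet(genes = "g2")),
                   character(0))
  # essential subunit down: reaction silenced
  expect_identical(expandGeneKnockouts(m, knockoutSet(genes = "g1")), "R")
  expect_identical(expandGeneKnockouts(m, knockoutSet(genes = c("g2", "g3"))),
                   "R")
  # a gene with no GPR reference silences nothing, with a warning
  expect_warning(
    out <- expandGeneKnockouts(m, knockoutSet(genes = "gX")),
    "no reaction")
  expect_identical(out, character(0))
  expect_error(expandGeneKnockouts(m, knockoutSet(genes = "nope")),
               class = "validationError")
  expect_error(expandGeneKnockouts(m, knockoutSet(reactions = "nope")),
               class = "validationError")
})

test_that("merge precedence: env intersects, measurements fix, knockouts win", {
  m <- makeModel("prec", list(
    list(id = "U", stoich = c(A = 1), lower = -10000, upper = 0),
    list(id = "R", stoich = c(A = -1, B = 1), lower = 0, upper = 1000),
    list(id = "E", stoich = c(B = -1), lower = 0, upper = 1000)))

  # a glucose-uptake-style setting inside the model bounds: no override
  ec <- mergeConstraints(m, env = envdf("U", -11, -11))
  expect_equal(as.numeric(reactionBounds(ec)["U", ]), c(-11, -11))
  expect_equal(nrow(ec@overridden), 0L)

  # measurement followed by a knockout of the same reaction: KO wins, audited
  ec2 <- mergeConstraints(m, measurements = meas("R", 10),
                          knockouts = knockoutSet(reactions = "R"))
  expect_equal(as.numeric(reactionBounds(ec2)["R", ]), c(0, 0))
  expect_true(any(grepl("knockout overrode measurement", ec2@overridden$source)))

  # environment vs measurement with empty intersection: hard conflict
  expect_error(
    mergeConstraints(m, env = envdf("R", 0, 5), measurements = meas("R", 7)),
    class = "conflictError")
  # env outside model bounds entirely: also a conflict
  expect_error(mergeConstraints(m, env = envdf("U", 5, 10)),
               class = "conflictError")
  # env clipped by model bounds is audited, not fatal
  ec3 <- mergeConstraints(m, env = envdf("U", -20000, 0))
  expect_equal(as.numeric(reactionBounds(ec3)["U", ]), c(-10000, 0))
  expect_equal(nrow(ec3@overridden), 1L)
})

test_that("merging is idempotent and knockouts dominate", {
  m <- makeFixture("TOY-BR")
  args <- list(m, measurements = meas("U", 10),
               ratios = list(fluxRatio(c(R1 = 1), c(U = 1), 0.6)),
               knockouts = knockoutSet(reactions = "E2"))
  ec1 <- do.call(mergeConstraints, args)
  ec2 <- do.call(mergeConstraints, args)
  expect_equal(reactionBounds(ec1), reactionBounds(ec2))
  expect_equal(as.matrix(ec1@equalityCoef), as.matrix(ec2@equalityCoef))
  expect_identical(ec1@overridden, ec2@overridden)
  for (r in ec1@silenced)
    expect_equal(as.numeric(reactionBounds(ec1)[r, ]), c(0, 0))
})

test_that("constraint file readers parse the documented formats", {
  d <- tempfile("cons"); dir.create(d)
  env_f <- file.path(d, "env.csv")
  writeLines(c("reaction_id,lower_bound,upper_bound", "U,-11,-11"), env_f)
  e <- readEnvironmentalConditions(env_f)
  expect_equal(e$lower, -11)

  meas_f <- file.path(d, "meas.csv")
  writeLines(c("reaction_id,value,stddev", "U,10,", "E,10.4,0.2"), meas_f)
  mm <- readFluxMeasurements(meas_f)
  expect_equal(mm$value, c(10, 10.4))
  expect_true(is.na(mm$stddev[1]) && mm$stddev[2] == 0.2)

  ko_f <- file.path(d, "kos.txt")
  writeLines(c("R1", "gene:g1", "# comment"), ko_f)
  ko <- readKnockouts(ko_f)
  expect_identical(ko@reactions, "R1")
  expect_identical(ko@genes, "g1")

  ratio_f <- file.path(d, "ratios.txt")
  writeLines("R1 / U = 0.6", ratio_f)
  rr <- readFluxRatios(ratio_f)
  expect_length(rr, 1L)
  expect_equal(rr[[1]]@tau, 0.6)
})
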