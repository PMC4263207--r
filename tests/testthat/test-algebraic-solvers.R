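test_that("determined systems solve to their hand-derived flux vectors", {
  # conservation forces the whole chain to the measured uptake
  lin <- makeFixture("TOY-LIN")
  ec <- mergeConstraints(lin, measurements = meas("U", 10))
  sol <- solveDetermined(lin, ec)
  expect_equal(fluxes(sol), c(U = 10, R = 10, E = 10), tolerance = 1e-10)
  expect_identical(sol@method, "direct")
  expect_true(sol@consistent)

  # branch point split by the flux ratio R1/U = 0.6
  fix <- toyBRDetermined()
  sol2 <- solveDetermined(fix$model, fix$ec)
  expect_equal(fluxes(sol2), c(U = 10, R1 = 6, R2 = 4, E1 = 6, E2 = 4),
               tolerance = 1e-10)
})

test_that("solvers refuse systems outside their determinacy preconditions", {
  br <- makeFixture("TOY-BR")
  expect_error(solveDetermined(br, mergeConstraints(br)),
               class = "methodNotApplicableError")
  expect_error(solveLeastSquares(br, mergeConstraints(br)),
               class = "methodNotApplicableError")

  lin <- makeFixture("TOY-LIN")
  ecod <- mergeConstraints(lin, measurements = meas(c("U", "E"), c(10, 10.4)),
                           measurement_mode = "as_equation_rows")
  expect_error(solveDetermined(lin, ecod), class = "methodNotApplicableError")
})

test_that("least squares reconciles redundant measurements as derived by hand", {
  lin <- makeFixture("TOY-LIN")
  ec <- mergeConstraints(lin, measurements = meas(c("U", "E"), c(10, 10.4)),
                         measurement_mode = "as_equation_rows")
  # equal weights: v_R = (10 + 10.4) / 2
  sol <- solveLeastSquares(lin, ec)
  expect_equal(unname(fluxes(sol)["R"]), 10.2, tolerance = 1e-10)
  expect_gt(sol@residualNorm, 0)
  expect_false(sol@consistent)

  # weight 4:1 pulls the estimate toward the uptake measurement
  solw <- solveLeastSquares(lin, ec, weights = c(U = 4, E = 1))
  expect_equal(unname(fluxes(solw)["R"]), (4 * 10 + 10.4) / 5, tolerance = 1e-10)
  expect_identical(solw@method, "weighted_least_squares")

  # consistent measurements: exact, zero residual
  ec2 <- mergeConstraints(lin, measurements = meas(c("U", "E"), c(10, 10)),
                          measurement_mode = "as_equation_rows")
  sol2 <- solveLeastSquares(lin, ec2)
  expect_equal(unname(fluxes(sol2)["R"]), 10, tolerance = 1e-10)
  expect_lt(sol2@residualNorm, 1e-8)
  expect_true(sol2@consistent)
})

test_that("inverse-variance weighting matches explicit weights and equal weights match unweighted", {
  lin <- makeFixture("TOY-LIN")
  ec <- mergeConstraints(lin,
                         measurements = meas(c("U", "E"), c(10, 10.4),
                                             sd = c(0.5, 1)),
                         measurement_mode = "as_equation_rows")
  auto <- solveLeastSquares(lin, ec, weighted = TRUE)
  manual <- solveLeastSquares(lin, ec, weights = c(U = 4, E = 1))
  expect_equal(fluxes(auto), fluxes(manual), tolerance = 1e-10)

  same <- solveLeastSquares(lin, ec, weights = c(U = 1, E = 1))
  plain <- solveLeastSquares(lin, ec)
  expect_equal(fluxes(same), fluxes(plain), tolerance = 1e-10)
})

test_that("noise-free measurements of a determining subset recover the generating flux", {
  br <- makeFixture("TOY-BR")
  set.seed(11)
  for (rep in 1:20) {
    u <- runif(1, 1, 10); f <- runif(1, 0.05, 0.95)
    truth <- c(U = u, R1 = f * u, R2 = (1 - f) * u, E1 = f * u, E2 = (1 - f) * u)
    ec <- mergeConstraints(br, measurements = meas(c("U", "R1"),
                                                   c(u, f * u)),
                           measurement_mode = "as_equation_rows")
    sol <- solveLeastSquares(br, ec)
    expect_lt(max(abs(fluxes(sol) - truth)), 1e-8)
    # the direct solver agrees when measurements are applied as bounds
    ecb <- mergeConstraints(br, measurements = meas(c("U", "R1"), c(u, f * u)))
    expect_lt(max(abs(fluxes(solveDetermined(br, ecb)) - truth)), 1e-8)
  }
})

test_that("redundant measurements reduce the mean estimation error under noise", {
  lin <- makeFixture("TOY-LIN")
  set.seed(314)
  n_mc <- 150; sigma <- 0.5; truth <- 10
  err1 <- err2 <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    # one noisy measurement determines the chain
    ec1 <- mergeConstraints(lin, measurements = meas("U", truth + rnorm(1, 0, sigma)),
                            measurement_mode = "as_equation_rows")
    err1[i] <- abs(unname(fluxes(solveLeastSquares(lin, ec1))["R"]) - truth)
    # a redundant second measurement averages the noise down
    ec2 <- mergeConstraints(lin, measurements = meas(
      c("U", "E"), truth + rnorm(2, 0, sigma)),
      measurement_mode = "as_equation_rows")
    err2[i] <- abs(unname(fluxes(solveLeastSquares(lin, ec2))["R"]) - truth)
  }
  expect_lt(mean(err2), mean(err1))
})

test_that("solutions violating inequality bounds warn instead of failing", {
  m <- makeModel("tight", list(
    list(id = "U", stoich = c(A = 1), lower = 0, upper = 5),
    list(id = "E", stoich = c(A = -1), lower = 0, upper = 1000)))
  ec <- mergeConstraints(m, measurements = meas("E", 8),
                         measurement_mode = "as_equation_rows")
  # conservation forces U = 8 > its upper bound 5
  expect_warning(sol <- solveLeastSquares(m, ec), "violates effective bounds")
  expect_equal(unname(fluxes(sol)["U"]), 8, tolerance = 1e-8)
})
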