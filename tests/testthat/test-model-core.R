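test_that("CSV dialect rows parse into the documented stoichiometries", {
  p <- writeToyCSV()
  m <- readCSVModel(p$reactions, p$metabolites)
  expect_s4_class(m, "MetabolicModel")
  expect_identical(reactionIds(m), c("R2", "R4", "R5", "U"))

  S <- stoichiometricMatrix(m, "full_system")
  expect_equal(S["A", "R2"], -1)
  expect_equal(S["B", "R2"], 1)
  expect_equal(as.numeric(reactionBounds(m)["R2", ]), c(0, 1000))

  expect_equal(S["A", "R4"], -2)
  expect_equal(S["B", "R4"], 1)
  expect_equal(S["C", "R4"], 1)
  expect_identical(reactionTable(m)$gpr[2], "g1 and g2")

  # one-sided equations are drains under the structural rule
  expect_true(reactionTable(m)$drain[reactionIds(m) == "R5"])
  expect_true(reactionTable(m)$drain[reactionIds(m) == "U"])
  expect_false(reactionTable(m)$drain[reactionIds(m) == "R2"])
})

test_that("equation parser handles coefficients, reversibility and errors", {
  eq <- parseReactionEquation("A + 2 B <-> C")
  expect_equal(eq$stoich[c("A", "B", "C")], c(A = -1, B = -2, C = 1))
  expect_true(eq$reversible)
  expect_false(parseReactionEquation("A -> B")$reversible)
  # both-sides metabolites collapse to the net coefficient
  expect_equal(parseReactionEquation("2 A -> A + B")$stoich,
               c(A = -1, B = 1))
  expect_error(parseReactionEquation("A + B"), class = "parseError")
  expect_error(parseReactionEquation("->"), class = "parseError")
})

test_that("CSV round-trip reproduces ids, coefficients, bounds and GPRs", {
  p <- writeToyCSV()
  m1 <- readCSVModel(p$reactions, p$metabolites)
  out_r <- tempfile(fileext = ".csv"); out_m <- tempfile(fileext = ".csv")
  writeCSVModel(m1, out_r, out_m)
  m2 <- readCSVModel(out_r, out_m)
  expect_identical(reactionIds(m2), reactionIds(m1))
  expect_identical(metaboliteIds(m2), metaboliteIds(m1))
  expect_equal(as.matrix(stoichiometricMatrix(m2, "full_system")),
               as.matrix(stoichiometricMatrix(m1, "full_system")))
  expect_equal(reactionBounds(m2), reactionBounds(m1))
  expect_identical(reactionTable(m2)$gpr, reactionTable(m1)$gpr)
})

test_that("SBML Level 2 reader round-trips counts, bounds, GPR and externals", {
  m <- readSBML(extdata("toy_chain_l2.xml"))
  expect_equal(nReactions(m), 4L)
  expect_equal(nMetabolites(m), 3L)
  expect_equal(sum(metaboliteTable(m)$external), 1L)  # M_B_e via compartment "e"
  expect_equal(sum(!metaboliteTable(m)$external), 2L)
  rt <- reactionTable(m)
  expect_equal(as.numeric(reactionBounds(m)["R_T", ]), c(-1000, 1000))
  expect_equal(as.numeric(reactionBounds(m)["R_U", ]), c(0, 1000))
  expect_identical(rt$gpr[rt$id == "R_U"], "g1 and (g2 or g3)")
  expect_setequal(geneIds(m), c("g1", "g2", "g3"))
  # drains: R_U (single metabolite) and R_EX_B (all-external), not the transport
  expect_setequal(rt$id[rt$drain], c("R_U", "R_EX_B"))
})

test_that("SBML Level 3 + FBC reader uses flux bounds, gene products and objective", {
  m <- readSBML(extdata("toy_branch_l3fbc.xml"))
  expect_equal(nReactions(m), 5L)
  expect_equal(as.numeric(reactionBounds(m)["R2", ]), c(-1000, 1000))
  expect_equal(as.numeric(reactionBounds(m)["R1", ]), c(0, 1000))
  rt <- reactionTable(m)
  expect_identical(rt$gpr[rt$id == "R1"], "(b001 and (b002 or b003))")
  expect_setequal(geneIds(m), c("b001", "b002", "b003"))
  expect_identical(objectiveReaction(m), "E1")
  # the branched topology matches the programmatic TOY-BR fixture
  expect_equal(as.matrix(stoichiometricMatrix(m, "internal_only")),
               as.matrix(stoichiometricMatrix(makeFixture("TOY-BR"), "internal_only")),
               ignore_attr = TRUE)
})

test_that("duplicate identifiers are rejected as validation errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines(sub('id="R_R"', 'id="R_U"', readLines(extdata("toy_chain_l2.xml"))),
             bad)
  expect_error(readSBML(bad), class = "validationError")

  p <- writeToyCSV()
  lines <- readLines(p$reactions)
  writeLines(c(lines, lines[2]), p$reactions)  # repeat the R2 row
  expect_error(readCSVModel(p$reactions, p$metabolites),
               class = "validationError")
})

test_that("stoichiometric matrices match their written-out definitions", {
  lin <- makeFixture("TOY-LIN")
  S <- as.matrix(stoichiometricMatrix(lin, "internal_only"))
  expect_equal(S, matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
                         dimnames = list(c("A", "B"), c("U", "R", "E"))))

  br <- makeFixture("TOY-BR")
  Sb <- as.matrix(stoichiometricMatrix(br, "internal_only"))
  expect_equal(dim(Sb), c(3L, 5L))
  expect_equal(Sb["A", ], c(U = 1, R1 = -1, R2 = -1, E1 = 0, E2 = 0))

  # scope bookkeeping and per-column identity on a model with externals
  m <- readSBML(extdata("toy_chain_l2.xml"))
  expect_equal(ncol(stoichiometricMatrix(m, "full_system")), nReactions(m))
  expect_equal(nrow(stoichiometricMatrix(m, "internal_only")),
               sum(!metaboliteTable(m)$external))
  Sf <- stoichiometricMatrix(m, "full_system")
  expect_true(all(Matrix::colSums(abs(Sf)) > 0))
})
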