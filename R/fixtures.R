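#' @include accessors.R lp.R
NULL

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Toy and random metabolic-model fixtures
#'
#' Programmatic generators for the small models used throughout the tests
#' and examples:
#' * `TOY-LIN` — linear chain `U: -> A`, `R: A -> B`, `E: B ->`
#'   (3 reactions, 2 internal metabolites, 1 degree of freedom);
#' * `TOY-BR` — branched `U: -> A`, `R1: A -> B`, `R2: A -> C`,
#'   `E1: B ->`, `E2: C ->` (2 degrees of freedom);
#' * `TOY-CYC` — `TOY-LIN` plus the futile pair `F: B -> C`, `G: C -> B`;
#' * `RANDOM-N` — a random sparse network with `n` reactions, generated
#'   pathway-first (a linear spine guarantees a feasible positive flux) with
#'   extra random internal edges; deterministic per `seed`.
#'
#' Every fixture is checked feasible by an LP at build time; the named toys
#' carry hand-derived expected values (degrees of freedom, null-space
#' dimension) in `attr(model, "expected")`.
#'
#' @param name `"TOY-LIN"`, `"TOY-BR"`, `"TOY-CYC"` or `"RANDOM-N"`.
#' @param n Number of reactions for `RANDOM-N` (>= 4).
#' @param seed Mandatory seed for `RANDOM-N`.
#' @param big_bound Bound magnitude for the irreversible reactions.
#' @return A [MetabolicModel-class].
#' @examples
#' makeFixture("TOY-BR")
#' makeFixture("RANDOM-N", n = 12, seed = 7)
#' @export
makeFixture <- function(name = c("TOY-LIN", "TOY-BR", "TOY-CYC", "RANDOM-N"),
                        n = 12L, seed = NULL,
                        big_bound = fluxkitDefaults()$big_bound) {
  name <- match.arg(name)
  rxn <- function(id, stoich, gpr = NA_character_)
    list(id = id, stoich = stoich, lower = 0, upper = big_bound, gpr = gpr)

  if (name == "TOY-LIN") {
    m <- makeModel("TOY-LIN", list(
      rxn("U", c(A = 1)), rxn("R", c(A = -1, B = 1)), rxn("E", c(B = -1))))
    attr(m, "expected") <- list(dof = 1L, nullspace_dim = 1L)
  } else if (name == "TOY-BR") {
    m <- makeModel("TOY-BR", list(
      rxn("U", c(A = 1)),
      rxn("R1", c(A = -1, B = 1)), rxn("R2", c(A = -1, C = 1)),
      rxn("E1", c(B = -1)), rxn("E2", c(C = -1))))
    attr(m, "expected") <- list(dof = 2L, nullspace_dim = 2L)
  } else if (name == "TOY-CYC") {
    m <- makeModel("TOY-CYC", list(
      rxn("U", c(A = 1)), rxn("R", c(A = -1, B = 1)), rxn("E", c(B = -1)),
      rxn("F", c(B = -1, C = 1)), rxn("G", c(C = -1, B = 1))))
    attr(m, "expected") <- list(dof = 2L, nullspace_dim = 2L)
  } else {
    if (is.null(seed))
      fkStop("validationError", "RANDOM-N fixtures require a seed")
    if (n < 4L)
      fkStop("validationError", "RANDOM-N needs n >= 4 reactions")
    m <- withLocalSeed(seed, {
      n_met <- n - 2L
      mets <- sprintf("M%d", seq_len(n_met))
      spine <- c(list(rxn("U", setNames(1, mets[1]))),
                 lapply(seq_len(n_met - 1L), function(i)
                   rxn(sprintf("R%d", i),
                       setNames(c(-1, 1), mets[c(i, i + 1L)]))),
               list(rxn("E", setNames(-1, mets[n_met]))))
      extra <- n - length(spine)
      k <- 0L
      while (k < extra) {
        ab <- sample(n_met, 2L)
        id <- sprintf("X%d", k + 1L)
        spine[[length(spine) + 1L]] <-
          rxn(id, setNames(c(-1, 1), mets[ab]))
        k <- k + 1L
      }
      makeModel(sprintf("RANDOM-%d-seed%d", n, seed), spine)
    })
  }
  ## feasibility self-check: the all-bounds LP must be solvable
  lp <- solveLP(numeric(nReactions(m)),
                asDense(stoichiometricMatrix(m, "internal_only")),
                rep(0, sum(!m@metabolites$external)),
                m@reactions$lower, m@reactions$upper)
  if (lp$status != "optimal")
    fkStop("numericalError", "fixture '%s' failed its feasibility self-check", name)
  m
}
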