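---
title: "Flux analysis methods: models, constraints, determinacy and solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux analysis methods: models, constraints, determinacy and solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkit)
```

## The model and its assumptions

fluxkit works with constraint-based metabolic models: a stoichiometric
matrix $S$ over metabolites and reactions, reaction bounds
$l \le v \le u$ in mmol/gDW/hr, optional gene–protein–reaction (GPR)
boolean rules, and a designated objective reaction (typically biomass).
The central assumption is quasi-steady state for the balanced
(internal) metabolites, $S_{\mathrm{int}}\,v = 0$: intracellular pools
turn over much faster than the growth time scale, so accumulation terms
vanish.  External (boundary) metabolites are exempt from balancing; drains
— reactions with a single metabolite, or whose metabolites are all
external — carry matter across the system boundary.  Reversibility is
encoded purely through bounds: a reversible reaction has a negative lower
bound.  When a document omits bounds we default to $[0, 10^4]$
(irreversible) or $[-10^4, 10^4]$ (reversible); $10^4$ is a single
configurable constant standing for "unbounded" (`big_bound` in the
readers), chosen because LP solvers need finite bounds and typical
flux magnitudes are below $10^2$ — it is reported, never hidden.

## Constraints and how they merge

Four constraint types layer onto the model, merged by
`mergeConstraints()` innermost last:

1. **environmental conditions** intersect with the model bounds (a
   requested interval outside the declared bounds is clipped and
   audited, an empty intersection is an error);
2. **flux measurements** either fix bounds to `[value, value]`
   (`as_equality_bounds`), enter the equation system as unit rows
   (`as_equation_rows`, the right mode for the algebraic solvers where
   they must remain *soft*), or are merely recorded
   (`as_fitting_targets`) so the QP fit can use them as targets.  The
   third mode exists because the QP method's precondition is precisely
   that measurements are *not* hard constraints; without it the fit
   would be vacuous.  Measurement standard deviations are consumed only
   by the weighted least squares and QP weighting ($w = 1/\sigma^2$,
   inverse variance, the standard MFA convention; unit weight when no
   stddev is given) — for determinacy accounting a measurement is an
   exact equality either way;
3. **flux ratios** $\left(\sum_i \kappa_i v_i\right)/\left(\sum_j
   \kappa_j v_j\right) = \tau$ are enforced only in linearized form
   $\sum_i \kappa_i v_i - \tau \sum_j \kappa_j v_j = 0$.  A flux vector
   with zero denominator satisfies the row trivially; we document this
   rather than guard it, since a $|\text{denominator}| \ge \varepsilon$
   constraint would be nonlinear.  A ratio whose coefficients cancel
   entirely (e.g. $v/v = 1$) is flagged degenerate with a warning;
4. **knockouts** force $(0, 0)$ and win over everything else, with the
   override recorded — the audit of "bounds actually used" is part of
   every report.  Conflicts other than knockout-over-measurement are
   hard errors naming the reaction and both sources: silently narrowing
   overlapping constraints would hide data problems.

## Determinacy and dispatch

The number of linearly independent equations against the number of flux
unknowns decides the method portfolio.  Because genome-scale systems have
hundreds of degrees of freedom, `classifySystem()` first computes the
cheap approximation (unknowns minus raw equation count, ignoring linear
dependency) and performs the exact rank computation only when the
approximation is at or below a threshold (default 50, configurable; any
modest value separates the genome-scale regime, where the approximate
count sits in the hundreds, from desk-scale systems near zero).  Numerical
rank uses singular values with the standard tolerance
$\max(m,n)\,\varepsilon\,\sigma_{\max}$; the tolerance matters because the
determinacy verdict depends on it, so it is stated and fixed.

Measurements enter the combined matrix as unit-coefficient rows rather
than by variable elimination — the rank, and hence the verdict, is
provably the same, and the implementation stays simpler.  The verdict is:
*underdetermined* when the exact degrees of freedom are positive,
otherwise *determined*, except that an inconsistent right-hand side
(augmented rank exceeding coefficient rank — redundant, conflicting
measurements) marks the system *overdetermined*.  A naive "more
independent equations than unknowns" definition is impossible on the
coefficient matrix alone, whose rank never exceeds the unknown count; the
augmented-rank criterion is the operational version of the same idea.
`availableMethods()` turns the verdict into the applicable method list;
`nullSpaceBasis()` exposes the admissible flux space itself as an
orthonormal kernel basis whose dimension equals the exact degrees of
freedom.

For genome-scale degrees-of-freedom accounting we balance **all**
metabolites (scope `"full_system"`, the default of the classification
functions), treating every reaction including drains as an unknown;
the optimization methods balance internal metabolites only, the standard
FBA convention.  Both scopes are explicit arguments, and on the toy
fixtures (which declare no external species) they coincide.

## Solvers and numerical choices

**Algebraic route.**  `solveDetermined()` solves the combined system with
an SVD pseudo-inverse (conditioning; a normal-equations solve would square
the condition number).  `solveLeastSquares()` keeps balances, ratios and
knockout zeros hard, parametrizes the admissible space by the kernel of
the hard rows, and fits the measurements in (weighted) least squares on
that subspace.  Both report a residual norm; the algebraic route cannot
enforce inequality bounds, so violations are *warnings* — failing silently
would hide measurement problems.

**LP.**  No linear-programming package is available in this environment's
R library, so the package carries a dense two-phase primal simplex with
bounded variables (shift to the nonnegative orthant, explicit upper-bound
rows) and Bland's anti-cycling rule, which guarantees termination on the
degenerate polytopes steady-state systems produce.  It is deterministic:
identical inputs give identical vertices.  It is sized for desk-scale
systems (tens of reactions); the test suite cross-checks it against
`boot::simplex` and against exhaustive vertex enumeration on the toy
polytopes.  FBA returns whichever optimal vertex the pivoting reaches and
points users to `fvaUnderOptimality()` for uniqueness characterization.
pFBA fixes the stage-1 optimum as an *equality* (relative tolerance
$10^{-9}$) rather than a $\ge$-fraction, because its purpose is exactly to
select among exact-optimum alternatives; the L1 objective uses the usual
$v = v^+ - v^-$ splitting.  Feasibility checks throughout use a $10^{-6}$
absolute tolerance; both tolerances are arguments.

**QP.**  The measurement fit minimizes
$\sum_m w_m (v_m - \hat m_m)^2$ subject to steady state, bounds and
ratios.  The Hessian is diagonal and only positive *semi*definite (zeros
on unmeasured fluxes), which rules out the strictly-convex QP solvers
installed here; the package therefore implements a primal active-set
method on the box constraints, solving each equality-constrained
subproblem on the kernel of the working set and taking minimum-norm steps
along flat directions — deterministic, and unique in the measured
subspace as the method's contract requires.  Tests pin it against
hand-derived Lagrange solutions and a brute-force grid.

## Fixtures: what the generators emulate

The programmatic fixtures are deliberately minimal metabolisms:
`TOY-LIN` (a linear uptake–conversion–excretion chain), `TOY-BR` (one
branch point, the smallest system where ratio constraints and the QP fit
are non-trivial), `TOY-CYC` (the chain plus a futile two-cycle, the
smallest system where FBA optima are degenerate and pFBA's parsimony
matters), and `RANDOM-N` (a seeded random sparse network built
pathway-first — a linear spine from uptake to excretion guarantees a
feasible positive flux, because rejected infeasible random
stoichiometries would make test failures uninformative).  Every fixture
asserts its own feasibility by LP at build time.

These fixtures exercise the algebra and the method contracts exactly, but
they do not emulate genome-scale features: cofactor coupling, thousands of
alternate optima, rank-deficient balance blocks from conserved moieties,
or the bound dialects of published SBML files.  Passing the desk-scale
suite therefore demonstrates correctness of the methods, not robustness
to every model in the wild; the genome-scale E. coli test (iJR904,
downloaded separately — the model is not redistributed) covers the parser
and classification at realistic size when the file is present.  Problem
sizes in the default test run are deliberately small — toys of 3–5
reactions, random systems up to 12 — which keeps the full suite in the
ten-second range while still covering every method.

## Degenerate inputs and tie-breaks

Zero-coefficient ratio rows are carried (they change no rank); reactions
fixed by equal bounds count toward the raw equation total; a robustness
profile over a reaction with zero prior flux is degenerate (all grid
points coincide) and warns; infeasible robustness grid points are marked
infeasible, not fatal.  Gene knockouts that touch no GPR produce a
warning and silence nothing — reactions without rules are unaffected by
gene deletions.  `fvaUnderOptimality()` applies the spec'd relaxation
direction literally ($\ge f \cdot Z^*$ for maximization, $\le$ for
minimization); with $f = 1$ (the default) the two coincide in effect.

## Known limitations

No inequality flux ratios (only equality ratios are defined); no
χ²-based gross-error classification of measurements; no irreducible
infeasible subsystem computation (infeasibility diagnostics list the
constraint sources present, not a minimal conflict set); SBML is read,
never written; the simplex is dense and not intended for genome-scale FVA
sweeps.
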