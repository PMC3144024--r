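---
title: "Flux coupling analysis by feasibility testing: models, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux coupling analysis by feasibility testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffca)
```

## The model

A metabolic network here is a stoichiometric matrix $S \in \mathbb{R}^{m
\times n}$ (rows = internal metabolites, columns = reactions) and a
reversibility flag per reaction. The object of study is the steady-state
flux cone

$$C = \{ v \in \mathbb{R}^n : S v = 0,\; v_i \ge 0 \ \forall i \in Irr \},$$

a polyhedral cone: no flux bounds, no objective. Exchange with the
environment is modelled by *not balancing* external metabolites — an
uptake or export reaction is simply an unbalanced column. When reading
SBML, species with `boundaryCondition="true"` (or in a user-listed external
compartment) are dropped from the balance rows; flux-bound parameters are
ignored because the analysis is over the unbounded cone, with all uptakes
assumed able to carry flux.

Within $C$, a reaction is **blocked** if its flux is zero in every
$v \in C$. Unblocked reactions fall into three types: **Irev** (only one
sign of flux is feasible at steady state — this includes model-reversible
reactions whose context forbids one direction), **Prev**
(pseudo-irreversible: both signs feasible, but zero on the lineality space
$\{v : Sv = 0, v_{Irr} = 0\}$) and **Frev** (fully reversible: active
somewhere on the lineality space). Irev reactions that are only
backward-feasible have their column negated (`flipped`), so all downstream
systems may assume Irev means "forward".

## The pairwise decision procedure

Every "reaction $i$ is active" condition is realized as a pin $v_i = 1$ (or
$-1$): $C$ is a cone, so scale is irrelevant, and pinned systems keep the
LPs bounded and well scaled. The procedure dispatches on the pair's types:

* **Irev/Irev** — test the feasibility of
  $(P1)\; \{Sv = 0,\; v_k \ge 0\; (k \in Irr \cup Irev),\; v_i = 1,\; v_j = 0\}$
  and its mirror $(P2)$. $(P1)$ feasible means $i$ can run without $j$;
  infeasible means $i \to j$. Both infeasible means at least partial
  coupling, resolved by maximizing and minimizing $v_j$ subject to
  $v_i = 1$: equal finite optima give full coupling with that ratio.
* **Irev/Prev** — the only admissible relation is $prev \to irev$. Test
  $(P2)\; \{v_{prev} = 1, v_{irev} = 0\}$ and its backward complement
  $(P3)\; \{v_{prev} = -1, v_{irev} = 0\}$; both infeasible means
  $prev \to irev$, otherwise uncoupled.
* **Prev/Prev, Frev/Frev** — only full coupling is admissible, and on these
  types it is equivalent to a statement about the plain kernel: with
  blocked columns removed from $S$ and **no** non-negativity constraints,
  $(P4)\; \{S'v = 0, v_i = 0, v_j = 1\}$ is infeasible iff $i
  \Leftrightarrow j$. One feasibility test decides the pair, on a smaller
  system.
* **Irev/Frev, Prev/Frev** — cannot couple; reported uncoupled with zero
  LP calls.

Non-negativity in $(P1)$–$(P3)$ is imposed on $Irr \cup Irev$ of the
sign-normalized network. Adding the Irev class does not change the solution
set — those reactions are single-signed at steady state by definition — but
makes the systems match the case dispatch's assumptions explicitly.

The decision in the Irev/Irev "both infeasible" branch needs optimality,
not just feasibility; that is the one place FFCA solves LPs to optimality,
and the reason full vs partial distinction costs two extra LPs there. For
$(P4)$-decided pairs the procedure itself never computes a ratio; we
recover it afterwards from one kernel vector of the reduced system with
$v_i = 1$ (on that subspace $v_i = 0 \Rightarrow v_j = 0$ forces $v_j = k
v_i$ identically, so any witness yields $k$). This post-hoc ratio is an
extension beyond the bare decision procedure, reported for symmetry with
the Irev/Irev case.

Where the $(P4)$ case is sometimes described loosely as a system of linear
*inequalities*, the kernel equivalence it rests on holds with the
irreversibility constraints dropped; we follow the derivation, not the
loose phrase — the systems contain equalities and pins only.

## Reference implementations

The optimality-based flux-coupling-finder family is implemented for
cross-validation:

* `wfcf` — no splitting: for each feasible sign $s$ of $v_i$, minimize and
  maximize $v_j$ with $v_i = s$. By convexity the attainable $v_j$ values
  form exactly that interval, so "$i$ forces $j$" is "$0$ outside every
  interval". A collapsed interval is a constant ratio, and a constant
  non-zero ratio under forcing already implies full coupling (a point with
  $v_i = 0, v_j \ne 0$ added to a pinned witness would violate the ratio),
  which saves the reverse-direction LPs in that case.
* `wrfcf` — the same rule behind the reversibility-type prunings, with
  cheaper one-sided tests where the admissible relation is known (an Irev
  target is non-negative, so forcing needs only the minimum).
* `wrpfcf` — `wrfcf` with the Prev/Frev single-LP test.
* `fcf-split` — the classical algorithm: split every reversible reaction
  into forward and backward irreversible columns, compute per-direction
  flux intervals with the *partner column pinned to zero* (so a direction
  at unit rate carries no two-cycle component and the measured flux is the
  net flux), then merge: original $i$ forces original $j$ iff for every
  feasible direction of $i$ the attainable net flux of $j$ excludes zero.
  Removing a two-cycle from any flux vector stays inside the split cone
  and preserves net fluxes, so the union of the two partner-suppressed
  subcones reaches every net value — the merge is exact, and it must (and
  does, by test) reproduce the no-splitting result.

All variants share preprocessing and differ only in pairwise LP budget;
the suite asserts `fcf-split ≥ wfcf ≥ wrfcf ≥ wrpfcf` on every generated
network with at least one reversible reaction. LP counters count public
solver queries (one feasibility or one optimization each), the same
accounting used when comparing the methods.

## The exact oracle

On small networks the ground truth is computed without any LP: reversible
reactions are split, coefficients are rationalized (continued fractions,
denominator cap $10^6$) and each row rescaled to integers, and the extreme
rays of the split cone $\{x \ge 0, S_{split} x = 0\}$ are enumerated by the
double description method with the combinatorial adjacency test. All ray
updates are integer combinations reduced by their gcd, so zero/non-zero and
ratio judgments are exact. Two-cycle rays are discarded; the rest fold back
to original coordinates as the network's elementary flux modes.

Every steady-state flux is a conformal (cancellation-free) sum of these
modes, so: blocked = zero in every mode; $i \to j$ iff every mode active in
$i$ is active in $j$; full coupling iff mutual with one exact flux ratio
across all modes active in $i$ (integer cross-multiplication; modes from
the lineality space participate like any others, which settles how ratios
involving Frev reactions are checked). The lineality-space basis is a
maximal independent subset (fraction-free elimination) of the modes
supported entirely on reversible reactions.

Cone rays admit only positive rescaling, and folded rays may have a
negative leading entry, so the canonical form is "integer entries divided
by their gcd, rows sorted lexicographically" rather than "first non-zero
entry one"; this is equally deterministic.

The oracle refuses networks above `max_reactions = 16` by default
(combinatorial growth); it is a verification instrument, not a production
method.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_feas` | 1e-9 | constraint tolerance of the LP backend (pivot threshold; dimensionless, fluxes are normalized to pins of 1) |
| `zero_tol` | 1e-8 | magnitude below which a witness entry counts as zero when supports are inspected |
| `eps_ratio` | 1e-6 | max allowed gap between the max- and min-ratio LPs for declaring a constant ratio |
| `max_reactions` | 16 | oracle enumeration cap |
| `max_den` | 1e6 | denominator cap when rationalizing coefficients for the oracle |

The defaults suit integer or simple-fraction stoichiometries, where pivots
stay far from the tolerances. The feasibility thresholds are our choice
(solver tolerances for this procedure are not standardized); all are
exposed through `ffca_tol()` and the CLI flags `--eps-feas`/`--eps-ratio`.

## Numerical choices

The LP backend is a dense two-phase primal simplex (Rcpp) with Bland's
rule, which guarantees termination on the degenerate tableaus these
homogeneous systems produce constantly. Infeasibility is the phase-1
optimum exceeding its tolerance; unboundedness is an improving column with
no blocking ratio, reported as a first-class status (the relevant outcome
"no finite ratio", never folded into infeasibility). A solver breakdown
(iteration limit) raises an error rather than guessing — the method's
correctness hinges on trusting infeasibility verdicts. Pinned variables
are eliminated by substitution before solving; free variables are split
into positive and negative parts.

Degenerate inputs follow the definitions literally: an all-zero column is
unblocked (any value satisfies $Sv = 0$), and is Frev if model-reversible,
Irev otherwise. Pair iteration is lexicographic over $(i, j)$, $i < j$, in
input column order, and no coupling information is propagated between
pairs — each pair is decided by its own systems, keeping the behaviour
exactly the published procedure's (a transitive-closure shortcut would
change LP counts, not results).

## What the synthetic generator does and does not emulate

The verification suite draws 200 networks with 2–6 metabolites, 3–12
reactions, integer coefficients in $\{-3,\dots,3\}\setminus\{0\}$ at
density 0.3–0.8, 1–2 single-metabolite exchange columns and a reversible
fraction between 0 and 0.6. Those sizes keep the exact oracle fast while
covering all reversibility types, blocked reactions, lineality spaces of
dimension $\ge 1$ and every coupling relation; the suite and all of its per-network seeds
derive deterministically from one base seed. Problem sizes were chosen so
the whole dual-route comparison (five methods × 200 networks) completes in
about a minute on one core.

Real genome-scale models differ in ways the generator does not imitate:
thousands of reactions, highly skewed degree distributions, many more
blocked reactions, and stoichiometries like 0.01 from lumped biomass
equations. Passing the suite therefore demonstrates correctness of the
decision logic on exact arithmetic-scale instances, not numerical
robustness at genome scale or any particular published model's counts —
reproducing published full-scale tables additionally depends on the
model files and on how each study identified external metabolites, which
is not part of this package's test surface.

## Known limitations

* The oracle's double description step has no compression or bit-pattern
  optimizations; it is deliberately small-scale.
* SBML support covers the stoichiometric subset only (no gene rules,
  objectives, or flux-bound arithmetic) — by design, since the cone uses
  none of them.
* The simplex backend is dense; genome-scale models would want a sparse
  LP engine behind the same `feasibility_system` interface (the backend is
  a single choke point by construction).
* Coupling is computed for the full network only; subnetwork-restricted
  or bounded-flux variants are out of scope.
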