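# ffca — feasibility-based flux coupling analysis of metabolic networks

Flux coupling analysis (FCA) asks, for every pair of reactions in a
stoichiometric metabolic network, whether activity of one reaction at steady
state forces activity of the other. Over the steady-state flux cone

```
C = { v ∈ R^n : S·v = 0,  v_i ≥ 0 for all i ∈ Irr }
```

(with `S` the m×n stoichiometric matrix and `Irr` the irreversible
reactions), two unblocked reactions `i`, `j` are

* **directionally coupled** (`i → j`) if `v_i ≠ 0` implies `v_j ≠ 0` for all
  `v ∈ C`;
* **partially coupled** (`i ↔ j`) if coupled in both directions;
* **fully coupled** (`i ⇔ j`) if additionally `v_j / v_i = k` for a fixed
  constant `k`;
* **uncoupled** otherwise.

FCA is used throughout constraint-based modelling — network evolution, gene
essentiality, interpretation of measured fluxes, regulation — and this
package is for anyone who needs those relations from an SBML or plain-text
model: it implements **FFCA**, which decides each pair by testing small
linear systems for *feasibility* (an LP with constant objective, so the
solver can stop at the first feasible basis) instead of solving LPs to
optimality.

The pairwise tests operate after preprocessing (blocked-reaction detection
and classification of the unblocked reactions into `Irev`, `Prev`
(pseudo-irreversible) and `Frev` (fully reversible)), and exploit two
structural facts:

* **Reversibility-type prunings** — of the 3×3 type combinations only four
  can couple at all: Irev/Irev (any relation), Irev/Prev (only
  `prev → irev`), Prev/Prev and Frev/Frev (only full coupling). The
  remaining combinations are reported uncoupled with zero LP calls.
* **Prev/Frev improvement** — for a Prev/Prev or Frev/Frev pair, full
  coupling is equivalent to "`v_i = 0` implies `v_j = 0` on the kernel of
  `S` with blocked columns removed", so a *single* feasibility test on a
  smaller, inequality-free system decides the pair.

For cross-validation the package also ships the classical optimality-based
flux-coupling-finder algorithm (with reversible-reaction splitting and
post-processing, `fcf-split`) and its improved variants (`wfcf`, `wrfcf`,
`wrpfcf`), plus an exact-arithmetic oracle for small networks that
enumerates the elementary flux modes by the double description method and
reads all relations off their co-activity patterns. All methods produce
identical coupling matrices; they differ only in LP budget.

## Worked example

A three-step pathway with a 1:2 stoichiometric step (uptake → A, A → 2 B,
B → export):

```r
library(ffca)
net <- fixture_network("COEF2")
fc  <- flux_coupling(net)
tidy(fc)
#> # A tibble: 3 × 6
#>       i     j rxn_i rxn_j relation ratio
#>   <int> <int> <chr> <chr> <chr>    <dbl>
#> 1     1     2 R1    R2    full         1
#> 2     1     3 R1    R3    full         2
#> 3     2     3 R2    R3    full         2
glance(fc)
#> # A tibble: 1 × 9
#>   method n_total n_unblocked n_blocked fully partially directionally uncoupled lp_calls
#> 1 ffca         3           3         0     3         0             0         0       15
```

Every pair is fully coupled (a single linear pathway), and the balance of
metabolite B fixes `v_R3 = 2·v_R2`, so the reported ratio for (R2, R3) is 2.
The run needed 15 LPs: 3 feasibility tests in preprocessing and 12 in the
Irev/Irev pairwise case. `autoplot(fc)` draws the coupling matrix;
`write_coupling_table()` writes the integer-code TSV with the
blocked/Irev/Prev/Frev footer.

A shell front end is installed as `exec/ffca`:

```sh
ffca synth --fixture COEF2 --out model.tsv
ffca analyze model.tsv --method ffca --out couplings.tsv --report report.json
ffca classify model.tsv
```

`--method` selects `ffca`, `wrpfcf`, `wrfcf`, `wfcf`, `fcf-split` or
`oracle` (small networks only).

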