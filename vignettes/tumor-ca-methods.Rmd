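---
title: "The tumorca model: stochastic rule, engines, and seam-based load balancing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumorca model: stochastic rule, engines, and seam-based load balancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(tumorca)
```

## The model

`tumorca` simulates avascular tumor growth as a stochastic cellular
automaton on a finite 2-D lattice. A site holds at most one tumor cell
(state $\varepsilon = \{0, 1\}$); borders are fixed, and out-of-bounds
sites behave as permanently occupied. Once per simulation step, every
live cell at position $r$ draws one uniform $rr \in [0,1)$ and its fate
is read off a partition of the unit interval:

* $rr \ge W$ — the cell **dies** and its site is cleared; $1 - W$ is the
  per-step death probability.
* $rr < W'$ — the cell receives a **proliferation signal**: its counter
  `PH` is incremented, and once `PH` reaches the threshold `NP` the cell
  attempts **mitosis** into an empty neighboring site; on success the
  daughter starts with `PH = ph_init` and the parent's counter resets
  to 0.
* otherwise — a second uniform against $W''$ decides a **migration**
  attempt into an empty neighboring site.

A cell whose attempt finds no empty site, or that takes neither branch,
stays **quiescent** (the $G_0$, non-mitotic phase). Candidate target
sites are the 4 axial (von Neumann) neighbors by default, scanned in
RNG-shuffled order so that direction choice is unbiased and an attempt
succeeds whenever *any* candidate is free; the 8-site Moore set is
available via `model_params(neighborhood = "moore")`.

The single-draw partition is deliberate: the death and signal tests
reuse the same draw, so the three branches are disjoint intervals
$[0, W')$, $[W', W)$, $[W, 1)$ whenever $W' \le W$ (which the default
parameter set satisfies). The alternative — independent draws for death
and signal — would change the fate distribution (division probability
$(1-W^c)W'$ instead of $W'$); we implement the partition literally and
verify it against its analytic probabilities in the test suite.

### Parameters and defaults

| name | meaning | default |
|---|---|---|
| `p_survive` ($W$) | per-step survival probability | 0.8 |
| `p_signal` ($W'$) | chance of a proliferation signal | 0.2 |
| `p_migrate` ($W''$) | chance a non-signaled survivor tries to move | 0.25 |
| `np_threshold` (`NP`) | signals required before mitosis | 1 |
| `ph_init` (`PH`) | starting signal counter of seeds and daughters | 1 |
| `delta` ($\delta$) | longest per-step displacement (rows/cols) | 1 |

With the defaults the analytic per-evaluation fate distribution for a
cell with free neighbors is P(die) = 0.2, P(divide) = 0.2,
P(migrate) = 0.6 × 0.25 = 0.15, P(quiescent) = 0.45; the acceptance
suite checks the empirical frequencies at $n = 10^6$ to ±0.005.

### A note on the default dynamics

The default parameter set is *critical*: when space is free, a cell's
expected number of successors per step is exactly
$0.2 \cdot 0 + 0.2 \cdot 2 + 0.6 \cdot 1 = 1$, and crowding only pushes
it below 1. The live-cell count is therefore a supermartingale, and a
tumor grown from a single seed goes extinct with probability one —
typically within a few steps, occasionally after a few hundred
evaluations. Long single-seed runs under the defaults consequently end
at size 0; sustained growth to $10^5$-cell masses requires a
supercritical parameter choice (for instance a higher `p_survive`).
This is a property of the published rule and parameter values
themselves, not of the implementation; the test suite pins the analytic
fate frequencies, exact engine equivalences, and all structural
invariants independently of it, and uses immortal
(`p_survive = 1`) or mildly supercritical (`p_survive = 0.95`) variants
wherever a test needs a tumor that reliably survives and loads the
partition machinery.

## Engines

### Sequential two-list engine

Work should scale with the tumor, not the lattice, so live cells are
kept on an active-cell list: the current list is consumed in order,
each cell's fate is applied to the lattice *in place*, and survivors
plus daughters are appended to the next list, which becomes current at
the step boundary. Because updates are in place, a target chosen as
empty can be taken by an earlier-processed cell in the same step; the
loser simply stays quiescent that step. Daughters are first evaluated
in the step after their birth. Processing order is list order; the
model's distribution of interest is order-insensitive, and a
`sort_cells_rowmajor()` helper exists to put the list engine on the
exact path of the oracle engine.

```{r}
st <- init_state(64, 64, "center", model_params(p_survive = 1), seed = 7)
out <- run_simulation(st, 60)
tail(out$metrics, 3)
```

### Full-grid oracle engine

`step_oracle()` is the naive scheme the list engine replaces: scan
every lattice site in row-major order and evaluate the cells that were
live at the start of the step, spending RNG draws only on live cells.
When the active list is sorted row-major, both engines visit the same
cells in the same order with the same draws, so their next states are
*bit-identical* — an exact, independently-coded cross-check that the
test suite runs over hundreds of randomized states.

### Phase-ordered parallel engine

The lattice is divided into `t` horizontal regions, one per worker,
each split top seam part / center / bottom seam part (border regions
lack their outward seam part). Every existing part is at least $\delta$
rows high, so any two same-type parts are separated by at least
$2\delta$ rows of other-type parts. Since no cell moves farther than
$\delta$ per step, workers that simultaneously process all subregions
of one *type* can never write into the same subregion's next list:
the step runs bottom seams, then centers, then top seams, with a
barrier between phases and no locks inside them. After the third
barrier a coordinator records metrics, decides load balancing, and
swaps the lists.

The concurrency model is a contract, not a primitive: `tumorca`
realizes it as a serialized phase schedule — one legal interleaving of
the concurrent execution — which keeps runs bit-reproducible for a
fixed master seed and worker count while satisfying the same
post-conditions (phase ordering, write-disjointness, census
conservation). Write-disjointness is not assumed but measured: every
next-list append carries the writing worker's tag, and two distinct
writers within one phase would be counted as an ownership violation;
the suite asserts the count stays zero, including in runs engineered to
keep cells flowing across a busy seam.

Each worker draws from its own splitmix64 stream keyed on
(master seed, region index, step), so results do not depend on worker
scheduling and replay exactly. The sequential engines instead consume
R's global RNG (`set.seed()`-reproducible). Sequential and parallel
runs therefore never match bitwise — evaluation order and streams
differ — and equivalence is assessed distributionally: final tumor
sizes over independently seeded runs, compared with a two-sample
Kolmogorov–Smirnov test (`equivalence_check()`; final sizes are
integers, so ties occur and the asymptotic KS p-value is used, which is
conservative).

### Load balancing

After every step the coordinator takes the per-region lattice census.
For an adjacent pair with counts $c_i, c_{i+1}$ the relative imbalance
is $100\,|c_i - c_{i+1}| / \max(c_i, c_{i+1}, 1)$ percent — the
$\max(\cdot, 1)$ bounds it in $[0, 100]$ and keeps it defined for empty
regions. Pairs above the threshold $\rho$ start a seam move shrinking
the larger region, most-imbalanced first, ties to the lower seam; a
seam that is active, or adjacent to an active or just-selected seam, is
skipped (adjacent moves would shrink or grow one region from both
sides while its lists are in flight), and so is a move whose shrinking
center could not give up $\delta$ rows and stay $\ge \delta$ high
(aborting instead at phase 1 if geometry has changed since the
decision).

A move shifts the boundary by $\delta$ rows in three coordinator
rounds: (1) the seam part on the shrinking side absorbs $\delta$ rows
from its center, becoming $2\delta$ thick; (2) those rows are handed
across the boundary to the other seam part, conserving total seam
thickness; (3) the enlarged part releases $\delta$ rows into the
growing center. At every intermediate state all parts are $\delta$ or
$2\delta$ thick and the $2\delta$-separation argument still holds, so
no phase ever lets two workers share a next list. Cell-list membership
is *not* updated when the geometry moves; cells are processed from
whatever list they are on, and their outputs are routed by the current
geometry — the lazy reconciliation that keeps the coordinator O(t).

```{r}
out <- run_parallel(100, 100, "center", model_params(p_survive = 1),
                    n_steps = 120, n_workers = 4, rho = 5, master_seed = 2)
tail(out$metrics, 3)
out$region_counts[120, ]   # balanced load
out$seam_rows[c(1, 120), ] # seams have spread with the tumor
```

## Numerical and design choices

* **Coordinates** are 1-based with row 1 the topmost lattice row; row
  bands are half-open `[start, end)` so heights are `end - start`.
* **Initial seams** are spread evenly over a band of height
  $H^0 = \max(\text{tumor height}, 3\delta t)$ centered on the seed
  mass (integer-balanced heights, so every interior region is at least
  $3\delta$ high even after rounding), then the first and last regions
  are extended to the lattice edges.
* **PH lifecycle**: `evaluate_cell()` increments `PH` on a signal and
  resets it to 0 when it returns a division fate; if the chosen target
  was meanwhile taken, the parent keeps the reset counter — the reset
  is tied to the decision, not to its success. Daughters start at
  `ph_init`. With the default `NP = 1` the counter is inert; the
  machinery matters only for `NP > 1`.
* **Degenerate inputs**: an empty seed list is a valid absorbing state;
  `n_steps = 0` is the identity; duplicate or out-of-bounds seeds,
  probabilities outside $[0,1]$, $\rho < 0$, and lattices shorter than
  $3\delta t$ are rejected with named errors.
* **Problem sizes in the test suite** were chosen to exercise each
  property at the smallest scale that makes it non-trivial: 20×20
  randomized states for exact oracle equivalence, 200×200 / 300-step
  runs with 30 runs per arm for the KS comparison, 1000 randomized
  partition walks for the geometry invariants, $10^6$ draws for the
  fate frequencies, and 700×700 / 4000-step runs (five seeds) for the
  reference-experiment recomputation in `scripts/acceptance.R`.

## What the simulator does and does not capture

The model is deliberately minimal: homogeneous cells, no nutrient or
oxygen fields, no proliferation-capacity/telomere bookkeeping, no
distinction between apoptosis and necrosis, no 3-D lattices, and no
vascularization. Passing tests show that the implementation honors this
rule set and its concurrency contract exactly; they say nothing about
how well the rule set approximates any real tumor. Timing quantities
(cells processed per second in the sweep tables) depend on hardware and
are reported for information only — throughput and speedup claims are
outside what this package can reproduce or verify.
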