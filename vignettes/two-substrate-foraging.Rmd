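---
title: "A two-substrate foraging model: mechanics, information metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-substrate foraging model: mechanics, information metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(chemforage)
```

## The model

`chemforage` simulates a population of rod-like motile cells of length
$\ell = 2$ on a one-dimensional periodic lattice of $N = 100$ sites. Two
essential substrates, A and B, are laid out as static von Mises
concentration profiles,
$$C_i \;=\; \frac{C_{max}\, e^{\kappa \cos(2\pi (x_i - \mu_C)/L)}}{L\, I_0(\kappa)},$$
peaked at $\mu_A = 25$ and $\mu_B = 75$ with $\kappa = 0.1$ and
$C_{max} = 500$ by default. The fields never deplete: cells are assumed
dilute relative to the resource supply. The von Mises form is the
maximum-entropy choice on a ring for a fixed circular mean and variance, so
the cells are given a gradient and nothing else.

Each cell carries internal stores $A_{in}, B_{in}$ (real-valued molecule
counts), and a fixed budget of $R_{tot} = 400$ receptors divided between
A-specific and B-specific types, half of each type on each end of the cell.
One time step ($\Delta t = 1$) is a fixed cycle:

1. **Absorb.** Each store gains
   $\big(k\,\tfrac{C(x-1) + C(x+1)}{2} - S\big)\Delta t$, where $k$ is the
   absorption coefficient and $S$ the basal maintenance cost. A store driven
   negative is clamped to zero, independently per substrate; the consequences
   are assessed at the end of the cycle.
2. **Sense.** The bound-receptor count on each end is binomial: $n$ trials
   (that side's receptor budget) with success probability
   $C/(K_d + C)$ evaluated at that end, $K_d = 2$. The four channels
   (A-right, A-left, B-right, B-left) are independent. A Gaussian variant
   with the binomial mean and $\gamma$-scaled binomial variance (rounded,
   clipped to $[0, n]$) is used for noise sweeps.
3. **Move.** Displacement is the right-minus-left bound-receptor excess
   $\psi = A_R^* + B_R^* - A_L^* - B_L^*$, clipped to $[-v_{max}, v_{max}]$
   ($v_{max} = 10$); positions wrap around the ring.
4. **Reallocate.** The *equal* strategy keeps $A_{tot} = B_{tot} = R_{tot}/2$.
   The *adaptive* strategy sets
   $B_{tot} = \mathrm{round}\!\big(R_{tot}\, A_{in}/(A_{in}+B_{in})\big)$ —
   receptors flow toward the internally scarcer substrate.
5. **Assess.** A cell dies when either store has hit zero; otherwise it
   divides when both stores strictly exceed the threshold $D = 5S$ (the
   reserve needed to survive five maintenance steps), leaving two daughters
   at the same site with half the stores each; otherwise it continues.

A third behavioral variant, `random_move`, replaces step 3 with a uniform
integer displacement in $[-v_{max}, v_{max}]$ (the allocation stays equal);
it serves as the non-chemotactic baseline.

## Population bookkeeping

Cells do not interact, so the population is embarrassingly parallel; the
implementation updates all cells as vectors in a fixed order, which cannot
change the law of the process but makes runs bit-reproducible under a fixed
seed. Daughters are appended at the end of a step and first act in the next
one; a freshly divided cell cannot divide twice within a step.

To keep the exponentially growing population tractable, the run carries a
cap: whenever the environment cell count strictly exceeds `cell_max`
(default 10000), cells are removed uniformly at random down to
`cell_adjusted` (9000) — uniform subsampling preserves the spatial
distribution in expectation — and a running multiplier is scaled by
`count_before / cell_adjusted`. The *real* population count, environment
cells times the multiplier, is what the growth metric consumes; the
multiplier is kept real-valued precisely so that the repeated ratio does not
accumulate rounding bias, and the growth rate is invariant under any
constant rescaling of the series.

## Metrics

All estimators are plug-in (empirical histogram) quantities in bits.

* **Growth rate** $G_T$: the mean over retained steps of
  $\log_2(P_{j+1}/P_j)$ on the real-count series — log2 doublings per step.
  Steps inside an initial transient window (default the first third of the
  run) are discarded; runs that hit zero report `NA` (extinction).
* **Per-cell MI.** Each cell-step contributes four (input concentration,
  bound count) samples, one per channel. Samples are pooled by
  receptor-allocation key $(A_{tot}, B_{tot})$ across all cells and times,
  and a cell's MI is *its group's* estimate
  $MI_{cell} = \sum_{ch} MI(\text{input}_{ch}, \text{output}_{ch})$ — the
  four channels are treated as independent and added. Pooling by allocation
  is the reading under which all equal-strategy cells, operating one and the
  same channel, receive an identical value; estimating per individual
  trajectory instead would manufacture spurious across-cell spread out of
  sampling noise.
* **MI(T)**: the average of $MI_{cell}$ over every (cell, step) occurrence
  after the transient, each occurrence weighted equally. The summed input
  entropy $H(X)$ and conditional entropy $H(X|Y)$ are averaged the same way,
  and satisfy $H(X) - H(X|Y) = MI$ exactly on the shared histograms.
* **Subjective information** $SI$: at each step, the population standard
  deviation (divisor $n$) of $MI_{cell}$ across the cells present; $SI$ is
  the time average of these spreads. A single-allocation population has
  $SI = 0$ identically; heterogeneous channel tuning makes it positive.
  Steps with fewer than two cells contribute zero spread.
* **Cell stress** $c^* = S/k$: the break-even ambient concentration below
  which a cell loses a substrate. With the default field (per-site
  concentrations 4.5–5.5), stress begins to bite only as $c^*$ approaches
  4.5.

## Numerical choices

* **Binning.** Inputs take at most $N$ distinct static field values per
  channel and outputs are integers, so the default binning treats every
  distinct value as its own bin — exact for this simulator, including the
  Gaussian variant (outputs are rounded). Equal-width binning with a
  configurable bin count is available for continuous data.
* **Sparse groups.** The adaptive strategy spreads cells over up to
  $R_{tot}+1$ allocation keys. Keys with fewer than `min_group_n` samples
  (default 10) merge into the nearest well-populated key before estimation,
  since plug-in MI on tiny groups is badly biased.
* **Integer receptor arithmetic.** The adaptive rule rounds to integer
  counts; a side budget is `floor(tot/2)` on the left and the remainder on
  the right, so $A_{tot} + B_{tot} = R_{tot}$ holds exactly even for odd
  allocations.
* **Degenerate allocation.** A cell with $A_{in} + B_{in} = 0$ (only at
  birth or on the brink of death) splits its receptors equally — the
  unbiased choice for an uninformative internal state.
* **Thresholds.** "Exceeds the division threshold" is implemented as a
  strict inequality; a store exactly at $D$ does not trigger division.
  Death tests exact equality with zero, which is well-defined because the
  clamp writes an exact 0.
* **Initial stores** default to zero, with death assessed only after the
  first absorption, so founders seeded in viable locations survive step one.

## Regimes, and what the defaults can and cannot show

The model has a sharp saturation regime that is worth understanding before
interpreting any sweep. The per-substrate net gain per step is
$g = k\bar C - S$ with $\bar C$ the local two-end average concentration.
A post-division cell holds roughly one division's worth of reserve, so
division recurs every step whenever $2g > D = 5S$, i.e. whenever
$\bar C > 3.5\, c^*$. With the default field ($\bar C \approx 5$) this is
true *everywhere* for every $c^* \lesssim 1.4$: every cell divides every
step, deterministically, and $G_T$ pegs at exactly 1 bit/step regardless of
strategy — movement, sensing noise, and allocation are all irrelevant to
growth because death is impossible (minimum concentration 4.51 exceeds every
such $c^*$). In this regime the growth side of the equal-versus-adaptive
comparison is a tie by construction, and only the information-side metrics
(MI(T), $SI$) distinguish the strategies. Stress sweeps over
$c^* \in [0.2, 1]$ with the default field therefore produce flat growth
curves; for stress to shape growth and survival, $c^*$ must be pushed into
the range of the field values themselves (for example sharper fields,
$\kappa = 2$, where the antiphase peaks create genuinely lethal zones — the
configuration used by the test suite to exercise death, selection and
spatial clustering).

A second caveat concerns the MI estimates. The plug-in estimator's upward
bias is roughly $(|X|-1)(|Y|-1)/(2 N_s \ln 2)$ bits for $N_s$ samples. The
equal strategy pools everything into one group with hundreds of thousands of
samples, so its bias is negligible; the adaptive strategy spreads the same
samples over ~50 groups, each with ~100 distinct inputs and outputs, adding
an appreciable positive bias to every group estimate. At the default run
size, comparisons of MI(T) *between* strategies are therefore confounded by
bias in the direction of the adaptive strategy unless the sample count per
group is grown substantially or the binning is coarsened; comparisons
*within* a strategy across conditions are on safer ground. The estimators
themselves are verified against exact double-sum oracles in the test suite.

## What the simulated data do and do not emulate

The generator produces the study conditions themselves — static antiphase
resource fields, a clonal population with no cell-cell interaction, no
substrate depletion, no receptor conversion cost, memoryless motility — so
passing tests demonstrate correctness of the mechanics and estimators under
these idealizations, not fidelity to any real microbial system. In
particular, real chemotaxis has temporal-comparison memory (run-and-tumble),
real populations compete for resources, and real receptor reallocation is
slow and costly; none of that is modeled.

## Problem sizes

The test suite runs populations up to the default cap of 10000 environment
cells for 31 steps (the sweep conditions: both strategies, $k = 1..5$ at
$S = 1$, five paired seeds), and uses smaller capped runs (a few hundred
cells, 10–40 steps) for mechanical unit tests; Monte-Carlo moment checks use
$10^5$ draws. These sizes were chosen so the whole suite exercises the full
study configuration while completing in a few minutes.
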