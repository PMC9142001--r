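# chemforage

An agent-based simulator of single-celled organisms foraging for **two
essential substrates** on a one-dimensional periodic lattice, together with
the information-theoretic and demographic metrics needed to ask: *does a cell
that maximizes information about its environment also maximize its growth?*

The package is aimed at researchers studying the fitness value of
information — chemotaxis, sensing noise, and bet-hedging — who want a small,
fully reproducible in silico system in which the sensing channel of every
individual can be measured exactly.

## The model in brief

Cells of length $\ell = 2$ live on a ring of $N = 100$ sites carrying static
von Mises concentration profiles of substrates A and B,

$$C_i = \frac{C_{max}\,\exp\{\kappa\cos(2\pi(x_i-\mu_C)/L)\}}{L\,I_0(\kappa)},$$

peaked at $\mu_A = 25$ and $\mu_B = 75$. Each time step a cell:

1. **absorbs** each substrate at rate $k\,\bar C - S$ (two-end average
   concentration $\bar C$, maintenance cost $S$), stores clamped at zero;
2. **senses** through noisy receptors: the bound count on each end is
   $\mathrm{Binomial}(n,\, C/(K_d + C))$ over that side's share of a fixed
   budget of $R_{tot} = 400$ receptors (or a Gaussian variant whose variance
   is scaled by a noise factor $\gamma$);
3. **moves** by the clipped right-minus-left excess of bound receptors,
   $\Delta i = \mathrm{clip}(A_R^*+B_R^*-A_L^*-B_L^*,\, \pm v_{max})$;
4. **reallocates** its receptor budget — *equal* ($A_{tot}=B_{tot}$) or
   *adaptive* ($B_{tot} = R_{tot}\,A_{in}/(A_{in}+B_{in})$, receptors flow to
   the scarcer internal store);
5. **divides** when both stores exceed $D = 5S$ (daughters split the stores)
   and **dies** when either store hits zero.

A capping scheme (subsample to `cell_adjusted` whenever the population
exceeds `cell_max`, tracked by a real-valued multiplier) keeps exponential
growth tractable without biasing the growth rate
$G_T = \langle \log_2 P_{j+1}/P_j \rangle$.

From the per-cell sensing samples the package estimates, by plug-in
histograms: the per-cell mutual information
$MI_{cell} = \sum_{ch} MI(\text{input}, \text{bound count})$ over the four
channels (pooled by receptor-allocation group), its population-time average
$MI(T)$, input and conditional entropies, and the **subjective information**
$SI$ — the time-averaged across-population standard deviation of
$MI_{cell}$, which is exactly zero when every cell operates the same channel
and positive when individuals tune their channels differently.

## Worked example

```r
library(chemforage)

cfg <- sim_config(strategy = "adaptive", steps = 31, seed = 1)
sim <- run_simulation(cfg)
sim
#> Two-substrate foraging simulation: 31 steps, strategy 'adaptive'
#>   founders: 100   final real count: 1.0737e+11 (env cells 9000 x multiplier 1.193e+07)
#>   divisions: 219700   deaths: 0   capped steps: 24

compute_metrics(sim)
#> Foraging run metrics (transient discarded):
#>   growth rate G_T : 1 bits/step
#>   MI(T)           : 0.7369 bits
#>   H(X) / H(X|Y)   : 18.93 / 18.19 bits
#>   subjective info : 0.3898 bits
#>   cell stress c*  : 1   (steps used: 21)
```

The growth rate of exactly 1 bit/step says the population doubled every
retained step: at cell stress $c^* = S/k = 1$ the ambient concentrations
(4.5–5.5 molecules/site) are so far above break-even that every cell divides
every step — see the vignette for this saturation regime and its
consequences. The positive subjective information (0.39 bits) reflects the
adaptive cells occupying many different receptor allocations; an
equal-allocation run reports `SI = 0` identically.

Sweeps over stress or sensing noise return tidy replicate tables:

```r
sw <- run_stress_sweep(k_values = c(1, 2), strategies = c("equal", "adaptive"),
                       replicates = 2,
                       base = sim_config(steps = 20, cell_max = 2000,
                                         cell_adjusted = 1500))
aggregate_sweep(sw)[, c("strategy", "c_star", "GT_mean", "MI_T_mean", "SI_mean")]
#>   strategy c_star GT_mean MI_T_mean SI_mean
#> 1 adaptive    0.5       1     3.666    1.43
#> 2 adaptive    1.0       1     3.912    1.63
#> 3    equal    0.5       1     0.501    0.00
#> 4    equal    1.0       1     0.501    0.00
```

A thin command-line front end is included for shell use:

```sh
Rscript inst/scripts/forage-sim.R --config run.yaml --out results/ --seed 42
```

writing `steps.csv`, `density.csv`, `channels.csv` and `summary.json`.

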