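# cpmsort

Connectivity-preserving Cellular Potts simulations of differential-adhesion
cell sorting, with the observables and scaling analysis needed to measure
the coarsening kinetics of two-dimensional binary cell mixtures.

## What problem this solves

When two randomly mixed cell populations segregate into homogeneous domains
(cell sorting, a basic collective behavior in development and regeneration),
the question of *which kinetic law* governs the coarsening — logarithmic,
$t^{1/3}$, $t^{1/4}$ — discriminates between mechanisms such as
evaporation–condensation of single cells or fragments versus diffusion and
coalescence of whole clusters. Standard Cellular Potts Model (CPM)
simulations muddy this comparison because their update rule lets cells
fragment at any workable temperature, opening a nonphysical
fragment-mediated evaporation channel. This package implements a modified
Metropolis update that applies a **local connectivity test at every copy
attempt**: the sites holding the candidate and target cell IDs within the
Moore neighborhood of the copy site must each form a single connected set.
Starting from simply connected cells, the test provably keeps every cell one
connected component — no fragments, no multiply connected cells — which a
flood-fill audit verifies along every run.

The Hamiltonian is the minimal sorting energy
$$H = \sum_{\langle k,l\rangle} J_{\tau,\tau'}(1-\delta_{\sigma_k,\sigma_l})
      + \frac{B}{2A_0}\sum_i (A_i - A_0)^2,$$
with defaults $J_{BB}=J_{YY}=8$, $J_{YB}=14$, $J_{YM}=10$, $J_{BM}=22$,
$B=200$, $A_0=100$, $T=50$, and a 20-site fourth-order stencil for the
boundary sum. Dynamics accept a proposed single-site copy with probability
$\min(1, e^{-\Delta E/T})$; one MCS is one copy attempt per lattice site.
Observables: the boundary length $\Gamma(t)$ (heterotypic site contacts),
the spin-field autocorrelation $C(r,t)$ and its first zero $R(t)$ (cluster
size), and homotypic cluster counts. Analysis tools fit power-law exponents
on log-log windows, quantify the master-curve collapse of $C(r/R)$, and
evaluate the diffusion-coalescence prediction $m = 1/(2-d\alpha)$ (with
$\alpha=-1$: $1/4$ in 2D) and the detachment probability $e^{-\Delta E/T}$.

## Worked example

```r
library(cpmsort)
init <- build_aggregate(n_cells = 200, ratio_blue = 0.5, seed = 1)
init
#> CPM state: 260 x 260 lattice (free BC), 200 cells (100 B, 100 Y), 47600 medium sites

check_sorting_inequalities(default_J())
#> character(0)                       # defaults satisfy the sorting inequalities

run <- run_cpm(init, cpm_params(), mcs_total = 2000,
               sample_times = c(0, 10, 100, 500, 2000), seed = 1)
run$trace[, c("t_mcs", "gamma", "energy", "n_clusters", "acceptance", "max_components")]
#>   t_mcs gamma energy n_clusters acceptance max_components
#> 1     0  1930 550620          2         NA              1
#> 2    10  2571 598912         11 0.02863018              1
#> 3   100  2130 557849         12 0.02906920              1
#> 4   500  1740 524936         10 0.02937544              1
#> 5  2000  1308 493082          6 0.02990666              1

length(audit_detached_cells(run$state))
#> [1] 0
```

Reading the trace: `gamma` first rises from the blocky initial tiling as
interfaces roughen, then decays as same-type cells aggregate — at
$t = 2000$ MCS the heterotypic boundary is down to 68% of its random-mixture
value. `max_components = 1` at every sample is the connectivity guarantee:
the flood-fill audit found every one of the 200 cells to be a single
connected component. No cell is detached into the medium. Longer runs
(`mcs_total = 3e4` and up, see `scripts/`) reach the coarsening regime where
$\Gamma(t) \sim t^{-n}$ with $n \simeq 1/4$; `fit_exponent()` measures the
slope and `collapse_deviation()` verifies that $C(r, t)$ curves superimpose
once distances are rescaled by $R(t)$.

Setting `guard = FALSE` runs the standard, fragmentation-permitting CPM for
comparison — at $T = 50$ it fragments dozens of cells within $10^3$ MCS on
this same aggregate.

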