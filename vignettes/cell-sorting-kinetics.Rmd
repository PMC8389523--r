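---
title: "Connectivity-preserving Potts dynamics and the kinetics of cell sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-preserving Potts dynamics and the kinetics of cell sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmsort)
```

## The model

`cpmsort` simulates cell sorting in two-dimensional binary mixtures of
adhesive cells with a Cellular Potts Model (CPM, also called the
Glazier–Graner–Hogeweg model). Each biological cell is the set of lattice
sites sharing one integer ID $\sigma$; each cell carries a type
$\tau \in \{B, Y\}$ (blue, yellow), and a third type $M$ labels the fluid
medium surrounding the aggregate. The energy of a configuration is

$$
H \;=\; \sum_{\langle k,l \rangle} J_{\tau,\tau'}\,
  \bigl(1 - \delta_{\sigma_k, \sigma_l}\bigr)
\;+\; \frac{B}{2A_0} \sum_{\text{cells } i} \bigl(A_i - A_0\bigr)^2 ,
$$

where the first sum runs over neighboring site pairs and charges the contact
energy $J_{\tau,\tau'}$ to every pair of sites with unmatching IDs, and the
second is a quadratic compression penalty holding each cell's area $A_i$
near the nominal area $A_0$. The medium is a background phase: it has no
nominal area and is excluded from the second sum (a flag restores it for
experiments). No perimeter/cortical-tension term is included: sorting by
differential adhesion only requires the contact-energy inequalities below,
and a perimeter term is insensitive to how the two types are arranged.

Dynamics are modified-Metropolis: a *candidate site* is drawn uniformly at
random, a *target value* is drawn uniformly among its Moore (8-site)
neighbors, and the copy is accepted with probability
$p = \min(1, e^{-\Delta E/T})$, where $T$ is an effective temperature
modeling cellular activity. One Monte Carlo step (MCS) is as many copy
attempts as there are lattice sites.

## The connectivity guard

With the standard update rule the CPM does not conserve cell topology: at
working temperatures, small fragments detach from cells long before the
first T1 neighbor exchanges occur, biasing perimeters and centers of mass
and wasting simulation time on fragment shuffling. The package's central
algorithmic device is a *local connectivity test* applied at every copy
attempt: the copy is admissible only if, among the 8 Moore neighbors of the
candidate site, the sites holding the candidate (current) ID form a single
connected set, and likewise the sites holding the target ID. Connectivity
among ring sites uses 8-adjacency restricted to the ring. Starting from a
state in which every cell is simply connected, this local test is sufficient
to keep every cell a single connected component forever; the package ships a
global flood-fill audit (`audit_global_connectivity()`) that verifies
exactly this along every run, and the test suite drives the audit both after
individual accepted copies and at every sample time of full runs.

Three semantic choices deserve note, since a local rule alone does not pin
them down:

* **Ring adjacency is 8-adjacency.** Two diagonal ring sites touching only
  at a corner count as adjacent. The global audit — not the local rule — is
  the contract; the exhaustive $3^8$-pattern test and the run-time audits
  pin the semantics empirically.
* **The medium is exempt by default.** An aggregate may legitimately
  enclose medium pockets, so the medium region is not required to stay
  connected (`medium_exempt = FALSE` restores the symmetric rule).
* **Cells are never annihilated.** A copy that would erase a cell's last
  site is rejected (in guarded *and* standard mode), so the cell number N is
  conserved throughout.

The standard, fragmentation-permitting algorithm remains available
(`guard = FALSE`) for algorithm-comparison experiments; it differs from the
guarded chain only by the absence of the connectivity rejection.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| $J_{BB} = J_{YY}$ | 8 | homotypic contact energy per site pair |
| $J_{YB}$ | 14 | heterotypic contact energy |
| $J_{YM}$ | 10 | yellow–medium contact energy |
| $J_{BM}$ | 22 | blue–medium contact energy |
| $B$ | 200 | bulk modulus (area stiffness) |
| $A_0$ | 100 sites | nominal cell area |
| $T$ | 50 | effective temperature |
| Hamiltonian stencil | order 4 (20 sites) | smooths lattice anisotropy |
| proposal stencil | order 2 (Moore, 8 sites) | target-value draws |

These satisfy the sorting inequalities checked by
`check_sorting_inequalities()`: demixing requires
$J_{YB} > (J_{BB}+J_{YY})/2$, and the engulfment ordering $J_{YM} < J_{BM}$
makes yellow wet the medium, so sorted aggregates end as a blue core in a
yellow shell. The heterotypic excess $2J_{YB} - J_{YY} - J_{BB} = 12$ sets
the detachment barrier: with a barrier-to-temperature ratio of about 7.5 the
single-cell detachment probability $e^{-7.5} \approx 5.5\times10^{-4}$ is
negligible, which is why evaporation–condensation cannot drive coarsening
here. At these values $\Delta H/T \simeq J/T \simeq 0.2$, inside the regime
where the net Metropolis transition rate $1-e^{\Delta H/T}$ is close to its
linearization $-\Delta H/T$ (about 11% relative error, see
`small_delta_rate()`), so a temperature change mostly rescales time without
changing the kinetics.

The boundary sum uses the 20-site fourth-order stencil to smooth the
anisotropy of the square lattice; correspondingly the cell size $A_0 = 100$
keeps opposite sides of a cell out of each other's interaction range. The
proposal stencil stays at the Moore neighborhood: proposals from farther
shells could copy the ID of a non-touching cell and create an instant
fragment, and the connectivity test is defined on the Moore ring. Every
attempt — including no-op proposals and connectivity rejections, which both
consume real algorithm time — counts toward the MCS budget.

## Initial states

`build_aggregate()` realizes the standard starting condition: $N$ square
cells of $\sqrt{A_0}\times\sqrt{A_0}$ sites, tiled as the $N$ whole squares
closest to the lattice center (a rounded cluster in which every cell starts
at exactly $A_0$ sites), surrounded by a medium margin of $5\sqrt{A_0}$
sites per side by default. Exactly `round(ratio_blue * N)` cells are drawn
uniformly to be blue — exact counts, not binomial sampling, so the mixture
ratio is a controlled variable. The initial square shapes relax within a few
MCS and are irrelevant to long-time coarsening. `build_periodic()` tiles a
torus exactly (no medium) for boundary-condition comparisons. The outermost
lattice ring is frozen medium in free mode, and initialization guarantees
cells never reach it at the default margin.

## Observables

* **Boundary length** $\Gamma(t)$: the number of order-1 (von Neumann)
  neighboring site pairs whose sites belong to B and Y cells respectively —
  the classic sorting-progress metric. Cell–medium contacts are excluded by
  default (they persist after sorting completes); a flag includes them for
  sensitivity checks. Only power-law slopes are compared downstream, which
  are insensitive to the constant factor between contact counts at different
  stencil orders.
* **Autocorrelation** $C(r,t)$ of the spin field $s = +1$ (B), $-1$ (Y),
  medium excluded from all averages (setting it to 0 instead would bias the
  mean at the aggregate rim; results are invariant under swapping the spin
  signs). Pairs are binned into unit-width annuli around integer $r$; the
  sums are evaluated by FFT over all offsets simultaneously and integer pair
  counts are recovered by rounding, so the result is exact — the test suite
  compares it against a literal all-pairs loop.
* **Cluster size** $R(t)$: the position of the first zero of $C(r,t)$,
  located by linear interpolation between the bracketing bins; `NA` (caller
  should widen `max_r`) when the curve never crosses zero.
* **Cluster count** $N(t)$: 8-connected components of each type's site set.
  For rounded clusters $\Gamma \sim N R$ and mass conservation gives
  $N \sim R^{-2}$, hence $\Gamma \sim R^{-1}$.

## Scaling analysis

`fit_exponent()` fits the slope of $\log y$ vs $\log t$ over an explicit
window (default: the last 1.5 decades). Windows matter: once a finite
system approaches complete sorting, $\Gamma$ decays faster than any
coarsening law, so fits must precede the finite-size cutoff. For replicated
runs the package fits per seed and averages the exponents.

Coarsening theory enters through two closed forms. Diffusion-and-coalescence
of rounded domains with mobility $\propto$ mass$^{\alpha}$ gives the growth
exponent $m = 1/(2 - d\alpha)$; cells without aligning interactions have
$\alpha = -1$, hence $m = 1/4$ in 2D (and $1/5$ in 3D). The competing
evaporation–condensation (Ostwald/LSW) mechanism would give $1/3$, but its
elementary step — cell detachment — is exponentially suppressed (see above),
and with the guard enabled fragment-mediated evaporation is impossible by
construction. The guarded simulations accordingly coarsen with
$n = m = 1/4$ regardless of mixture ratio and boundary conditions, and
`collapse_deviation()` quantifies the dynamic self-similarity: late-time
$C(r/R(t))$ curves superimpose on a master curve.

## Problem sizes used by the shipped checks

The full study conditions (mixtures of $2\times10^3$–$3.2\times10^5$ cells
run for $10^6$–$2\times10^6$ MCS, five seeds) take on the order of a day of
single-CPU time; `scripts/kinetics_overnight.R` implements that protocol for
batch use. The regular test suite and `scripts/acceptance.R` run a
desk-scale version chosen to finish in minutes while still sitting inside
the coarsening regime:

* free-BC aggregates of $N = 300$ cells (50:50 and 20:80) and a periodic
  torus of $N = 200$ cells, default parameters, $3\times10^4$ MCS, two
  seeds for the even mixture;
* $\Gamma(t)$ exponents fitted on $[10^3, 3\times10^4]$ MCS — late enough
  that initial-tiling transients have relaxed, early enough that sorting is
  not complete at this $N$;
* connectivity audits on an $N = 200$ aggregate over $10^4$ MCS (guarded)
  and $10^3$ MCS (standard rule).

At this scale the even-mixture exponent lands near $1/4$ for both boundary
conditions and the collapse ratio is well below $1/2$. The collapse
comparison uses only curves from the coarsening regime — past the initial
transient and with $R(t)$ below about $45\%$ of the aggregate radius.
Beyond that point a desk-scale system holds just a handful of clusters,
$C(r,t)$ reflects their particular arrangement rather than a self-averaged
scaling form, and no master curve can be expected (at full scale this
restriction is immaterial because $R$ stays far below the system size). Two full-scale
features are *not* resolvable at desk scale and are deliberately left to the
overnight protocol: the extended even-mixture transient in which $R(t)$
grows as $t^{1/3}$ while clusters are still entangled (at small $N$ this
window is too short to fit), and the 20:80 boundary-length decay reaching
the $1/4$ slope (at $N = 300$ the minority clusters are so few that
coalescence events are rare within $3\times10^4$ MCS; the desk-scale checks
instead verify the uneven mixture's earlier entry into the rounded-cluster
regime via its smaller $R(t)$ at matched times).

## Numerical choices and degenerate inputs

* Energies are double precision; the incremental $\Delta E$ of a copy is
  exact to round-off against a full recompute (tested at $10^{-9}$
  relative).
* The engine's random stream is a xoshiro256++ generator seeded from R's
  RNG at each advance, so `set.seed()` gives bit-identical traces within
  this implementation while keeping per-attempt cost low.
* Candidate sites are drawn uniformly over all mutable sites (the whole
  torus, or the free-mode interior); boundary-restricted candidate lists
  would be faster but are omitted to keep the chain's law transparent.
* `first_zero()` requires a positive first bin and flags non-crossing
  curves rather than extrapolating. `autocorrelation()` refuses `max_r`
  beyond half a periodic lattice (minimum-image ambiguity).
* Degenerate requests error early with descriptive messages: non-symmetric
  $J$, non-positive $A_0$ or $T$, lattices too small for the aggregate plus
  margin, non-factorizable periodic tilings, copies of unknown IDs.

## Known limitations

* Two-dimensional square lattices only; no 3D, no hexagonal lattices, no
  perimeter or chemotaxis Hamiltonian terms, no motility or alignment
  models.
* The synthetic initial states are idealized (exact-area square cells,
  perfectly rounded cluster); real tissues start from segmented images with
  area and shape dispersion. Passing desk-scale tests demonstrates the
  coarsening physics of the model, not agreement with any particular
  experimental tissue.
* The MCS clock is algorithm-relative: the guarded and standard chains'
  MCS differ by a constant real-time factor that this package does not
  attempt to measure.
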