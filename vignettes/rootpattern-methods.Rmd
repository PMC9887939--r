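---
title: "Methods: a nonlocal shrub–sedge model of water-limited vegetation patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a nonlocal shrub–sedge model of water-limited vegetation patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rootpattern` simulates a two-species, water-limited vegetation system: a
clonal shrub (species 1, think *Guilandina bonduc*) expanding into a
grassland of a sedge (species 2, think *Cyperus atlanticus*). Three fields
evolve on a periodic domain: aboveground biomass densities $B_1$, $B_2$ and
soil-water content $W$, all in kg/m². Time is in years, space in metres.

$$
\partial_T B_i = G_B^{(i)}\,B_i\,(1 - B_i/K_i) - M_i B_i + \mathcal D_i,
\qquad
\partial_T W = P - L\,W - W\sum_i G_W^{(i)} + D_W \Delta W .
$$

Water input is the precipitation rate $P$ (mm/y); the package adopts the
convention 1 mm rainfall $\equiv$ 1 kg/m² of soil water, so $P$ enters the
water balance unscaled. Evaporation $L = N(1 - \sum_i R_i B_i/K_i)$ is
reduced by canopy shading and bounded below by $N(1 - R_1 - R_2) > 0$.

**Root augmentation.** The shrub draws water through laterally extended
roots whose reach grows with shoot size:
$\mathcal S_1(B_1) = S_{G_1}(1 + E_1 B_1)$. Its growth rate integrates soil
water under a Gaussian root kernel centred at the shoot whose width is
$\mathcal S_1$ of the *shoot* biomass, and the water uptake at a point sums
the kernels of all plants whose roots reach it (the kernel arguments are
transposed between the two integrals — this asymmetry is mandatory and is
what digs bare-soil halos around large shrubs). The kernel mass is
$(1 + E_1 B)^2$: a bigger plant taps proportionally more water. This
short-range facilitation (water gathered where biomass already is) plus
long-range inhibition (neighbourhood depletion) is the scale-dependent
feedback that amplifies perturbations into periodic patterns. The sedge's
roots are laterally confined; its rates use the exact local limit
$G_B^{(2)} = \Lambda_2 W (1+E_2B_2)^2$, $G_W^{(2)} = \Gamma_2 B_2 (1+E_2B_2)^2$.

**Nonlocal sprouting.** New shrub clones emerge from root suckers at a
distance. The density of potential sucker sites follows a fat-tailed
(Cauchy-type) kernel $\Phi$ of width $S_{D_1}$, much narrower than the root
zone but with algebraic tails, and sprouting is gated by local water:
$\mathcal D_1 = \Theta_1 \frac{W}{W + W^*_1} (\Phi_1 \!*\! B_1)$. Because
water availability is lowest in the depleted halo and recovers beyond it,
this term preferentially seeds new spots *outside* the parent's halo —
patchy invasion. The sedge's short-range seed dispersal uses the same form
with width $S_{D_2}$ (an optional purely local switch exists and leaves all
uniform equilibria unchanged).

Default parameters are the reference set (`preset_params()`);
presets `low_altitude` (long roots, $E_1=16$ m²/kg), `high_altitude` (short
roots, $E_1=5$, wetter) and `weak_feedback` ($E_1=2$, too weak to pattern)
encode the standard scenarios. Presets ship as plain-text config files
under `inst/extdata/presets/`.

## Numerics

**Pseudo-spectral RK4.** Spatial operators are evaluated in Fourier space
on the periodic grid (exact spectral Laplacian, FFT convolutions); time
stepping is classical fourth-order Runge–Kutta. Kernels are defined
directly by their transfer functions: $\hat G = (1+E_1B)^2
e^{-\mathcal S^2 k^2/2}$ for the root kernel and $\hat\Phi = e^{-S_D |k|}$
for the fat-tailed kernel (its exact transform, identical in 1D and 2D).
This makes kernel masses exact on any grid, reduces smoothly to the local
limit when a width falls below the grid scale, and keeps the uniform-state
algebra identical in 1D and 2D — the property the 1D bifurcation analysis
relies on, and the reason the 1D kernels are normalized to the same masses
as the 2D ones.

**Kernel approximation.** The shrub growth integral is not a convolution —
the kernel width depends on local biomass — so it is approximated by a
linear combination of $J$ fixed-width convolutions. Widths sit at $J$ nodes
of $\mathcal S(B)$, uniform in $B$ over $[0, K_1]$; weights interpolate
linearly between the two bracketing widths and are rescaled so the total
mass $(1+E_1B)^2$ is exact for every $B$ (node-exact by construction).
$J = 5$ is the production default; the test suite checks the approximation
against direct $O(n^4)$ quadrature of the defining integrals (relative
$L_2$ error < 5% at $J=5$ on random smooth fields) and that the error
falls monotonically through $J = 2, 5, 9$. Two deliberate details: the
interpolation is extrapolated linearly (not clamped) below $B = 0$ so the
map $B \mapsto w(B)$ has no kink at zero — a kink there breaks
finite-difference linearization about states with $B = 0$; and interior
nodes make the right-hand side only $C^0$ in $B$, which degrades the
observable RK4 order when fields cross a node (the order test therefore
uses $J = 2$, whose single segment is smooth).

**Time step and guards.** The stiffest rates are the uptake sinks under a
full canopy ($\Gamma_1 K_1 (1+E_1K_1)^2 \sim 10^3$/y at the reference
parameters), and explicit RK4 needs roughly $dt < 2.8/\text{rate}$; the
default $dt = 10^{-3}$ y holds a safety margin of ~2. RK4 can undershoot
zero; fields are clipped at zero after each full step, with the clipped
mass accumulated and asserted tiny (< $10^{-8}$ of total mass) in tests —
an accounting guard, not a stabilizer. A run is steady when the mean
absolute per-step change summed over the three fields drops below
`steady_tol` ($10^{-9}$ kg/m² by default; $10^{-11}$ for
invasion-threshold probes, where a marginally unstable spot can otherwise
be declared steady before its slow instability emerges). Non-finite values
abort with the last valid state.

**The compiled core and its mirror.** The production stepper lives in
`src/core.cpp` (Armadillo FFTs); a pure-R implementation of the identical
discrete operators (`veg_rhs`, `rk4_step(engine = "r")`) is kept as a
reference and the two are asserted equal to machine precision in the test
suite. The brute-force quadrature oracles are a third, independent route.

## Stability analysis

`uniform_equilibria()` reduces the model on uniform fields (kernel masses
$(1+E_iB_i)^2$ and 1) to three scalar equations: bare soil (BS) is
analytic, the single-species states (GU, CU) come from damped Newton on the
divided growth equation plus the water balance from a fixed lattice of
starting points, the mixed state (MU) from the full 3-variable system.
Reported residuals are below $10^{-10}$; duplicates merge at $10^{-8}$.

The dispersion relation $\sigma(k)$ about a uniform state is built
*numerically*: for each $k$ the $3\times3$ operator acting on
$(b_1,b_2,w)\cos kx$ is assembled by central finite differences of the
discretized right-hand side on a dedicated one-wavelength 1D grid. This
sidesteps the error-prone algebra of differentiating the biomass-dependent
kernel width, and is exactly testable: at $k = 0$ it must reproduce the
uniform Jacobian (asserted to $10^{-6}$), and about bare soil the biomass
modes decouple with the closed-form rate $\Lambda_i W - M_i +
\Theta_i \frac{W}{W+W^*_i} e^{-S_{D_i} k}$ (note: no root-kernel factor —
the growth convolution acts on the *uniform* water field). The
finite-difference step is $10^{-5}\max(1, |\bar u_\alpha|)$, balancing
truncation against cancellation in right-hand sides of magnitude $\sim P$.

`turing_threshold()` bisects $P$ on the sign of $\max_{k>0}\lambda(k)$ and
verifies the three defining conditions ($\lambda = 0$, $d\lambda/dk = 0$,
$d^2\lambda/dk^2 < 0$) at the returned point. `scan_branches()` continues
the uniform branches over $P$ by warm-started Newton and flags both
uniform and finite-$k$ stability; stable patterned branches are traced by
simulation sweeps (`pattern_branch_sweep()`), not continuation — unstable
nonuniform branches are out of scope.

## The invasion pipeline

A probe run places a Gaussian shrub bump (peak $0.5K_1$, footprint radius
1 m — the initial spots are stated only as "very small", and the suite
checks insensitivity to this choice) on the uniform sedge equilibrium and
integrates. Spots are connected components of $\{B_1 > 0.1K_1\}$ under
periodic 4-connectivity (igraph components; centroids use the
circular-mean convention). Outcomes: **incomplete** — the spot count never
durably exceeds its initial value and the sedge persists; **complete** —
the sedge's mean biomass falls below the extinction threshold
($10^{-4}$ kg/m², configurable), typically after spot replication;
**retreat** — the invader dies. Replication requires the count to exceed
its initial value for a dwell of 5 y, guarding against threshold flicker.

`find_P_inv()` bisects precipitation on this label. Numerical choices that
matter here: the threshold is the one quantity sensitive to the
kernel-approximation order, so probes default to $J = 9$; the default
transect is 128 m at $dx = 0.25$ m. Domain doubling at fixed $dx$ leaves
probe outcomes unchanged, while refining $dx$ or raising $J$ shifts the
threshold downward by on the order of a percent — the reported value
should be read as carrying that discretization uncertainty on top of its
bracket width. `steady_tol` is tightened to $10^{-11}$
because near the threshold an unstable spot's escape rate is small; and
the bisection reports the final bracket midpoint, so its resolution is the
bracket width (25 mm/y in the acceptance run), not the printed digits.

## Synthetic scenarios — what the tests do and do not establish

All inputs are generated: uniform states plus seeded uniform noise on the
biomass fields only (water relaxes fast; the instability is
biomass-driven), Gaussian spot sets (four spots at the corners of a
centred square of side $0.3L_x$ for the invasion snapshots — the placement
is this package's choice), and tanh-blended adjacent patches for front
experiments. Scenarios serialize to JSON manifests and regenerate
bit-identically.

Acceptance simulations are scaled down to fit a desktop budget: 2D runs
use 32–48 m boxes at $64^2$–$96^2$ (vs. the "extended domains" of
GPU-scale work) and 1D runs 64–128 m transects. The box must comfortably
exceed the pattern wavelength: in a 20 m box the four-spot experiment
degenerates (halos overlap, the spots merge and the sedge is excluded even
under high water stress), which is why 48 m is the floor for that
scenario. A green suite therefore establishes the
*mechanisms* — Turing onset and its absence at weak feedback, bi- and
tristability, halo formation, the incomplete/complete dichotomy and its
threshold location on the stated grid — not landscape-scale statistics,
domain-size-independent pattern selection, or behaviour under real
rainfall variability. Field heterogeneity, slopes, seasonality and the
surface-water variable eliminated from this model family are all outside
what any test here can speak to.

## Known limitations

- The fat-tailed kernel's spectral evaluation truncates its algebraic tail
  at the grid Nyquist scale; far-field sucker densities are accurate to
  ~a few percent at $6\,S_{D_1}$ on the default grids (tested), worse at
  domain-corner distances.
- Piecewise-linear kernel weights make the right-hand side $C^0$ at
  interior nodes; observable time-step convergence order degrades there
  while remaining stable and accurate at the default $dt$.
- Branch continuation stops at folds (reported as branch termination);
  unstable patterned branches are not computed.
- The classifier's horizon logic can label a near-threshold run
  "complete but unconverged" when replication is still in progress at
  `t_max`; thresholds inherit the probe horizon as part of their
  operational definition.
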