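---
title: "Methods: the cortisol transport model and its inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cortisol transport model and its inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweatcort)
```

## The transport model

Cortisol reaches sweat through a chain of physiological barriers, and the
package models that chain as a lumped single-gland compartmental system.
In blood, 80–90% of cortisol is bound to corticosteroid-binding globulin
(CBG) and a further fraction to albumin; only the free fraction $\alpha$
(about 5% at baseline) can leave the capillary. The free-concentration
gradient drives a molar source into the interstitial fluid (ISF),

$$J_{source} = k_{DE}\,(\alpha C_{blood} - C_{ISF})\,V_p,$$

with $k_{DE}$ a generalized dermal clearance constant for steroids.
Water filters across the capillary wall by the Starling principle,
$Q_{water} = L_{p,c} A_c (P_c - P_{ISF})$, setting the ISF advection
velocity $u_{ISF} = Q_{water}/A_{ISF}$ and, scaled by the measured
normalized sweat velocity $u_{sweat,n}$, the duct velocity
$u_{sg} = Q_{water}\,u_{sweat,n}/A_{sg}$. Free cortisol moves along the
ISF path by advection and diffusion with the distributed source, crosses
the gland wall by Fick's law with conductance $D_{sg,wall}/h_{sg}$, is
diluted on entry into the duct by the water influx,
$C_{sg,dil} = C_{sg}/(1 + K_{w/c}\,u_{sg,n})$, and finally travels along
the duct under advection, diffusion and a first-order sink
$S_{enzyme} C_{sg,dil}$ representing 11β-HSD2 conversion of cortisol to
cortisone. The model output is the duct concentration at the skin-surface
outlet.

Every mechanism is linear in concentration, so the steady-state surface
readout is exactly proportional to $C_{blood}$ and to $\alpha$. This is
load-bearing: it makes the inverse problem a scalar linear root find, it
makes the sensitivity of the output to $\alpha$ analytically predictable,
and it is asserted by the test suite to $R^2 = 1$ within $10^{-6}$.

### Coupling topology

The compartment framework leaves three junction choices open, resolved
here as the least-assumption serial topology:

* The capillary source $J_{source}/V_{ISF}$ is applied uniformly along
  the ISF domain, using the local ISF concentration in the gradient (the
  capillary bed runs alongside the path rather than entering at a point).
* Gland-wall exchange acts at the ISF outlet boundary and feeds the duct
  inlet after dilution. The pre-dilution entry concentration $C_e$ is set
  by a flux balance at the junction — the wall influx equals the
  advective carry into the duct — which gives
  $C_e = C_{ISF}(L)/(1+\beta)$ with
  $\beta = u_{sg} h_{sg}/(D_{sg,wall}(1+K_{w/c} u_{sg,n}))$. This choice
  conserves cortisol mass across the wall–dilution junction exactly, and
  the suite checks global balance (source molar inflow vs. duct outlet
  outflow with the sink off) to within 2% on the default grid.
* All Starling-filtered water is routed into the duct
  ($Q_{water,sg} = Q_{water}$): in a lumped single-gland model there is
  no other sink for the filtered volume.

### Boundary conditions

ISF inlet (capillary side): zero diffusive flux, with advective inflow
carrying solute-free water. ISF outlet: reflecting for solute advection —
water passes into the gland but cortisol crosses only by wall diffusion.
Duct inlet: Dirichlet at the diluted entry concentration. Duct outlet:
zero diffusive flux (advection-dominated exit). These are the minimal
choices consistent with the serial compartment picture.

## Parameters

Literature defaults (all SI except pressures in mmHg): $P_c = 30$,
$P_{ISF} = -3$ mmHg, $L_{p,c} = 6.5\times10^{-10}$ m s⁻¹ mmHg⁻¹,
$k_{DE} = 1.01\times10^{-3}$ s⁻¹, all three diffusion coefficients
$2.84\times10^{-10}$ m² s⁻¹, $A_{sg} = 1.96\times10^{-11}$,
$A_c = 1.5\times10^{-8}$, $A_{ISF} = 2.2\times10^{-8}$ m²,
$V_p = 3.02\times10^{-13}$, $V_{ISF} = 6.0\times10^{-13}$ m³,
$\alpha = 0.05$, $K_{w/c} = 20$, $h_{sg} = 5\times10^{-5}$ m. The shipped
`inst/extdata/table1.yaml` reproduces this set.

Three quantities the literature table does not pin down are exposed as
configuration with documented defaults:

* **Geometry.** The ISF path length defaults to $L_{ISF} = 10^{-4}$ m
  (dermal capillary-to-gland spacing scale) and the duct length to
  $L_{sg} = 2\times10^{-3}$ m (typical dermal duct). The model's
  qualitative properties (linearity, positivity, oracle agreement) are
  tested across a 10× range of both.
* **Passive sweat velocity.** $u_{passive}$ normalizes the duct velocity
  for the dilution term. Its default is chosen so that $u_{sg,n} = 1$
  when $u_{sweat,n} = 1$ at the default geometry, i.e.
  $u_{passive} = Q_{water}/A_{sg} \approx 1.64\times10^{-5}$ m s⁻¹.
  Measurement files supply $u_{sweat,n}$ directly, so no raw sweat-rate
  conversion is needed.
* **Enzyme turnover.** No literature value exists for $S_{enzyme}$; the
  default is 0 (sink off) and a non-zero nominal must be supplied where
  the sink matters — the sensitivity fixture uses $5\times10^{-3}$ s⁻¹,
  the midpoint of the personalization bounds $[0, 0.01]$. Following the
  duct equation literally, the sink acts on the diluted concentration.

Units: internal state is SI (mol m⁻³); all I/O is nmol L⁻¹ with the fixed
conversion 1 nmol L⁻¹ = 10⁻⁶ mol m⁻³, asserted in tests.

## Numerics

The PDEs are discretized by the method of lines on uniform grids —
first-order upwinding for advection (robust at the duct's cell Péclet
numbers), central differences for diffusion. The duct inlet value is
derived algebraically from the ISF outlet state, so the coupled system is
tridiagonal. Two steady-state routes are provided and cross-checked:

* `method = "transient"` (default contract): stiff integration
  (`deSolve::lsoda`, banded Jacobian) with geometric time checkpoints;
  steady state is declared when the surface readout changes by less than
  `steady_tol` (default $10^{-8}$ relative) across a checkpoint interval
  spanning many relaxation times. Failure to settle before `max_time`
  yields an explicit `converged = FALSE`, never a silent result.
* `method = "direct"`: the semi-discrete system is linear,
  $\dot y = A y + b$, so the steady state solves $A y = -b$; the three
  bands of $A$ are recovered by probing the same right-hand side used for
  integration (one shared discretization) and the system is solved by the
  Thomas algorithm. This route is exact for the discretized system and
  two orders of magnitude faster, so the estimation and sensitivity loops
  use it by default; the transient route remains the validity check that
  a steady state is actually reached and is the default for single
  forward simulations.

Default grids are 40 ISF × 60 duct nodes; doubling both changes the
default-condition output by well under 1% (tested), and an independently
coded dense-grid direct solve (240 × 320 nodes, assembled from the
stationary balance equations in the test helpers) agrees with the package
solver to better than 1% across operating points, including the
no-sweating pure-diffusion balance. Tiny negative round-off in profiles
is clipped to zero.

## Inverse estimation

The estimation strategy interleaves two loops.

**Outer loop (blood concentration).** Starting from 355 nmol L⁻¹ (the
pre-surgery cohort average), candidate blood concentrations are iterated;
each is forward-simulated and scored by the squared sweat error
$e_i = (C_{sweat} - \hat C_{sweat,i})^2$, stopping at
$e_i \le 0.01$ nmol² L⁻². The update is a proportional first step
followed by safeguarded secant steps — exact in one or two iterations for
a linear map, and bounded at 50 iterations with the best iterate retained
otherwise. The error trace starts at the initialization's error, but the
criterion is checked on updated estimates: sweat concentrations are
$\mathcal{O}(1)$ nmol L⁻¹, so the 0.01 nmol² L⁻² threshold is frequently
already met at the initialization, and stopping there would return the
initialization for most records. Negative candidates (possible under
measurement noise) are clipped to zero with a warning. A zero sweat
measurement returns exactly zero by linearity.

**Inner loop (personalization).** A single sweat value cannot jointly
identify $C_{blood}$ and $\alpha$, so the package separates two modes:
*calibrate* fits the personalized parameters per subject × condition
group from records carrying a reference blood value, by bounded least
squares on the summed sweat error (Brent's method for the default single
parameter, box-constrained quasi-Newton for several); *estimate* inverts
sweat-only records with the calibrated (or literature) parameters. The
default personalized set is $\{\alpha\}$ — the only parameter whose
output CV dominates the sensitivity ranking by an order of magnitude —
with bounds $[0.01, 0.30]$ spanning the literature baseline and
post-surgical elevations; $S_{enzyme}$ is opt-in. Requests with more free
parameters than informative records fail loudly rather than fitting
silently. Group granularity is subject × condition, matching how
per-condition free-fraction estimates are reported clinically.

Because personalization uses the reference blood values and the outer
loop does not feed back into them, the interleave stabilizes in one pass;
the loop still iterates (capped at 5) and checks parameter drift below
$10^{-9}$ relative.

## The synthetic cohort generator

The generator emulates the structure of a perioperative study: 44
subjects by default, each contributing a pre-surgery visit and one
post-surgery visit, with 34/50 of subjects dexamethasone-treated.
Per-condition free-fraction medians default to 4.8% (pre-surgery), 11.3%
(post-surgery without dexamethasone; surgical stress depletes CBG and
free cortisol rises two- to four-fold) and 5.4% (post-surgery with
dexamethasone; suppression). Blood cortisol medians default to
355·e^{−σ²/2} nmol L⁻¹ pre-surgery (tying the mean to 355), 500 without
and 120 with dexamethasone — plausible perioperative levels chosen once,
as distributional summaries of this kind are not published per condition.
All positive quantities are drawn log-normal (positivity and the right
skew typical of cortisol); spreads (`alpha_sdlog = 0.25`,
`blood_sdlog = 0.4`, `velocity_sdlog = 0.3`) are configuration-exposed
defaults chosen for qualitatively realistic dispersion. Measurement noise
is multiplicative Gaussian on the log scale with CV 0.10 by default
(assay errors scale with concentration), applied independently to the
sweat and blood assays; `noise_cv = 0` yields exactly model-consistent
records. Generation is deterministic under the spec's seed, and a
row-aligned ground-truth sidecar (true blood concentration, true
$\alpha$, noise-free sweat value) makes recovery exactly scoreable.

What the generator does **not** emulate: surgery timing and dynamics,
dexamethasone pharmacokinetics, assay-specific artifacts (volume limits,
contamination), intra-subject correlation beyond the shared condition,
or model misspecification — synthetic records are generated by the same
transport model that the estimator inverts. Passing recovery tests
therefore demonstrates the correctness and stability of the inversion
machinery, not the clinical accuracy of the transport model itself, which
can only be established against trial data.

## Sensitivity analysis

One-at-a-time Monte-Carlo perturbation: for each parameter, 100 draws
uniform in ±20% of nominal, all else at nominal, forward simulation per
draw, and the coefficient of variation (CV, %) of the simulated sweat
cortisol as the sensitivity measure. The operating point is
$C_{blood} = 355$ nmol L⁻¹ and $u_{sweat,n} = 1$ (configurable); for
$\alpha$ the CV is invariant to this choice because the output is
proportional to $\alpha$, and its population CV is exactly
$0.2/\sqrt{3} \approx 11.55\%$ — finite-sample CVs at $n = 100$ scatter
around this value, which anchors the acceptance band. Parameters with CV
above 0.1% are ranked as personalization candidates; $\alpha$ ranks first
at the defaults. Non-converged draws are excluded with a warning, and
more than 10% failures abort the analysis.

## Agreement statistics

RMSE, Pearson correlation and Bland–Altman bias with limits of agreement
(bias ± 1.96 SD of the differences), stratified per condition plus
overall. The correlation CI uses the Fisher z-transformation
($\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$) — the standard choice,
consistent with asymmetric intervals around high correlations; at
$|r| = 1$ the interval degenerates to the point. Differences are oriented
estimated − measured. Strata with fewer than 3 pairs are reported with
empty statistics and a warning.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic
inputs generated at run time: cohorts of 44 subjects (88 records) for
end-to-end recovery checks, 100-draw sensitivity runs over a few seeds,
and smaller cohorts for unit-level properties. All stochastic steps are
seeded; cohort generation, estimation and sensitivity results are
bit-for-bit reproducible under a fixed seed.

## Known limitations

* The lumped effective areas/volumes are population-scale literature
  values; the model is 1-D and ignores gland anatomy, so absolute sweat
  concentrations inherit the uncertainty of the untabulated geometry
  (path lengths, passive velocity) even though ratios and the inversion
  are insensitive to it.
* CBG/albumin binding kinetics are collapsed into the static fraction
  $\alpha$; cortisone is not tracked beyond the first-order sink.
* Estimation treats each record quasi-statically — no time-series
  dynamics, no population (mixed-effects) pooling across subjects.
* With one calibration record per group, the fitted $\alpha$ absorbs the
  record's measurement noise entirely (the in-sample fit is exact);
  recovery accuracy under noise should therefore be judged against the
  ground-truth sidecar, as the acceptance tests do.
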