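---
title: "Methods: the go-or-grow growth/invasion model and its in-silico trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the go-or-grow growth/invasion model and its in-silico trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotrials)
```

## The model

`gliotrials` simulates glioblastoma multiforme growth and invasion on a 2-D
brain grid at the spatial scale of clinical MRI (1.5 mm voxels).  Four
dimensionless concentrations evolve per voxel: proliferative tumour cells
$P$, invasive tumour cells $I$, brain cells $B$, and accumulated necrotic
mass $N$.  The go-or-grow dichotomy is explicit: $P$ cells replicate but do
not move; $I$ cells move but do not replicate; hypoxia converts $P$ to $I$
(rate $\alpha H$) and normoxia converts back ($\beta (1-H)$).

$$\partial_t P = M P - \alpha H P + \beta (1-H) I - \gamma_F P$$
$$\partial_t I = \delta \nabla\!\cdot\!(D \nabla I) - \eta \nabla\!\cdot\!(I \nabla B)
  + \alpha H P - \beta (1-H) I - \gamma_F I$$
$$\partial_t B = -\gamma_F B, \qquad \partial_t N = \gamma_F (P + I + B)$$

with total concentration $C = P + I + B + N$, local hypoxia
$H = \tfrac12\!\left(1 - \tanh 40 (C_{hyp} - C)\right)$, mitotic rate
$M = \tau (1-H)\,\tfrac{T}{T + a}$ (where $T = P + I$ and $a$ is the
cooperative-growth scale discussed below), necrosis rate
$\gamma_F = \gamma\!\left(\tfrac{P+I}{100} + \tfrac{1}{B + 0.01}\right)
\tfrac12\!\left(1 - \tanh 40 (C_{ltm} - C)\right)$, hypoxic threshold
$C_{hyp} = \sigma \log(1 + T) + \Omega$, and necrotic threshold
$C_{ltm} = C_{hyp} + \Phi$.

Defaults (see `model_params()`): $\alpha = 2.02$/hr, $\beta = 2.00$/hr,
$\tau = 0.35$/hr, $\gamma = 0.17$/hr, $\Omega = 1.1$, $\sigma = 1.5$,
$\Phi = 0.10$, $D = 1$, with $\delta \in [8\times10^{-7}, 4\times10^{-3}]$
mm²/hr and $\eta \in [1.4\times10^{-4}, 1.4\times10^{-3}]$ mm/hr spanning
the motility phenotypes.  Time is in hours throughout; reported survival
uses 730-hour (30.42-day) months.

Angiogenesis enters through $\sigma$: a denser tumour recruits
vasculature, raising the concentration the tissue tolerates before turning
hypoxic.  Anti-angiogenic treatment sets $\sigma = 0$, freezing the
hypoxic threshold at $\Omega$.

### Design choices in the closures

Three structural choices were genuinely open and were settled by analysing
the model's behaviour; each is exposed as an option so the alternative
remains reproducible.

**The angiogenic drive is the total tumour density** ($T = P+I$; option
`angiogenic_drive`).  If the threshold follows the proliferative density
only, any voxel entering hypoxia destroys its own vascular support while
converting $P$ to $I$ (at $\alpha \approx 2$/hr), the threshold collapses
to $\Omega$ within hours, and the voxel dies completely regardless of all
other parameters.  That positive feedback makes dense tumour and brain
tissue unable to coexist for more than a day or two anywhere, which
contradicts the phenomenology the model is meant to produce (a
high-density rim that persists for weeks while necrosis lags).  Driving
the threshold with $P + I$ removes the conversion feedback while keeping
the intended angiogenesis mechanism; biologically, both compartments are
tumour burden secreting pro-angiogenic factors.

**Necrosis accumulates mass** ($\partial_t N = +\gamma_F(P+I+B)$, and $N$
counts toward $C$).  With the opposite sign the total concentration falls
on cell death, so crowding never saturates and the local tumour density
grows without bound (we observed $P+I$ running to overflow).  With $N$
accumulating, a fully necrotic voxel keeps $C$ above the necrotic
threshold permanently: the necrosis rate stays high, no cell survives in
the necrotic core, and the reaction terms conserve mass exactly when
$\tau = 0$ (the conservation oracle used in the tests).

**Cooperative growth (`allee`, default 0.05).**  A pure continuum model
with exponential low-density growth lets infinitesimal diffusive tails
mature into visible tumour within a day ($\ln(10^{5})/0.35 \approx 33$
hr), so invasion speed becomes almost independent of $\delta$ and the
three motility phenotypes collapse onto one behaviour.  This spurious
invasion by sub-cellular densities is a known artifact of reaction-
diffusion glioma models; the standard remedy is a minimum-density cutoff.
We use the smooth Monod form $T/(T+a)$ rather than a hard threshold
because a hard gate deadlocks low-$\delta$ tumours entirely (the source
voxel dies before exporting a viable density).  With $a = 0.05$ — the MRI
detection floor, i.e. proliferation is efficient only at imageable
densities — colonisation time scales inversely with the seeding flux
$\delta I / h^2$, which restores the strong $\delta$-separation between
highly-dispersive, moderately-dispersive, and hypoxia-driven tumours.
This value was fixed once, by checking which choices reproduce the
published qualitative pattern grid, before any acceptance testing.

Other conventions: the logarithm in the angiogenesis term is natural
(option `log_base`); the $\tanh$ steepness 40 is a named parameter for
sensitivity work; necrosis bookkeeping, thresholds and seeding follow the
printed values exactly.

## Discretisation

Forward Euler with a 5-point Laplacian for concentration-driven diffusion
and donor-cell (first-order upwind) fluxes for hypoxia-driven advection —
the simplest positivity-friendly scheme consistent with "finite
differences".  No-flux boundaries are imposed by zeroing face fluxes into
non-mask voxels (skull and background are impermeable).  Diffusion support
collapses to $10^{-6}$ (not exactly zero, to avoid discrete artefacts) in
the necrotic core, defined as $\ge 80\%$ brain death, so invasive cells do
not diffuse back into the dead centre.  The step size is
$\mathrm{dt} = 0.5\,\min\!\big(h^2/(4\delta D_{max}),\; h^2/(\eta B_{max}),\;
(\alpha + \beta + 100\gamma)^{-1}\big) \approx 0.024$ hr at reference
rates; the $100\gamma$ term covers the necrosis-rate divergence as
$B \to 0$.  Negative values produced by a step are clipped to zero and the
clipped mass is tracked; a run aborts if it ever exceeds $10^{-6}$ of the
total mass (in practice clipping is zero to round-off).  The compiled
stepper (`src/advance.cpp`) is verified against the R reference
discretisation to $10^{-14}$ per step, and mass conservation with
$\tau = 0$ holds to $10^{-14}$ relative over 1000 steps.

## Virtual MRI

A brain voxel is *necrotic* if more than 80% of its brain cells are dead
($B/B_0 < 0.2$); otherwise *high-density tumour* (the gadolinium-
enhancement proxy) if $P + I > 0.7$; otherwise *FLAIR* if
$0.05 \le P + I \le 0.7$.  Precedence necrotic > high-density > FLAIR
makes the necrotic "hole in the brain" win over residual tumour; FLAIR
bounds are inclusive.  Areas are percentages of brain-mask voxels.
Progression patterns compare the first follow-up (2 simulated months
after treatment, or the treatment-death midpoint for patients dying
sooner) with the appearance at death, using relative changes with a 25%
band (borrowed from the gadolinium response criterion; the qualitative
radiologic criteria never quantify the "no change" arrow) and a 1
percentage-point absolute band, since area changes below about 1% of the
brain are not called as change on MRI: FLAIR up with stable necrosis is
Expanding FLAIR; both up is Expanding FLAIR + Necrosis; stable FLAIR with
rising necrosis is Expanding Necrosis.

## Trials

Treatment (or diagnosis) fires at the first of two monitored criteria —
high-density tumour size or necrotic area — and death at the first of
FLAIR or necrosis (tumour size or necrosis for untreated controls); which
criterion binds depends on the phenotype, so per-arm summaries typically
show only one of the two ranges.  Per-patient variability comes entirely
from criterion titration: each
arm's treatment trigger and death threshold are evenly spaced grids over
the design ranges (deterministic and reproducible; the pairing is
shuffled by the arm seed).  Monitoring runs at a 12-hour cadence — fine
relative to month-scale outcomes.  The untreated growth phase is
deterministic, so it is simulated once per arm and patients branch off at
their individual trigger crossings; control patients read both times off
the shared trajectory.  Runs hitting the censoring guard enter the
Kaplan-Meier analysis as censored.  Survival analysis (product-limit
curves, median, log-rank with $\chi^2$ p-values, and an optional
permutation p-value) is delegated to the `survival` package behind the
package's own API; the efficacy-survival curve is fitted as
$f(x) = a e^{bx} + c e^{dx}$ by Levenberg-Marquardt least squares with a
log-linear initialisation and seeded multi-start.

Rate- and motility-reducing agents multiply $\tau$ (uniformly, or
pointwise through a tumour-treating-fields efficacy map) and $\eta$ by
$1 - \text{efficacy}$ at the moment the trigger fires.  The spatial
efficacy map is built by taking the voxelwise maximum of two array
orientations, evaluating a cubic dose-response (intensity in V/cm to
fraction of untreated proliferation, clamped to $[0,1]$, with
$f(0) = 1$), and multiplying $\tau$.  The default cubic is a synthetic
monotone stand-in anchored at (0, 1), (1, 0.70), (2, 0.30), (3, 0.10):
the mechanism is in scope but the underlying experimental dose-response
points are not distributed here.

## Problem sizes used in tests and the acceptance script

The reference geometry is a synthetic, irregular, roughly elliptical
brain mask (the generator is first-class, seeded, and exercised by the
test suite); a labeled-grid reader ingests segmented slices in CSV or PGM
form when higher anatomical fidelity is wanted.  The test suite uses
40x30 to 60x45 grids; the acceptance script runs reduced cohorts
(about 10 patients per arm on a 48x36 mask with a one-year censoring
horizon).  These sizes were chosen so a full trial completes in minutes
on one core while preserving the orderings of interest; absolute survival
times shrink roughly with the brain radius, so published full-size
medians are fidelity targets only when a full-size labeled slice is
supplied.

## What the synthetic data do and do not show

The synthetic mask reproduces the topology that matters to the model
(connected tissue, impermeable boundary, irregular outline) but not real
anatomy: no ventricles, no white/gray contrast (unless the optional
ridge field is enabled), and half the linear extent of a full axial
slice.  Passing tests therefore demonstrate the mechanisms — phenotype-
dependent progression patterns, treatment-induced FLAIR expansion,
necrosis-coupled invasion, futility orderings — not patient-level
calibration.  Known limitations beyond that:

* Under anti-angiogenic treatment the colonised FLAIR region equilibrates
  close to the necrotic threshold, so the hypoxia-driven necrosis wave
  consumes it from behind.  Treated highly-dispersive tumours therefore
  show expanding rather than plateauing necrosis, usually reach the
  necrosis death criterion before the FLAIR one, and do **not** reproduce
  the long post-treatment survival that distinguishes that phenotype
  clinically: at desk scale the treated highly-dispersive arm separates
  sharply from every other arm on the log-rank test but sits on the wrong
  side of the median ordering.
* Hypoxia-driven invasion in this implementation consumes invasive cells
  at the necrotic rim, so the advancing front needs continuous
  replenishment through proliferation; strong mitotic-rate reduction
  consequently slows hypoxia-driven tumours here, i.e. the rate-reduction
  futility expected for that phenotype is only partially reproduced
  (motility reduction behaves as expected: survival rises monotonically
  with motility-reducing efficacy).
* The progression-arrow convention (25% relative change with a 1
  percentage-point absolute band, follow-up at two months or the
  treatment-death midpoint) is a reading of qualitative radiologic
  criteria; labels of runs that die quickly are sensitive to it.
* 2-D geometry only; no pharmacokinetics, dose scheduling, vascular
  normalisation, or acquired-resistance phenotypes.
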