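---
title: "Methods: SPR fragment screening triage and steady-state affinity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPR fragment screening triage and steady-state affinity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprfrag)
```

`sprfrag` implements the analysis cascade of a surface plasmon resonance
(SPR) fragment screen: simulation of Biacore-style injection cycles,
correction of raw traces into report points, hit triage, constrained
steady-state affinity fitting, and downstream activity analysis
(ELISA-based inhibition and progress-curve rates). This vignette describes
the underlying models, the parameters that matter, and the design choices
made where the methodology was genuinely open.

## The binding model

All binding simulation and fitting assumes a 1:1 Langmuir interaction
between an immobilized ligand (e.g. the 92 kDa protease C1r) and an
injected analyte at concentration $C$:

$$R_{assoc}(t) = R_{eq}\,\bigl(1 - e^{-(k_a C + k_d)(t - t_{start})}\bigr),
\qquad
R_{eq} = \frac{C\,R_{max}\,n}{C + K_D},$$

with exponential dissociation $R(t) = R(t_{stop})\,e^{-k_d (t-t_{stop})}$
after the injection and $K_D = k_d / k_a$. The theoretical maximal
response scales with the mass ratio of analyte to ligand:

$$R_{max} = \text{immobilization (RU)} \times
\frac{MW_{analyte}}{MW_{ligand}} \times n .$$

The simulator uses the closed-form solution rather than numerical ODE
integration; the two agree to solver precision (the test suite keeps an
independent `deSolve` integration as oracle), and the closed form is far
cheaper for campaign-scale simulation. Mass-transport limitation,
rebinding and surface heterogeneity are deliberately not modeled: the
analysis layer only ever consumes steady-state (plateau) responses, for
which these kinetic refinements are irrelevant.

## What the synthetic campaign emulates

`simulate_campaign()` produces one single-concentration cycle per library
compound plus blank (buffer) cycles and DMSO calibration blocks at the
beginning, the end and every 50 cycles — the cadence at which instrument
drift is conventionally re-calibrated. Four compound classes define the
generative ground truth:

* **clean binders** — 1:1 binders with $n = 1$ and $K_D$ drawn
  log-uniformly from 50–250 µM by default. At the 500 µM screening
  concentration this spans fractional occupancies of roughly 0.67–0.91,
  i.e. compounds a screen at a 60 % $R_{max}$ threshold is designed to
  find. Dissociation is fast ($k_d = 0.5\,s^{-1}$), typical for fragments.
* **non-binders** — no specific signal; only bulk artifacts and noise.
* **sticky compounds** — non-specific binders leaving a slowly decaying
  residual (default 8 RU, half-time 600 s) on the surface, so the report
  point 10 s after injection still sees it. These are the clean screen's
  target.
* **superstoichiometric binders** — aggregation-like compounds modeled
  with $n \ge 2.5$ in the same kinetic law and an apparent $K_D$ drawn
  from 10–100 µM, below the clean-binder range: aggregation-driven binding
  presents as steep, apparently tight occupancy, which is what makes these
  compounds exceed the $2 \times R_{max}$ exclusion at the screening
  concentration.

Artifacts are layered on top: a bulk refractive-index jump during the
injection window proportional to the DMSO mismatch between sample and
running buffer (default 100 RU per percentage point), a quadratic
excluded-volume difference between the active and reference cells
(`excess_poly`), optional linear drift common to both cells, and i.i.d.
Gaussian noise (default 0.3 RU). The bulk jump is applied only while the
sample plug flows — during the association window — on both flow cells;
after the injection the surface returns to running buffer, so the
post-injection residual report point is bulk-free by construction. The
per-cycle DMSO content of analyte cycles is jittered within ±0.4 % of the
nominal 5 %, inside the 4–5.5 % calibration span.

Features of real campaigns the generator does **not** emulate: slow
instrument baseline wander beyond linear drift, carry-over between cycles,
compound depletion, temperature excursions, and any kinetic artifact
(mass transport, biphasic traces). Passing the planted-truth tests
therefore demonstrates that the cascade's logic is correct under the
stated noise model, not that it is robust to every instrument pathology.

## From raw cycles to report points

Each analyte cycle is double-referenced:
$(active - reference) - (blank_{active} - blank_{reference})$, using the
blank cycle of the nearest calibration block. The correction chain is
linear, so report-point extraction commutes with it.

**Solvent correction.** Solvent-only cycles spanning the DMSO range yield
pairs of (reference bulk response, active-minus-reference offset); a
degree-2 polynomial (configurable) fitted by least squares defines the
correction, and the observed bulk range defines its validity window.
Analyte cycles whose bulk falls outside that window are flagged
`in_range = FALSE` and excluded from hit calling — flagged, never
extrapolated, and never an exception. Calibration blocks are applied
piecewise to the nearest enclosing cycle span; no temporal interpolation
between blocks is attempted, matching the every-50-cycles schedule.

**Report points.** The steady-state binding point averages the last 2 s of
the association phase; the clean-screen residual point averages a 1 s
window centered 10 s after injection stop. A window mean is used instead
of a single sample because it resists point noise; this windowing is also
how baseline noise is handled (no separate instrument-software noise model
is reproduced).

## Triage

The cascade applies, in order: the insolubility flag (an *input* from
visual inspection — never computed), the clean screen (residual strictly
greater than 5.0 RU fails; exactly 5.0 RU passes), the calibration-range
flag, the superstoichiometric exclusion (binding strictly above
$2 \times R_{max}$), an abnormal-shape heuristic, and the hit criterion
(corrected binding at least 60 % of $R_{max}$). Inequality directions are
exact: strict for exclusions, inclusive for the hit fraction. Every
record is either a hit or carries an explanatory flag or a sub-threshold
percentage — nothing is silently dropped.

The abnormal-shape criterion has no quantitative definition in standard
practice (instrument software leaves it to the operator), so it is
operationalized as: binding report point below −1 RU (about three standard
deviations of the default noise), or a residual point exceeding both the
binding point and that same floor. Both constants are configurable in
`triage_config()`.

The campaign hit rate is rounded half up to one decimal. This matters:
95 hits in 2000 compounds is 4.75 %, which banker's rounding would print
as 4.7 %.

## Steady-state affinity

`fit_steady_state()` fits $R_{eq}(C) = C R_{max}/(C + K_D)$ with
$R_{max}$ **fixed** at its theoretical value. This constraint is the crux
of the method: fragment affinities frequently exceed the top tested
concentration (500 µM), where an unconstrained two-parameter fit is
hopelessly ill-conditioned; fixing $R_{max}$ makes $K_D$ estimable from
the curvature of the partial isotherm. It must not be relaxed silently —
relaxing it changes what the number means.

Numerical choices: the search is over $\log_{10} K_D \in [-9, 1]$
(`stats::optimize`, tolerance $10^{-12}$), unweighted least squares in
linear response space (instrument noise is approximately homoscedastic in
RU), an optional constant offset profiled analytically (off by default),
and a warning when the optimum sits at a search bound. Replicates are
aggregated as arithmetic mean ± sample SD on the $K_D$ scale (not
log-$K_D$), matching the mean ± SD convention of steady-state SPR
reporting; fewer than three replicates marks the result provisional. The
diagnostic `saturation = max(C)/K_D` tells the user how far up the
isotherm the data reach.

Domain mapping normalizes per-surface responses to occupancies,
$occ = raw \cdot MW_{ligand} / (immob \cdot MW_{analyte} \cdot n)$, which
removes immobilization density and ligand size and makes a full-length
surface directly comparable with domain-truncation surfaces.

## Activity assays

**Normalization.** Percent activity anchors each well to the controls of
its own plate column (positive = 100 %, negative = 0 %); values are not
clipped. Per-column rather than per-plate aggregation was chosen because
the plate layout places one control pair in every column; the
normalization is affine-invariant by construction.

**Single-dose testing** uses the classical equal-variance unpaired t-test
(Welch available by flag), significant at p < 0.05. No multiple-testing
correction is applied across a screening panel by default — each compound
is an independent hypothesis advanced to confirmation, not a family-wise
claim; `stats::p.adjust` composes trivially when a corrected view is
wanted.

**IC50 fitting** uses the constrained inhibitor-versus-response model
$pct(C) = 100/(1 + (C/IC_{50})^h)$ with top and bottom fixed at 100 and 0;
the `fixed_slope` default pins $h = 1$. Internally the fit is
log-parameterized ($\log IC_{50}$) via `minpack.lm::nlsLM`. Replicate
wells of a column are averaged before fitting (default): they share the
very controls they were normalized against, so they are not independent
observations, and fitting raw wells would understate the uncertainty. The
95 % CI is the large-sample normal interval on $\log IC_{50}$ from the
asymptotic covariance; in seeded Monte Carlo at the default plate design
(7 two-fold doses, triplicate wells, 5 % CV) this combination attains
94–97 % empirical coverage. A fit whose predicted inhibition span across
the tested range is below 20 percentage points is rejected as "no dose
dependence" rather than reported as an unstable number; an IC50 outside
the tested concentration span is flagged extrapolated.

**Progress curves.** Initial rates are least-squares slopes over a
configurable initial window (≥ 5 points); a treated/control rate ratio
below 0.5 is called inhibited.

## Library profiling

Rule-of-three boundaries (≤ 300 Da, ≤ 3 H-bond donors, ≤ 3 clogP) are
inclusive, matching their conventional statement; missing descriptors make
the verdict indeterminate, never silently compliant. Ligand efficiency is
the standard $LE = -\Delta G / HAC$ with $\Delta G = RT \ln K_D$ at
298.15 K in kcal/mol — reported LE ranges in the literature rarely state
the formula or temperature, so both are explicit and configurable here.
Atom-pair fingerprints come from `ChemmineR` (whose descriptor codes
already encode pair multiplicity), but the Tanimoto statistic
$|A \cap B| / |A \cup B|$ is computed by this package on the descriptor
sets, so the statistic is testable independently of the backend and other
backends can be plugged in as precomputed fingerprint lists. Clustering is
single-linkage on the $1 - T$ distance via `stats::hclust`, cut at a
distance threshold; the test suite verifies it against brute-force
agglomeration on small instances.

## Problem sizes and determinism

The shipped tests and the acceptance script use a 200-compound campaign
(10 % clean binders, 8 % sticky, 4 % superstoichiometric, σ = 0.3 RU),
dose series of 7 two-fold concentrations × 3 replicates at σ = 0.5 RU,
and 200 seeded repetitions for the IC50 Monte Carlo — sizes chosen so the
full suite runs in about a minute while keeping the Monte Carlo estimates
stable to a few percent. Every stochastic stage takes an explicit integer
seed, and derived stream seeds stay within the 32-bit range; identical
configuration and seed reproduce campaigns bit-for-bit.

## Known limitations

* Kinetic rate constants ($k_a$, $k_d$) are never fitted; the analysis is
  steady-state only, and the dissociation model exists to make the
  residual report point meaningful.
* The clean screen and superstoichiometric filters inherit the noise
  model's optimism: at 0.3 RU noise the planted classes are well
  separated, and real campaigns with drifting baselines will sit closer
  to the thresholds.
* The asymptotic IC50 interval is calibrated for the default plate
  design; very steep slopes or responses far from 50 % at every tested
  dose will degrade it (profile-likelihood is a natural extension).
* Compound structures are handled only as SMILES for similarity analysis;
  no substructure (e.g. PAINS) screening is included.
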