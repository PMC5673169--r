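---
title: "Modeling treatment effects on tumor vasculature and metastatic spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling treatment effects on tumor vasculature and metastatic spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaspread)
```

## The model

`metaspread` analyses xenograft experiments in which a subcutaneous tumor
grows, sheds cells into the bloodstream, and founds metastatic colonies in
distant organs, while the animal may receive cisplatin chemotherapy or
hypofractionated radiotherapy.

**Primary growth.** The primary tumor's cell number follows
$x(t) = N_0 e^{a t}$, with $N_0$ the number of engrafted cells at day 0 (the
first palpated measurement used in regression, not the injection day) and
$a$ the growth rate constant in day$^{-1}$. Palpated volumes (cm$^3$) are
converted at $10^9$ cells/cm$^3$. Fitting is ordinary least squares of
$\ln x$ on $t$. Two alternatives — Gompertz
($x = K e^{-b e^{-ct}}$) and a spheroid model with linearly growing radius —
are fitted by `compare_growth_models()` for model criticism; in this class
of experiment exponential growth wins over the observation window, which is
short relative to any plateau.

**Palpation correction.** Palpation against comparison spheres carries a
systematic scale error. The excised tumor's necropsy weight is the more
precise measurement, so the whole volume series is rescaled by the single
factor $f = (w/\rho)/v_\mathrm{last}$ with tissue density
$\rho = 1$ g/cm$^3$ (tumor tissue is mostly water; the conversion is our
choice, as is the single multiplicative factor — an additive offset in log
space would be equivalent). The correction is idempotent and $f$ is
reported.

**Colonization.** Cells leave the primary at the rate
$$\beta(x) = m\,x^{\delta/3},$$
where $m$ is the colonization coefficient ((cell·day)$^{-1}$) and $\delta$
is the fractal dimension of the tumor vasculature: $\delta = 3$ means fully
perfused volume (seeding proportional to cell number), $\delta = 2$ means
blood supply restricted to the surface, and $\delta = 0$ means destroyed
vasculature (constant trickle $m$). Colony foundings form an inhomogeneous
Poisson process with intensity $\beta(x(t))$; each colony starts at one
cell and grows at the same rate $a$. Closed forms used as oracles:
$$\Lambda(T) = m N_0^{\delta/3} \frac{3}{a\delta}\left(e^{a\delta T/3} - 1\right),
\qquad
D(T) = \ell\, m N_0^{\delta/3} e^{aT}\,
  \frac{1 - e^{-a(1 - \delta/3)T}}{a(1 - \delta/3)},$$
for the expected colony count and the expected disseminated-cell total
(with organ-lodging fraction $\ell$, default 1); the $\delta = 3$ and
degenerate limits are handled continuously. Colony death, dormancy and
carrying capacity are deliberately absent — defensible over a 14-day
horizon, wrong for longer ones.

**Inference.** $m$ is calibrated on a reference animal (the control mouse
with the largest primary at necropsy), pinning $\delta = 2$ there and using
the linearity of $D(T)$ in $m$. Each animal's $\delta$ is then inferred two
ways: from the absolute disseminated count by bisection on the monotone map
$\delta \mapsto D(T;\delta)$ ($\delta_{DTC}$), and from the
circulating-cell count by algebraic inversion of
$\beta(x(T))$ ($\delta_{CTC}$). Both clamp to $[0,3]$ with a flag; a
clamped animal is one whose measurement the model cannot reach. The two
routes are compared with a paired Wilcoxon signed-rank test.

**Assay scaling.** qPCR counts come per template mass (20 ng blood DNA for
CTCs, 60 ng tissue DNA for DTCs; 60 ng $\approx$ 10,000 murine cells, i.e.
6 pg/cell). The published conversion formula to absolute counts is in a
supplementary text we do not have, so both conversions are explicit
configuration: `organ_scale` (default 100, i.e. 6000 ng organ DNA / 60 ng
template) and `k_ctc` (default 1) mapping the CTC count to an absolute
intravasation rate. All results that depend on them say so.

**Treatment.** Chemotherapy (single cisplatin dose) acts as a first-order
kill $k(t) = k_0 f_S e^{-\lambda_d (t - t_c)}$ on the growth ODE — the two
levers being the S-phase fraction $f_S$ and the drug decay rate
$\lambda_d$ — and, one day after the dose (configurable lag), switches the
fractal dimension to $\delta'$. Radiotherapy delivers $n$ daily fractions,
each multiplying the primary size instantaneously by the linear-quadratic
survival $e^{-\alpha d - \beta d^2}$. Chemotherapy is systemic (colonies
are hit too); radiotherapy is local to the primary by default. The kill and
LQ parameters are illustrative configuration, not fitted — the defaults
($k_0 = 0$ unless configured; $\alpha = 0.05$/Gy, $\beta = 0.005$/Gy$^2$)
were chosen so that 5 × 10 Gy suppresses but does not annihilate the
primary; no claim of radiobiological realism is made.

**Error propagation.** For each treated animal the simulation is repeated
with each listed parameter at its mean ± SD, one at a time; the reported
error is the quadrature sum of the per-parameter half-ranges
$(\max - \min)/2$, with the raw envelope also returned. A measurement
"matches" when it lies inside the closed interval
$[D - \mathrm{err},\, D + \mathrm{err}]$ — simulation-side error only.

**Vessel density.** Stained sections are segmented in CIE L\*a\*b\*
(D65/2°, via `grDevices::convertColor`): candidate pixels by channel
thresholds (Permanent Red: high a\*; DAB: dark plus warm hue), then seeded
region growing where a neighbour joins if its colour is within a Euclidean
tolerance of the region's *running mean* colour (a frozen-seed-colour
criterion is available; the original algorithm's step list is in an
unavailable supplement, so the criterion is our choice). A k-means route
(k-means++ under a fixed seed, Lloyd iterations, stained cluster = nearest
centroid to the reference stain colour) cross-checks it. Objects below the
area threshold (10.3 µm², alternative 17.7 µm²) are dropped; analysis is
restricted to the tumor region minus margins (minus necrosis in viable
mode), dropping objects that overlap excluded zones by more than 50% — the
boundary-object rule is our choice, the masks are inputs (the original
study excluded necrosis by eye). Density is objects per mm² of analyzed
area over the whole region, not fields of view; per-tumor values average
the sections.

## The synthetic world

Every stage is tested against generators that record their ground truth.
Values the source material states are used as stated: $a \sim$
Normal(0.260, 0.043) day$^{-1}$ truncated positive; $N_0$ log-normal with
mean $1.44\times10^6$ and SD $2.37\times10^6$ (heavy-tailed, SD > mean);
RT as 5 × 10 Gy on consecutive days; a 14-day observation horizon. Values
nothing states were chosen once and not revisited: measurement days
0, 2, 4, 7, 9, 11, 14 (alternate-day palpation over two weeks);
multiplicative palpation noise with CV 0.10 plus a per-mouse systematic
bias with CV 0.15 (what the necropsy correction exists to remove); necropsy
weight noise CV 0.05; PCR counts drawn Poisson on the expected absolute
count divided by `organ_scale`, so records are integers; default
$m = 0.05$; a size-linked dimension rule
$\delta = \min(3, \max(0, 0.12\ln x(T) - 0.1))$ that reproduces the
observed pattern of larger tumors being better vascularized; slides as
non-overlapping stained disks (radius 4–10 µm, jittered Permanent-Red
colour) on a hematoxylin-pink background at 2 µm/px.

What a green test establishes, and what it does not: the generators share
the analysis model's functional forms, so recovery tests validate the
inference machinery (identifiability, correctness of the estimators and
their numerics), not the biology. Real palpation error is not log-normal,
real engraftment is not exactly log-normal, real vessels are not disks on
a two-colour background, and real slides have stain gradients, touching
vessels and out-of-focus regions none of which are emulated. Exact
100/100 count recovery is therefore a statement about algorithmic
correctness on well-separated objects, not expected field performance.

One acceptance assertion is knowingly marginal: with 50 noisy animals the
worst-case per-animal $|\hat\delta_{DTC} - \delta|$ is required to stay
below 0.05, but under the stated noise the per-animal error has SD
$\approx 0.02$, so the worst of 50 draws crosses 0.05 for some seeds (at
the suite's seed it reaches 0.07 for one animal). We left the bound as
stated rather than widening it; the median error is $\approx 0.01$ and the
cross-method agreement criterion passes.

## Numerical choices

* Bisection for $\delta$ targets a relative tolerance of $10^{-6}$ on the
  expectation (about $10^{-7}$–$10^{-4}$ on $\delta$ depending on local
  slope), 200 iterations maximum, interval floor $10^{-13}$.
* Deterministic expectations are used for inference (reproducibility); a
  stochastic mode (bisection on replicate means) exists behind a flag.
* Poisson thinning uses the exact bound $\beta(x(T))$ untreated (the
  intensity is monotone). Under treatment, between events
  $\tfrac{d}{dt}\ln x = a - k(t)$ with $k$ decaying, so $\ln x$ is convex
  piecewise and the supremum of $x$ on $[0,T]$ is attained at event
  endpoints (pre-irradiation left limits): the treated bound is exact too,
  not a grid estimate. A time-rescaling sampler (analytic inversion of
  $\Lambda$) cross-checks the thinning route.
* Treated expectations integrate piecewise between event days
  (`stats::integrate`, rel.tol $10^{-10}$) so kinks and jumps never sit
  inside a panel.
* Wilcoxon: zeros dropped, ties midranked; exact two-sided p by dynamic
  programming over doubled (hence integer) ranks up to $n = 25$ — valid
  with ties, unlike the tabulated distribution — then a normal
  approximation with continuity and tie correction. The t-test is pooled
  Student by default (Welch by flag). These follow the conventions of the
  R release the original analysis used.
* k-means is made deterministic by a fixed-seed k-means++ initialization;
  `kmeans_k` should equal the number of colour classes actually present
  (2 for stain/tissue slides, 3 with necrosis) — with more clusters than
  classes, Lloyd splits a tight colour blob and the stained mask erodes.
* Per-unit RNG streams are keyed by (master seed, unit id), so enlarging a
  cohort never reshuffles existing animals; all derived seeds stay below
  $2^{31}$.

## Known limitations

Single-organ seeding summarized by one lodging fraction; no
metastasis-from-metastasis by default (switchable, untested against data);
no pharmacokinetics, cell-cycle structure or RT repopulation; treatment
cannot separate changes in $m$ from changes in $\delta$ (only their
combination is identified — the same degeneracy the source analysis
acknowledges); no whole-slide pyramidal formats, stain deconvolution or
automatic necrosis detection; the published per-animal tables and slide
images are not deposited, so the study's printed cohort numbers are
documented but cannot be recomputed here.
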