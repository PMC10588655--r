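---
title: "Mapping brain oxygen extraction and perfusion with qBOLD and multi-delay ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain oxygen extraction and perfusion with qBOLD and multi-delay ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qboldr)
```

## The problem

The oxygen extraction fraction (OEF) — the fraction of delivered arterial
oxygen that tissue actually consumes — is a central marker of brain tissue
health. Together with cerebral blood flow (CBF) it determines the cerebral
metabolic rate of oxygen, CMRO~2~ = CBF × OEF × Hb~a~. During a vasodilatory
stress (for example acetazolamide), healthy tissue raises CBF and lowers OEF
while CMRO~2~ stays approximately constant; failure of this compensation is a
signature of vascular disease. `qboldr` implements a complete, testable
pipeline for this physiology: a quantitative BOLD (qBOLD) model of
asymmetric spin echo (ASE) MRI to map OEF and deoxygenated blood volume
(DBV), a general-kinetic-model fit of multi-delay pseudo-continuous arterial
spin labeling (pcASL) to map CBF and arterial transit time (ATT), ROI-level
statistics for a paired two-condition design, and a digital phantom that
makes every stage verifiable without acquired data.

## The qBOLD signal model

A voxel is modeled as two compartments. The extravascular (tissue) signal at
spin-echo displacement $\tau$ and fixed echo time TE is, in the static
dephasing regime,

$$
S_t(\tau) = S_0\, e^{-R_{2t}\,\mathrm{TE}} \times
\begin{cases}
e^{-\frac{3}{10}\, \mathrm{DBV}\, (\delta\omega\, \tau)^2} & \tau < T_c\\[4pt]
e^{\mathrm{DBV} - \mathrm{DBV}\,\delta\omega\,\tau} & \tau \ge T_c
\end{cases}
$$

with the characteristic frequency
$\delta\omega = \tfrac{4\pi}{3}\,\gamma B_0\, \Delta\chi_0\, \mathrm{Hct}\,
\mathrm{OEF}$, the reversible relaxation rate
$R_2' = \mathrm{DBV}\cdot\delta\omega$, and the regime boundary
$T_c = 1.76/\delta\omega$. The intravascular (blood) signal is the powder
average over randomly oriented vessels, which has a closed form in the
normalized Fresnel integrals $C$ and $S$:

$$
S_b(\tau) = e^{-R_{2b}\mathrm{TE} + i\,\delta\omega\tau/2}\,
\frac{C(\eta) - i\,S(\eta)}{\eta},
\qquad \eta = \sqrt{3\,\delta\omega\,\tau/\pi},
$$

with the empirical blood relaxation rate
$R_{2b} = 16.4\,\mathrm{Hct} + 4.5 + (165.2\,\mathrm{Hct} + 55.7)\,
\mathrm{OEF}^2$. The total magnitude signal is
$S(\tau) = S_0[\mathrm{DBV}\,|S_b| + (1-\mathrm{DBV})\,S_t/S_0]$, and OEF is
recovered from fitted $(R_2', \mathrm{DBV})$ through
$\mathrm{OEF} = 3R_2' / (4\pi\,\gamma B_0 \Delta\chi_0\,\mathrm{Hct}\,
\mathrm{DBV})$.

### Numerical choices

* **Short-$\tau$ exponent.** We use $\frac{3}{10}\mathrm{DBV}
  (\delta\omega\tau)^2$ — the only dimensionally consistent reading of the
  quadratic regime, and the standard asymptotic qBOLD form.
* **Branch boundary.** $\tau = T_c$ is assigned to the long-$\tau$ (linear)
  branch; the asymptotic branches are used as-is, without blending, and the
  branch is selected per voxel from that voxel's own $\delta\omega$.
* **$\eta$ convention.** $\eta = \sqrt{3\delta\omega\tau/\pi}$ is the unique
  value for which the Fresnel closed form equals the orientation average
  $\int_0^1 \exp(-i\,\delta\omega\tau(3x^2-1)/2)\,dx$; the package carries
  that quadrature (`powder_average_oracle`) as an independent check, and the
  test suite holds the two routes to $10^{-6}$ relative agreement.
* **Fresnel evaluation.** $C(u), S(u)$ are computed in-package: a Maclaurin
  series below $u = 1.5$ and, above, a tail integral rotated onto a
  non-oscillatory Laplace contour evaluated with 48-node Gauss–Laguerre
  quadrature. Both branches are at double precision against independent
  reference values.
* **Phase convention.** The sign of the $i\,\delta\omega\tau/2$ phase factor
  is immaterial downstream because ASE magnitude images are fitted; the
  package composes the complex signal and discards phase at the end.
* **Shared $\delta\omega$.** Blood and tissue compartments share a single
  per-voxel $\delta\omega$ (one OEF per voxel).

Defaults follow a 3 T protocol: TE 56 ms, TR 3 s, $\tau \in \{0, 16, 20,
\dots, 40\}$ ms, $\Delta\chi_0 = 0.264\times10^{-6}$, Hct 0.40,
$R_{2t} = 11.5\,\mathrm{s}^{-1}$. The gyromagnetic ratio is not part of the
published constant set; we expose $\gamma = 2.675\times10^{8}$ rad s⁻¹ T⁻¹
in the configuration. All internal units are SI (seconds, fractions);
percent and milliseconds appear only at I/O boundaries.

## Voxelwise estimation

The reference analysis uses variational Bayes in an external toolkit.
`qboldr` implements the same prior structure as maximum-a-posteriori (MAP)
estimation with a Laplace covariance — for a Gaussian posterior the point
estimates coincide, and the implementation is dependency-free and exactly
reproducible. Per voxel:

1. $S_0$ carries a flat prior and is profiled out in closed form (the model
   is linear in $S_0$).
2. $R_2'$ and DBV carry independent Gaussian priors on the natural scale
   (means 2.6 s⁻¹ and 3.6%; SDs $10^{3/2}$ s⁻¹ and $10^{1/2}$%). The two
   renderings of these SDs in the source material are mutually inconsistent;
   we adopt the pairing consistent with the cited simulation literature and
   expose both values in the configuration.
3. The optimizer works in softplus/logit coordinates so $R_2' > 0$ and
   $\mathrm{DBV} \in (0,1)$, with Nelder–Mead inner iterations.
4. The noise SD is estimated from residuals, alternating with parameter
   updates (up to 5 outer iterations, objective tolerance $10^{-8}$).
   Crucially, the initial noise estimate comes from the residuals of an
   *unpenalized* least-squares stage, not from the starting guess —
   otherwise model mismatch masquerades as noise and the alternation can
   stall at a spurious fixed point.
5. Two deterministic starts are used: the prior means, and a log-linear
   ("streamlined") estimate with $R_2'$ from the long-$\tau$ slope and DBV
   from the spin-echo intercept offset. The qBOLD posterior is
   banana-shaped, and the second start protects high-DBV voxels. The final
   answer is the start with the lower penalized negative log posterior.
   There is no randomness anywhere in the fit: identical inputs give
   bit-identical maps.

A known noise SD can be supplied instead (`sigma =`), in which case
estimates shrink monotonically to the prior means as the assumed noise
grows — the package tests this shrinkage property explicitly.

Post-processing follows the reference pipeline: voxels with OEF > 100% or
$R_2' > 20\,\mathrm{s}^{-1}$ (strict inequalities; equality is retained) are
excluded with a per-parameter report, and group-average maps keep only
voxels valid in at least half the population (⌈N/2⌉, i.e. 4 of 8).
Gaussian smoothing (σ in mm, converted to voxels per axis, kernel
renormalized at the boundary so constants are preserved) is applied to the
ASE inputs before fitting — σ = 4 mm for the human protocol — and σ = 1.5 mm
to ASL data.

## Perfusion from multi-delay pcASL

The labeled-blood difference signal follows the single-compartment general
kinetic model for a plug-flow bolus of duration LD arriving at ATT:
zero before arrival; $2\alpha \frac{M_0}{\lambda} f\, T_{1t}
e^{-\mathrm{ATT}/T_{1b}} (1 - e^{-(t-\mathrm{ATT})/T_{1t}})$ during
delivery; and post-bolus decay with $T_{1t}$. Defaults: PLDs
$\{0.9, 1.2, 1.4, 1.8, 2.1\}$ s, LD 2 s, $T_{1b}$ 1.65 s, $T_{1t}$ 1.3 s,
$\lambda$ 0.9 mL/g, $\alpha$ 0.85. The reference toolkit also carries a
macrovascular arterial component; its exact form and priors are not
published, so the tissue model is the default here (the arterial term is a
nuisance component for CBF) — a deliberate scope decision. Likewise $T_{1t}$
is used directly rather than a flow-corrected apparent $T_1$ (the
difference is below 2% at physiological perfusion).

Because the model is linear in perfusion, $f$ is profiled in closed form at
each candidate ATT and the fit is a deterministic 1-D search over ATT
(coarse grid + golden-section refinement). CBF is reported in mL/100 g/min
($f \times 6000$) after voxelwise M₀ calibration, which enters the model as
$M_0/\lambda$.

## The digital phantom

The phantom stands in for acquired, registered subject data. Nine cortical
ROIs (six default-mode-network regions and three reference regions) are
laid out as disjoint blocks on a small grid; per-subject, per-condition ROI
values of CBF, OEF and DBV are drawn from Gaussians with the published group
means and between-subject SDs (eight subjects, pre/post vasodilation).
Design choices, fixed once:

* OEF and DBV are the generative parameters; the $R_2'$ truth is *derived*
  as $\mathrm{DBV}\cdot\delta\omega(\mathrm{OEF})$ so truth and forward
  model are consistent by construction. The published per-ROI $R_2'$ column
  is only approximately consistent with the OEF/DBV columns (subject-level
  averaging), so it is used for report validation, not generation.
* Within-ROI spatial heterogeneity defaults to zero (a jitter flag exists);
  no voxel-level distributions are published.
* ATT is fixed at 1.3 s (only the initialization value is published);
  S₀ = M₀ = 1 in arbitrary units — OEF and CMRO₂ are scale-free in both.
* Thermal noise is Gaussian, not Rician: at tissue SNR the difference is
  negligible and Gaussian noise matches the fitter's likelihood. ASE noise
  SD is the mean in-ROI spin-echo signal divided by the ASE SNR. ASL noise
  SD is the mean in-ROI *peak difference signal* divided by the ASL SNR —
  the conventional SNR definition for ASL difference images (an SNR
  referenced to M₀ would put the noise several times above the entire
  perfusion-weighted signal and make recovery meaningless).
* Noiseless phantom runs skip the spatial smoothing step (`smooth_sigma_mm
  = 0` in `run_phantom_pipeline`): smoothing exists to suppress thermal
  noise, and on a noise-free piecewise-constant phantom it would only mix
  ROI and background voxels at block edges.

What a green phantom test does establish: the forward models, the fitters,
the exclusion and aggregation rules, and the statistics reproduce the
generative parameters and the published derived summaries end to end. What
it does not establish: robustness to realistic anatomy, susceptibility
artifacts, motion, registration error, or non-Gaussian noise — none of
which the phantom emulates.

## ROI statistics

Per-ROI means over valid voxels feed a subject × condition × ROI table.
Pre/post differences use two-sided paired t-tests with Bonferroni
correction over the nine ROIs (significance threshold 0.05/9 ≈ 0.0056).
CMRO~2~ at ROI level is computed per subject (subject CBF × subject OEF ×
Hb~a~) and then averaged — the only reading consistent with the published
table, where the CMRO~2~ cells deviate from the product of the cell means;
the product-of-means variant is also reported. Hb~a~ = Hb~t~ × Y~a~ =
8.441 × 0.98 = 8.272 µmol/mL.

The OEF–CBF association pools both conditions in a random-intercepts mixed
model `OEF ~ CBF + (1 | subject) + (1 | region)` fitted by REML (lme4), with
p-values from a t reference with n − 2 degrees of freedom (no small-sample
correction, matching the plain t statistics of the reference analysis). The
derived group summaries — mean baseline OEF, mean relative CBF increase,
mean relative OEF decrease, per-ROI absolute OEF change — are computed from
ROI-level group means, the construction that reproduces the published
values.

```{r summaries}
s <- summary_changes(reference_roi_table())
round(c(baseline_oef = s$mean_baseline_oef,
        cbf_increase = s$mean_cbf_increase_pct,
        oef_decrease = s$mean_oef_decrease_pct), 1)
round(s$abs_oef_change, 1)
```

## Known limitations

* At realistic voxelwise SNR the OEF point estimate is strongly
  prior-dependent: at SNR 100 (spin-echo amplitude over noise SD) the
  median absolute OEF error across a broad truth grid is ~10 percentage
  points, dominated by shrinkage of high-OEF/high-DBV voxels toward the
  prior. This is a property of the model/prior/protocol combination, not of
  the optimizer: an exhaustive grid search for the global MAP and the full
  posterior mean do no better. Voxelwise OEF from this protocol should be
  interpreted at ROI level, where averaging removes most of the error.
* The two asymptotic tissue-signal branches are discontinuous at $T_c$ by
  construction; no diffusion-regime or vessel-size corrections are applied.
* The ASL model omits the macrovascular component, dispersion and
  partial-volume effects.
* The phantom's geometry is deliberately artificial; registration and
  atlas definition are out of scope (any integer label volume is accepted).
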