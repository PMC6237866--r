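---
title: "Quantifying aromatase availability from dynamic PET: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aromatase availability from dynamic PET: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petkin implements the quantitative chain that turns a 60-minute dynamic
brain PET acquisition with a reversible aromatase tracer into regional and
voxel-wise binding-potential estimates, and the statistical layers that
relate those estimates to personality-trait scores. Because no scan data
are distributed with packages of this kind, every stage is exercised on a
synthetic cohort whose generative model mirrors the acquisition; this
vignette describes the models, the defaults, and what the synthetic route
does and does not establish.

## The acquisition model

A scan is a 38-frame dynamic sequence — 6 × 10 s, 6 × 30 s, 11 × 60 s and
15 × 180 s — spanning 60 minutes from injection
(`standard_frame_schedule()`). All times are carried in minutes and all
activities in kBq/mL; frame timing travels as a JSON sidecar beside each
NIfTI image because NIfTI itself has no portable frame-timing field.
Activity curves are assumed decay-corrected upstream, so the package does
no decay handling. Atlas and image must share a voxel grid exactly; the
2-mm resampling that produces that grid is an upstream preprocessing step,
and phantoms are generated directly on the final grid.

## Blood models

Total plasma activity is modelled as a linear rise from zero to the peak
followed by a tri-exponential decay,
$C_p(t) = \sum_i A_i e^{-\lambda_i (t - t_p)}$ for $t > t_p$, with the peak
value tied to $\sum_i A_i$ so the curve is continuous. The fit
(`fit_plasma_triexp()`) anchors the peak at the maximum sample — a
tri-exponential cannot represent the rise, so samples before the peak are
fitted by the straight line through zero — and optimizes log-amplitudes and
log-rates by Levenberg–Marquardt from five spread-out starts, keeping the
best sum of squares. Unweighted residuals are the default; a
relative-error weighting flag exists and is the right choice when accuracy
of the low-activity tail matters (at 3 % sampling noise the weighted fit
tracks the true curve to ~3 % beyond 5 minutes, the unweighted one to
~6 %).

The parent fraction — the share of plasma activity still carried by intact
tracer — follows a Hill function
$f(t) = 1 - a\,t^b/(t^b + c)$, which starts at 1, decreases monotonically
and saturates at $1-a$. The bounded fit (`fit_parent_hill()`)
logit-parameterizes $a$ and log-parameterizes $b$ and $c$. The default
generator parameters ($a = 0.55$, $b = 1$, $c = 6.6$) are calibrated to the
one quantitative anchor available for this tracer's metabolism: roughly
half the plasma signal is still parent compound at 60 minutes. The
metabolite-corrected input function is the pointwise product
$C_p(t)\,f(t)$, which by construction never exceeds the plasma curve.

## Tissue model and ground truth

Tissue kinetics follow the reversible two-tissue compartment model

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)C_1 + k_4 C_2,\qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

with total distribution volume $V_T = (K_1/k_2)(1 + k_3/k_4)$ and, for a
reference region devoid of specific binding ($k_3 = 0$),
$V_T^{ref} = K_1/k_2$. The distribution volume ratio is
$DVR = V_T / V_T^{ref}$ and the nondisplaceable binding potential is
$BP_{ND} = DVR - 1$; this identity is carried exactly through every result
object. The ODE system is integrated with `deSolve` (lsoda) on a uniform
5-second grid — fine enough to resolve the 10-second early frames — and
frame averages are taken by the trapezoidal rule. The unit tests check the
solver against a piecewise-analytic convolution for the one-tissue case and
an independent eigen-decomposed convolution for the full model.

Default generator kinetics are $K_1 = 0.3$, $k_2 = 0.1$/min for the
cerebellar reference ($V_T^{ref} = 3$, so the reference efflux rate
$k_2' = 0.1$/min), and $k_4 = 0.1$/min with $k_3 = BP_{ND}\,k_4$ for target
regions. $k_4$ matters: it sets the slow eigenvalue of the system and hence
how quickly the Logan plot (below) becomes linear. At $k_4 = 0.1$/min the
60-minute protocol sits comfortably in the linear regime (intrinsic bias
under 1 % across the simulated $BP_{ND}$ range), which is the defining
property of a tracer that is actually quantifiable with a one-hour scan —
as the modelled tracer empirically was. Slower binding (say
$k_4 = 0.05$/min) would build several percent of protocol-induced bias into
every downstream number and misrepresent the system being emulated.

## Logan graphical analysis

With an arterial input, the Logan transformation regresses
$\int_0^T C_T\,dt / C_T(T)$ on $\int_0^T C_p\,dt / C_T(T)$ for
$T \ge t^*$; in the linear regime the slope is $V_T$ (`logan_vt()`). The
reference-tissue form replaces the plasma integral by
$[\int_0^T C_{ref}\,dt + C_{ref}(T)/k_2'] / C_T(T)$ and its slope is the
DVR (`logan_reference_bpnd()`). Integrals are zero-anchored trapezoids on
frame midpoints; an analytic input model is integrated on a fine grid
rather than interpolated from samples.

Numerical behaviour worth knowing:

* **$t^*$.** The protocol never fixes it, so it is configuration with an
  audited default of 20 minutes — two thirds of the scan in the linear
  regime for the simulated kinetics — and every result carries the terminal
  segment's $R^2$ as a diagnostic.
* **Slow kinetics.** For rate constants whose slow eigenvalue is of the
  order of the scan length (e.g. $k_2 = 0.05$, $k_3 = 0.03$,
  $k_4 = 0.02$/min, where $1/\theta_2 \approx 89$ min), a 60-minute Logan
  slope underestimates $V_T$ by ~20 % no matter the implementation; the
  estimator-consistency test therefore simulates a 240-minute scan, where
  the slope converges to the closed form within 2 %.
* **$k_2'$ sensitivity.** Raising $k_2'$ by 50 % moves $BP_{ND}$ by under
  5 %, but halving it inflates the $C_{ref}/k_2'$ correction term more
  strongly (≈15 % at $t^* = 20$ under the default conditions, shrinking
  monotonically as $t^*$ moves later). The "average $k_2'$" is therefore
  estimated, not guessed: a one-tissue fit of each arterial subject's
  cerebellar curve against his metabolite-corrected input, averaged across
  subjects (`estimate_k2_prime()`), with a configurable fallback of
  0.1/min — logged loudly — when no arterial subject exists.
* **Noise bias.** Logan slopes are biased low under noise (the classic
  property of noise in the denominator); the suite asserts the direction.

Parametric images (`parametric_bpnd_image()`) apply the reference-tissue
form at every in-mask voxel with the image's own mean cerebellar curve as
reference. The OLS slope has a closed form in the two-column design, so the
whole image is one vectorized pass. Voxels whose terminal activity is
non-positive (where the transform is undefined) and voxels outside the
mask are set to 0.

The cross-validation that justifies the reference route
(`crossvalidate_vt_normalization()`) divides each arterial subject's
regional $V_T$ by the cerebellar $V_T$ and compares it with the
reference-Logan $DVR$; on simulated 4-subject arterial cohorts at 3 %
frame noise the discrepancy stays below the few-percent level reported for
the real acquisition.

## Regional statistics

Regional $BP_{ND}$ is the mean over each label's voxels (median available),
with the thalamus additionally reported as its five subregions — anterior
medial/lateral, central medial/lateral, posterior — plus the composite.
Sex comparisons use Welch's two-sample t-test by default (the
equal-variance variant is a flag; the source analyses say only "t-test",
and unequal variances are the safer default at $n = 10/11$), two-tailed at
$\alpha = 0.05$. Trait associations at the VOI level are simple OLS of
trait score on regional $BP_{ND}$, reporting slope, $R^2$, direction and
two-tailed p. The hormone check regresses plasma estradiol (females) or
free testosterone (males) on regional $BP_{ND}$ with Bonferroni control
over regions — the conservative default, since the source analyses state no
multiplicity rule — and skips regions with fewer than three quantifiable
values, mirroring the small-n situations that arise when a hormone is
unquantifiable in most of one sex.

## Voxel-wise association mapping

The per-voxel model is OLS of $BP_{ND}$ on $[1, \text{trait}]$; the trait
slope's t statistic is converted to a Z score through the
probability-integral transform of the $t_{n-2}$ distribution.

Family-wise error control over the amygdala VOI uses max-statistic
permutation rather than random-field theory: the covariate is permuted
across subjects, the maximum $|t|$ over the VOI recorded per permutation,
and each voxel's corrected p is the fraction of permuted maxima at or
above its observed $|t|$ (with the +1 correction). This is a deliberate
methodological substitution — exact under exchangeability, free of
smoothness estimation, and testable: the suite runs 500 null cohorts and
checks the realized family-wise error rate against the nominal 0.05.
Whole-brain trait maps are thresholded at two-tailed uncorrected
$p < 0.001$ separately per direction, connected components are formed
under 6-connectivity (18 available; 6 is the conservative default) and
clusters below 80 mm³ — ten 2-mm voxels — are dropped. Cluster volume is
always voxel count × |det| of the affine's 3×3 block, and peaks are
reported in world (MNI-like) millimetres. Sub-extent clusters recurring at
identical peak coordinates across traits are collected by
`subthreshold_coincidence()` (exact coordinate match by default, tolerance
configurable).

## The synthetic cohort

`generate_cohort()` draws, per subject: regional $BP_{ND}$ truths around
per-sex means (between-subject SD 0.15), trait scores, hormone levels,
a subject-scaled plasma curve, blood samples on the protocol's arterial
and venous grids, and a 4D phantom in which every voxel of a region
carries the region's two-tissue curve plus independent noise. Defaults
encode the study conditions: 10 females and 11 males with four males
arterially sampled; regional means ordered thalamus > medulla ≈ amygdala ≈
hypothalamus > cortex > cerebellum ≈ 0 (absolute levels are configurable —
no regional $BP_{ND}$ table is published for this tracer, so the thalamic
~1.3–1.6 defaults are a choice, not a measurement); a male-over-female
mean shift of 15 % in every region except the right hypothalamus, where
the tendency reverses; and two trait links — aggression score positively
tied to left-amygdala $BP_{ND}$ in females with population $R^2 = 0.83$,
and cooperativeness negatively tied to thalamic $BP_{ND}$ in both sexes
with $R^2 = 0.71$. Links are generated as
trait $= \beta\,BP_{ND} + \varepsilon$ with the error variance set from
the analytic population variance of the linked value, so the population
$R^2$ equals the target exactly and the sample $R^2$ scatters around it as
it should at $n = 21$.

The noise model is the standard dynamic-PET counting surrogate — Gaussian
with SD proportional to $\sqrt{\text{activity}/\text{frame duration}}$,
normalized so the relative SD of the final, lowest-rate frame equals the
configured `noise_fraction` (default 0.02), floored at zero. No noise
model is published for the emulated acquisition; this one reproduces the
qualitative structure (noisy short early frames, stable late frames).

What the phantoms deliberately omit: scanner resolution (no point-spread
function), partial-volume effects, motion, scatter and randoms, anatomical
shape (regions are rectangular blocks on a 16 × 16 × 12 grid), and spatial
noise correlation. Passing tests therefore establish that the estimators
are correct and calibrated under the stated generative model — recovery of
known truths, exact null behaviour, FWER control — not that they are robust
to the physics the phantoms exclude. Reported peak coordinates are
MNI-like only in the sense that the affine is anchored at a plausible
origin.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed and restores the global RNG
state; a cohort is a pure function of its specification. The test suite's
simulation sizes are chosen to estimate each property with adequate
precision at desk scale: 500 replicates for null-calibration and FWER
checks (binomial SE ≈ 0.01 at the 0.05 level), 1000 permutations per FWE
analysis, 20–30 replicates for power-style checks of near-certain effects,
and 200-subject check cohorts for association-strength recovery. The
end-to-end pipeline (`run_pipeline()`) writes every stage product plus a
manifest of files, seeds and resolved defaults, and
`recovery_report()` scores the run against the generator's ground truth.

## Known limitations

* The reference-tissue route inherits the Logan family's noise-dependent
  negative bias; at the default noise level it is ~1 % and absorbed into
  the 5 % recovery tolerance.
* Tri-exponential plasma fitting is ill-conditioned when decay rates
  approach each other; the multi-start strategy makes recovery reliable
  for well-separated truths but the individual amplitudes are not
  identifiable from noisy data in general (the fitted *curve* is).
* The voxel-wise GLM supports a single covariate plus intercept, matching
  the analyses it replaces; a richer design matrix is a natural extension
  point.
* No dispersion or delay correction is applied between blood and tissue
  curves, and venous samples are treated like arterial ones (no
  transformation between routes is modelled).
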