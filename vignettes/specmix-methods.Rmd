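---
title: "Multivariate UV-Vis calibration of overlapping drugs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate UV-Vis calibration of overlapping drugs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmix)
library(dplyr)
```

## The problem

Favipiravir (FV) and remdesivir (RV) are co-prescribed antivirals whose UV
absorption spectra overlap substantially between roughly 230 and 280 nm, so
neither drug can be quantified in a binary mixture from a single wavelength.
Multivariate calibration solves this by regressing concentrations on whole
spectra recorded over 220–400 nm at 1 nm resolution (181 channels),
exploiting the fact that under Beer–Lambert additivity a mixture spectrum is
a concentration-weighted sum of the pure-component absorptivity spectra:

$$ A = C\,K + E $$

with $A$ the $n \times p$ absorbance matrix, $C$ the $n \times m$
concentration matrix (µg/mL), $K$ the $m \times p$ matrix of pure
absorptivity spectra, and $E$ noise. specmix implements the three classical
estimators of this relationship and everything needed to validate them as an
analytical method.

## Calibration design

Calibration mixtures follow a five-level, two-factor multilevel design:
levels $\{1, 5, 9, 13, 17\}$ µg/mL per drug (centre 9, step 4), 25 runs laid
out by a cyclic generator of coded levels $\{-2,\dots,2\}$ in which each
level occurs exactly five times per factor. The second factor's coded column
is the generator rotated left by one position, which makes the two coded
columns orthogonal (zero dot product) and every level combination balanced
— the standard construction for multicomponent calibration designs. The
published layout does not state its generator explicitly; `generate_design()`
ships the sequence recovered from the printed table as
`five_level_generator()`, so the default design reproduces all 50 published
concentration cells bit-exactly, and other centres/steps reuse the same
generator. Odd-numbered runs (13) form the calibration set, even-numbered
runs (12) the validation set (`split_design(scheme = "odd_even")`); explicit
id lists are supported for other partitions.

## The three models

All three models share one contract: `fit_*()` returns a `calib_model`
whose prediction is $\hat c = (a - \bar a)\,B + \bar c$.

**CLS.** Classical least squares estimates the pure spectra directly,
$\hat K = (C^{\mathsf T} C)^{-1} C^{\mathsf T} A$, and predicts by the
minimum-norm solve $\hat c = a \hat K^{\mathsf T} (\hat K \hat K^{\mathsf
T})^{-1}$. No centring is applied; an optional intercept row models a
constant background (off by default). CLS is exact when every absorbing
species is in the model, and is the model that breaks first when an
unmodelled interferent appears.

**PCR.** Both blocks are column-centred; the first $a$ left singular
directions of the centred absorbance matrix define scores on which the
centred concentrations are regressed, folded back into $B$. The candidate
count is capped at the numerical rank (relative singular-value threshold
$10^{-10}$); requesting more is an error rather than a silently unstable
fit.

**PLS.** PLS2 via NIPALS on the centred blocks: per latent variable a unit
weight vector $w$, scores $t = X_{def} w$, loadings $p = X_{def}^{\mathsf T}
t / t^{\mathsf T} t$ and $q = Y_{def}^{\mathsf T} t / t^{\mathsf T} t$, with
deflation of both blocks and $B = W (P^{\mathsf T} W)^{-1} Q^{\mathsf T}$.
The inner iteration converges at relative tolerance $10^{-12}$ with a
500-iteration cap; non-convergence reports the offending latent variable.

Whether the original analysts centred their blocks or included a CLS
background term is not stated anywhere; the defaults above (centre for
PCR/PLS, no centring and no intercept for CLS, no autoscaling since all
channels share absorbance units) are declared package conventions, not
inferences from the published results. Singular vectors and weight vectors
are sign-fixed so their largest-magnitude element is positive, making every
fit deterministic across BLAS implementations.

## Model complexity selection

`loo_rmsecv()` leaves each calibration sample out once per candidate latent
variable count and reports per-component and pooled RMSECV, plus a 0-latent
baseline (training-fold mean prediction). Two selection rules are provided
because the original study plots RMSECV curves without stating its rule:

* `global_min` — smallest candidate attaining the minimum pooled RMSECV
  (ties broken low);
* `one_se_like_fratio` (default) — the Haaland–Thomas-style parsimony rule:
  the smallest candidate whose pooled RMSECV is within a factor 1.25 of the
  minimum.

On noiseless two-component data both rules select 2, and with the default
noise level the parsimony rule also selects 2 for both PCR and PLS — the
physically correct complexity for a two-analyte system without interferent.

RMSEC/RMSEP use divisor $n$ (`error_summary()`). The published error tables
cannot be reconciled with any single divisor when back-calculated from their
own printed recoveries, so the most common chemometric convention is adopted
and stated rather than reverse-engineered. CLS has no latent-variable axis;
it is excluded from RMSECV-vs-LV curves but `loo_rmse_cls()` reports its
single leave-one-out error.

## Synthetic spectra: what is emulated, and what is not

No instrument spectra were deposited with the original study, so the
package generates its own. `gaussian_component()` models a pure spectrum as
a sum of Gaussian bands; the defaults place the FV-like main band at 323 nm
and the RV-like main band at 246 nm with secondary bands chosen so the two
pure spectra overlap over roughly 230–280 nm, visually mimicking the
published overlap. Heights are scaled so design-range mixtures stay below
about 1.2 AU. These shapes are surrogates: the true absorptivities are not
published, and none of the calibration mathematics depends on the band
shapes — only on Beer–Lambert linearity, which the simulator implements
exactly.

`noise_model()` adds homoscedastic Gaussian absorbance noise (default
0.002 AU, typical bench-top photometric noise), optional constant/linear
baselines, an optional multiplicative term (off by default), and — for the
plasma scenario — a broad interferent background rising towards short
wavelengths whose level jitters ±15% per sample, standing in for residual
endogenous plasma absorbance after protein precipitation. Every stochastic
term requires an explicit seed; generation is bit-reproducible and leaves
the global RNG untouched.

What passing tests on this generator do show: the estimators are exact on
data satisfying their model (errors at machine precision), degrade
continuously and monotonically with noise, select the right complexity, and
separate as theory predicts under an unmodelled interferent (CLS degrades;
PCR/PLS recover with one extra latent variable). What they do not show:
performance on real instrument artefacts — wavelength registration error,
stray light, detector saturation, heteroscedastic noise — none of which the
generator emulates. Published instrument-dependent figures (absolute
RMSEC/RMSEP, LOD/LOQ, accuracy/precision values) are therefore not
reproduction targets; the published summary statistics that *are*
recomputable from printed per-sample values are reproduced exactly from the
bundled reference tables.

## Figures of merit

* `recovery_summary()` — recoveries $100\,\hat c/c$, mean, sample SD
  ($n-1$), RSD $= 100\,s/\bar x$; computed at full precision, rounded only
  for display. One published plasma table's "±" column matches the plain
  sample SD rather than the RSD; the package reports both so either
  convention can be read off.
* `lod_loq()` — ICH-style $LOD = 3.3\,SD/|slope|$, $LOQ = 10\,SD/|slope|$,
  with $SD$ the residual standard deviation $s_{y/x}$ (divisor $n-2$) of
  the predicted-versus-nominal line over the 1–17 µg/mL range
  (`linearity_merits()`). The source names but does not define this
  regression; the ICH convention its phrasing echoes is used.
* `accuracy_protocol()` / `precision_protocol()` — triplicate determinations
  at 4, 8 and 16 µg/mL; repeatability from one day's nine recoveries,
  intermediate precision from three days with day-specific noise draws and
  an optional between-day baseline component. The original protocol does not
  state the co-analyte level during these assays; the package assays binary
  mixtures with both drugs at the stated level, which keeps the samples
  inside the calibrated space.
* `standard_addition()` — per-spike recovery $100 \cdot found/added$ with
  mean and RSD from unrounded row recoveries (the published summary cells
  only recompute under this convention).
* `compare_methods()` — pooled-variance two-sample $t$ (df $n_1+n_2-2$;
  the printed critical 2.306 at df 8 confirms the pooled form) and
  larger-over-smaller variance-ratio $F$ (df ordered; printed critical
  6.388 at (4,4)), both at $P = 0.05$.

## Greenness

`eco_scale()` implements the analytical eco-scale: penalty points for
reagent amounts/hazards, energy, occupational exposure and waste are summed
and subtracted from 100; $>75$ is excellent, 50–75 acceptable, $<50$
inadequate. The original study reports scores of 79/81/78 for CLS/PCR/PLS
without itemizing penalties; the bundled
`ecoscale_penalties.csv` is an illustrative reconstruction totalling
21/19/22 and is documentation, not a claim about the authors' bookkeeping.
The GAPI and AGREE pictogram tools are external published software and out
of scope; only the eco-scale arithmetic is implemented.

## Numerical and degenerate-input choices

* Rank decisions use a relative singular-value threshold of $10^{-10}$.
* Collinear concentration columns abort CLS with the offending columns named.
* An all-excluding wavelength mask, mismatched grids at prediction time,
  out-of-range latent-variable requests and unseeded stochastic simulations
  are all errors, not warnings.
* Masking is idempotent and commutes with sample subsetting; the default
  mask keeps the full 220–400 nm range because the study never states which
  wavelengths its "noise region" covered — inventing an exclusion window
  would be a silent analysis choice, so it is left to the user.
* `run_pipeline()` validates seeds before any computation and writes every
  table atomically (temp file, then rename), so a failed run leaves no
  partial output behind.

## Problem sizes

The test suite and acceptance script run the full 25-mixture design with
181 (or, in stress loops, 46) wavelength channels; the noise-monotonicity
stress test uses 200 replicates at three noise levels and the
RMSEC-versus-RMSECV property uses 50 replicated simulations. These sizes
were chosen as the smallest that make the stochastic properties stable
across seeds while keeping the whole suite comfortably fast on a laptop.

## Known limitations

* Band-shape defaults are surrogates, not measured absorptivities.
* Only two-factor designs are generated; other level counts require a
  user-supplied generator.
* PLS1 (per-component) models, kernel/nonlinear PLS, derivative or smoothing
  pre-processing, k-fold/venetian-blind CV and wavelength-selection
  algorithms are out of scope.
* The plasma scenario models the interferent as one reproducible spectral
  shape with level jitter; real plasma background varies in shape between
  donors.
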