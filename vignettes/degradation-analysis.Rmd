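---
title: "Hybridization-mode-aware degradation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybridization-mode-aware degradation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `hookdeg`, the tunable parameters
and their defaults, the numerical choices made where the design was open,
what the chip simulator does and does not emulate, and the known
limitations. It states no empirical results beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## 1. The hybridization model

Probe intensities on PM/MM 3'-expression arrays are modelled by the
two-species hyperbolic Langmuir isotherm

$$ I^P = M \frac{X^{P,S} + X^{P,N}}{1 + X^{P,S} + X^{P,N}} + O, \qquad
   P \in \{PM, MM\}, $$

with binding strengths proportional to the concentrations of specific
($S$) and non-specific ($N$) transcripts, a common saturation intensity $M$
and optical background $O$ (assumed pre-subtracted or negligible; a
constant-background option exists on ingest). Degradation and incomplete
3'-primed amplification reduce the coverage of a probe at position $x$ by a
factor $d(x) \le 1$ that multiplies $X^{P,S}$; the non-specific
concentration is reduced by the chip-mean factor $d$ because it tracks the
total amount of RNA.

Two consequences drive everything else:

* only the specific part of the signal carries the positional bias, and
* saturation compresses any intensity ratio toward 1.

Probe positions are expressed either as the probe index $k$ within the set
(counted toward the 5'-end, $k = 1$ nearest the 3'-end — note this is the
reverse of vendor ordering; `chip_data(reverse_k = TRUE)` converts) or as
the distance $L$ in nucleotides between the transcript 3'-end and the
probe's nearest base ($L = 0$ for a probe abutting the terminus; when a
probe matches its target at several positions the most 3' match is taken,
with a warning). The two scales are linked by the mean probe spacing
$\langle \Delta L\rangle$ (nucleotides per index increment, typically
25-60 nt). The primary spacing estimator is the least-squares slope of the
median $L$ per index versus $k$; the vanishing-intercept ratio
$\langle L\rangle/\langle k\rangle$ and the two-point estimator
$(\langle L_{last}\rangle - \langle L_1\rangle)/(N_{pset}-1)$ are reported
alongside. Only the ratio estimator is sensitive to a uniform translation
of all positions; the slope and two-point estimators are not.

## 2. Hook transformation and fit

Per probe pair, $\Sigma = \tfrac12(\log PM + \log MM)$ and
$\Delta = \log PM - \log MM$ (all logs decadic). Per-set averages sorted by
$\Sigma$ and smoothed with a moving window give the hook curve. The
theoretical curve, parameterized by the latent specific/non-specific ratio
$R$, is

$$ \Delta(R) = \log\frac{R+1}{R\,10^{-\alpha}+1}
             - \log\frac{B^{PM}(R)}{B^{MM}(R)}, \qquad
   \Sigma(R) = \Sigma_{start} + \tfrac12\log\big[(R+1)(R\,10^{-\alpha}+1)\big]
             - \tfrac12\log\big[B^{PM}B^{MM}\big], $$

with saturation terms
$B^{PM} = 1 + 10^{-\beta+\Delta_{start}/2}(R+1)$ and
$B^{MM} = 1 + 10^{-\beta+\Delta_{start}/2}(R\,10^{-\alpha}+1)$, and
asymptote $\log M = \Sigma_{start} + \beta - \Delta_{start}/2$. Here
$\alpha$ is the PM/MM log affinity gap of specific binding (hook height,
typically ~0.85), $\beta$ the hook width (a proxy for the inverse
non-specific background), and $\Sigma_{start}$ the non-specific signal
level.

Numerical choices:

* **Smoothing** (`moving_average`): centered window, default 1000 probe
  sets; toward the top 5% of ranks the window shrinks linearly to one tenth
  (and follows the right edge), compensating the sparse saturation range.
  Points whose (possibly shrunk) window does not fit are dropped rather
  than padded.
* **Fitting** (`fit_hook`): Levenberg-Marquardt least squares of
  $\Delta$ at matched $\Sigma$, the latent $R$ eliminated by evaluating the
  model on a dense $\log R$ grid and interpolating. Initialization:
  $\Sigma_{start}$ at the 2nd percentile of $\Sigma$, $\log M$ at the 98th
  percentile + 0.3, $\alpha = \max\Delta$, $\beta = \log M - \Sigma_{start}$.
  Because the saturation terms involve $\beta$ and $\Delta_{start}$ only
  through $\beta - \Delta_{start}/2$, $\Delta_{start}$ is not separately
  identifiable from the curve shape; it is pinned to the mean $\Delta$ of
  the N-range (left end of the smoothed curve) and the remaining three
  parameters are fitted. A curve without a specific branch
  ($\max\Delta < 0.1$) or spanning less than half a decade in $\Sigma$ is
  rejected.
* **Regime classification** (`classify_regimes`): per-set $\Sigma$ is
  inverted monotonically to $R$; boundaries are $R < 0.1$ (N),
  $R < 1$ (mix), $R < R_{sat}$ (S) with $R_{sat}$ where $B^{PM} = 2$, and
  $\Sigma > \log M - 0.05$ (as). The absent fraction %N is the fraction of
  N-labelled sets; near the non-specific level the $\Sigma \to R$ mapping
  is shallow, so individual labels there carry noise (the %N recovery tests
  run at realistic set counts for this reason). The expression index is
  $\phi = \langle \log R\rangle_{present} + \Sigma_{start} - \log M$; the
  offset is a convention anchoring $\phi$ to the saturation level.

## 3. Degradation statistics

**Tongs plot / degradation hook.** Per set, $\Sigma$ is averaged over the
three most-3' probes, the three centered on the middle probe, and the three
most-5' probes; their differences to the set mean (tongs branches) and the
3'-5' difference (degradation hook) are smoothed against $\Sigma$. The
theoretical ordinate (`theoretical_tongs`) replaces $R$ by
$R\,10^{\gamma_s}$ per subset; `fit_tongs_opening` fits $\gamma_{3'}$ and
$\gamma_{5'}$ with the hook-shape parameters held fixed and returns the
tongs opening $\Delta\gamma_{3'/5'} = \gamma_{3'} - \gamma_{5'}$. The
smoothed-curve maximum is reported as a model-free fallback and becomes the
primary value only if the fit fails (the fitted value is primary when both
exist, because the maximum is attenuated by smoothing and saturation).
Conversions: $d_{tongs} = 10^{-\Delta\gamma}$ and
$\overline{\log d} \approx -0.5\,\Delta\gamma$ (geometric-mean argument,
valid for probes uniformly covering the probed region and a 3' subset close
to full coverage; with an initial shift of ~2 probes the approximation is
good to better than 10%).

**Positional decay.** Mean log PM per position over the specific or
non-specific ensemble (specific = S-regime sets, plus mix sets with
$R \ge 10^{-0.5}$ by default), normalized at the 3'-reference (geometric
mean of $k \in \{1,2\}$, or the first populated 25-nt bin below 150 nt on
the $L$-scale; bins with fewer than 20 probes are suppressed). The decay
law $d(x) = (1-d_\infty)e^{-(x-x_0)/\lambda} + d_\infty$ is fitted by
bounded Levenberg-Marquardt; on the index scale the fit coordinate is
$x = k-1$ (distance from the 3'-reference probe) and $d_\infty$ is fixed to
0 by default, since the index scale compresses the asymptotic range into
the last probes; on the nucleotide scale the default fit range is
$100 < L < 600$ (beyond ~600 nt probes are sparse and behave differently,
so that range is excluded from fitting). $\lambda$ and $d_\infty$ are
strongly correlated when the data span little curvature — single-exponential
fits (`fix_d_inf = 0`) are preferable whenever the asymptote is not clearly
reached.

**Two-point ratio.** $\log d^k$ = mean log PM over the last two probe
indices minus the first two, over the specific ensemble; fewer than 50
contributing sets flags low confidence. Decay-length conversions use the
conventional constant 8, $\lambda_k = -8/\ln d^k$ and
$\lambda_L = \lambda_k\langle\Delta L\rangle$ (the sign is fixed so
$\lambda > 0$). Note the averaging indices $\{1,2\}$ vs $\{10,11\}$ imply a
mean index gap of 9 (or 8.5 under a one-probe initial shift) rather than 8;
the constant 8 is kept for comparability, and the package's consistency
tests account for the actual span of the generating law.

**All-probe slope.** `affyslope` reproduces the legacy metric (OLS slope of
mean log PM vs $k$ over *all* probes). It is provided for comparison only:
absent probes do not respond to degradation, so the slope shrinks roughly
in proportion to the present fraction — the package's tests demonstrate the
strict decrease of $|slope|$ with the absent fraction while the
specific-ensemble $d^k$ is stable.

## 4. Control probes and the threshold hook

Control genes are summarized PM-only: $\Delta^{control}_{3'/5'}$ = mean log
PM of the 3' set minus the 5' set, against the mean signal of both sets.
The conventional quality rule ($3'/5'$ ratio below 3, i.e.
$\Delta < \log_{10} 3 \approx 0.48$) is valid only in the specific,
unsaturated range. `build_threshold_hook` traces the PM-only isotherm
trajectory of a 3'/5' pairing between the fitted hook's anchors
($\Sigma_{start}$ and $\log M$), dropping the MM terms analytically, and
calibrates the underlying true bias by 1-D root finding so that the curve's
maximum equals the constant threshold (to $10^{-6}$; the argmax is included
in the tabulated curve). The constant threshold defaults to
$\log_{10} 3 = 0.48$ and is configurable (0.47 is also in circulation).
Points below the hook threshold are TP, between the two thresholds FP, at
or above the constant one TN; FN = 0 by construction since the hook never
exceeds the constant. Boundary ties go to the worse-quality side.
PPV = TP/(TP+FP), SP = TN/(FP+TN).

## 5. Intensity correction

The correction rescales raw intensities, $I^{corr} = I / C(x, y)$, with
$C$ built from (i) the positional coverage decay $d_S(x)$ and (ii) a
per-set weight looked up at the set-mean log intensity $y$ (PM and MM each
use their own set mean, so the weaker specific content of MM probes is
reflected in their smaller correction).

Design choices, made after the straightforward variants proved inaccurate
on simulated chips:

* **Reference decay.** The raw intensity profile of the specific ensemble
  underestimates the coverage decay: the non-specific floor props up the
  distal probes and saturation compresses the proximal ones. The model
  therefore recovers each probe's specific binding strength through the
  fitted isotherm, $X = I/(M-I) - b$ with $b = 10^{\Sigma_{start}-\log M}$
  (`specific_decay_profile`), and fits the decay law on that profile with
  the model clamped at 1 (coverage cannot exceed the 3' level). On
  simulated chips this recovers the generating decay length where the raw
  profile is ~40% too long.
* **Per-set weight.** The default (`f_method = "isotherm"`) tabulates the
  binding ratio $R$ against $y$ by inverting the smoothed hook abscissa
  (per-set inversion is too noisy near the background level) and applies
  the correction as the ratio of isotherm intensities with and without the
  coverage factor. In the linear range this reduces to the mixture
  $C = d_S f + (1-f)$ with $f = R/(R+1)$ — non-specific signal is left
  untouched, fully specific signal is fully corrected — and under
  saturation it compresses the correction exactly as saturation compresses
  the bias. Sets in the N regime ($R < 0.1$) are strictly uncorrected.
  The alternative (`f_method = "hook"`) weights by the degradation-hook
  amplitude normalized to its maximum, the more direct graphical reading;
  it needs no inversion but under-weights sets of intermediate specificity,
  leaving a residual bias on the round-trip tests, and is therefore not the
  default.
* **Scales.** The index-scale correction (default) applies one factor per
  probe index and is robust to outliers; the $L$-scale variant uses each
  probe's nucleotide position and is more specific to sets with unusual
  layouts. Outside the tabulated $y$ range the nearest endpoint is used;
  chips whose degradation hook opens less than 0.05 (no detectable bias)
  or that lack a specific ensemble get the identity correction.

The round-trip property — correct, re-analyze, find $|\log d^k|$ and the
re-estimated opening near zero — is exercised in the test suite at the
default study conditions.

## 6. The chip simulator

`simulate_chip` draws one array from the same isotherm the analysis
assumes: a linear probe layout ($L = L_1 + \langle\Delta L\rangle(k-1)$
plus jitter), a fraction of absent sets with zero specific concentration,
log-uniform expression for the rest, per-probe affinity factors, positional
coverage $d(x)$ scaling the specific strengths and the chip-mean $d$
scaling the non-specific ones, and multiplicative log-normal intensity
noise. It is deterministic given the seed, and returns the generating
truth (per-probe coverage, mean degradation index, tongs opening and
two-point ratio of the coverage law) for recovery tests.

Default study conditions (chosen once, before any test outcomes, as a
realistic mid-size 3'-expression array):

| parameter | default | rationale |
|---|---|---|
| probe sets x size | 5000 x 11 | mid-size array at desk-scale runtime |
| spacing, first probe | 50 nt, 20-100 nt | typical layout; jitter +-10 nt |
| absent fraction | 0.30 | mid-range of published %N values |
| expression | log-uniform, 4 decades from R = 0.1 | continuum from the detection boundary into saturation |
| background $x_N$ | $10^{-2.5}$ | puts $\Sigma_{start}$ ~2.7 decades below $\log M$ |
| $M$, $O$ | $10^4$, 0 | background-subtracted input |
| $\alpha$ | 0.85 | typical PM/MM gap |
| affinity spread (S, N) | 0.20, 0.05 (log10 sd) | residual spread of sequence-corrected intensities; non-specific binding averages many targets and is narrower |
| intensity noise | 0.05 (log10 sd) | measurement noise of ~12% CV |
| decay | single exponential in $k$, shift $k_0 = 2$, $\lambda$ solved for opening 0.5 | initial shifts of 1-2 probes are typical; 0.5 is a strongly degraded sample |
| washing $w$ | 1 | washing asymmetries only enter the closed-form ratio limits |

The simulator emulates sequence-*corrected* data — the input the hook
analysis expects — hence the modest residual affinity spreads; raw
GeneChip intensities have much wider per-probe affinity variation, and no
sequence model is included (an additive log-scale pre-correction can be
applied upstream). It also does not emulate spatial artefacts, optical
saturation of the scanner, target depletion, or probe-specific washing.
Passing recovery tests therefore demonstrates correctness of the
estimators under the model's own assumptions, not robustness to every
artefact of real arrays.

Property-style tests that probe a specific mechanism use purpose-built
conditions stated in the test: the absent-probe dilution of the all-probe
slope and the decay-length consistency checks run at strong expression
($R \ge 30$, expression span 1.5 decades, background $10^{-3.5}$) so the
specific ensemble is floor- and saturation-free, isolating the effect
under test; problem sizes there are 2500-6000 sets. These are scientific
choices about which regime exhibits the mechanism, not tuning.

## 7. Degenerate inputs and edge rules

* Probe sets with fewer than 3 valid pairs are excluded; pairs with a
  missing intensity are dropped.
* A table without MM engages PM-only mode: $\Sigma_p = \log PM$, hook
  fitting and regime classification are disabled, the tongs curves and
  $d^k$ (over all sets) are still computed and the opening falls back to
  the curve maximum.
* All-identical positions give spacing 0 with a degenerate-layout warning;
  a single probe index is an error.
* Ties at classification thresholds: the constant-threshold boundary is
  assigned TN, the hook-threshold boundary FP (worse-quality side).
* `log d^k >= 0` leaves the decay lengths undefined (flagged), and a
  positive two-point ratio above 0.05 warns (5' brighter than 3').

## 8. Known limitations

* Sequence-specific affinity correction is out of scope; raw (or
  externally pre-corrected) log intensities are used. On raw intensities
  the wide affinity spread inflates the apparent N-range and blurs regime
  boundaries.
* %N classification near the background level is intrinsically noisy
  (shallow $\Sigma(R)$); %N is reliable as a chip-level summary, not per
  set.
* The exponential-plus-constant decay family fits the 100-600 nt range;
  the sparse far range is excluded rather than modelled.
* The correction is as good as the hook fit behind it; for chips without a
  specific branch it degrades gracefully to the identity.
* No RIN prediction and no per-gene expression summarization are included;
  corrected probe tables feed any downstream preprocessor.
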