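---
title: "Vibroarthrographic signal analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibroarthrographic signal analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The diagnostic problem

Vibroarthrography (VAG) records the vibrations and sounds emitted by a knee
joint during flexion–extension. Smooth, well-lubricated cartilage moves
quietly; degenerated surfaces grind and emit transient acoustic bursts
(crepitus). `vagdx` implements a complete analysis chain that turns raw
two-channel VAG recordings (medial and lateral joint-line microphones, 10 Hz
to 2 kHz band, plus a knee-angle encoder) into a binary healthy-control (HC)
versus osteoarthritis (OA) classification:

1. **Segmentation** — motion cycles are located from the encoder trace.
2. **Cleaning** — ensemble empirical mode decomposition (EEMD) removes the
   monotonic sensor-drift trend.
3. **State indicators** — twelve time-domain measures per channel per
   segment.
4. **Feature selection** — neighbourhood component analysis (NCA) weights.
5. **Classification** — MLP and RBF networks on selected measures plus
   demographics, with confusion/ROC reporting.

Because no public recordings of this kind exist, the package ships a seeded
synthetic generator that reproduces the *statistical* structure the analysis
assumes, so every stage is testable end to end.

## The synthetic cohort generator

`generate_dataset()` simulates a cohort in which each HC subject contributes
both knees and each OA subject one affected knee, every knee recorded in an
open (OKC) and a closed (CKC) kinetic chain. Demographics are drawn per
group from a configurable table (defaults: HC age 24.10 ± 5.56 y, height
1.71 ± 0.09 m, BMI 21.95 ± 3.09, 24/33 female; OA age 56.15 ± 12.99 y,
height 1.69 ± 0.09 m, BMI 31.19 ± 4.83, 19/34 female). Weight is *induced*
as `bmi * height^2` rather than drawn independently: BMI is a nonlinear
function of weight and height, so drawing all three marginals independently
cannot reproduce the BMI mean (Jensen's inequality shifts it upward by
roughly 1%). We chose to match the age, height, sex and BMI marginals
exactly and accept a ~0.3% bias on the weight mean, because BMI — not raw
weight — is a classifier input.

Each channel of a recording is the sum of five components:

* **friction noise** — band-limited Gaussian noise (10–1000 Hz) whose
  envelope follows the instantaneous angular speed,
  `0.6 + 0.4 |ω|/ω_max`. The modulation floor of 0.6 is deliberate: with a
  deeper modulation the amplitude-modulated Gaussian becomes strongly
  leptokurtic (a variance mixture), whereas measured healthy joints show
  near-Gaussian motion-portion statistics. With this floor the motion
  portion has kurtosis ≈ 3.1–3.2 before the white-noise floor pulls it
  closer to 3.
* **crepitus impulses** (OA knees only) — Poisson arrivals (default 8/s)
  gated to samples where the joint is actually moving, each a damped
  500 Hz oscillation (τ = 4 ms) with log-normal amplitude around 0.8
  relative units (σ_log = 0.3) and random sign. The two channels share
  impulse times — crepitus is one mechanical event seen by both sensors —
  but have independent noise. The default amplitude is an intentionally
  strong effect: the generator's job is to provide a cohort on which a
  correct pipeline must succeed, not to calibrate clinical difficulty.
* **sensor drift** — a linear monotonic ramp of total excursion 0.2
  (random sign per channel), the artifact the EEMD residual removal is
  designed to eliminate.
* **mains interference** — a 50 Hz sinusoid of amplitude 0.02 with random
  phase (European recording site).
* **white measurement noise** — SD 0.05.

Amplitudes are dimensionless: the recording hardware's gain is unspecified,
and signals are peak-normalized before feature extraction anyway. The
default sampling rate is 4096 Hz (at least twice the 2 kHz sensor
bandwidth); the encoder runs at 10 Hz, quantized to the 10-bit code grid
(360/1024 degrees) and hard-stopped to 0–90°. The angle profile is
`90·sin²(πt/T)` per cycle; OA knees optionally use `sin⁴` (`gentle = TRUE`),
giving the slower movement on- and offsets seen in painful joints.

What the generator does **not** model: cartilage contact mechanics, chain-
or knee-specific signal differences, non-stationary artifact bursts,
inter-subject gain variation. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that group differences of the modelled
kind are recovered — not that the clinical accuracies reported on real
patients are reproduced.

## Segmentation

`detect_motion_segments()` thresholds the smoothed absolute angular
velocity (default 5°/s) computed from the encoder. Velocity crosses zero
momentarily at peak flexion, so sub-threshold dips shorter than
`merge_gap = 0.5` s are bridged — otherwise every cycle would split into a
flexion and an extension half. Segments are padded by 0.1 s and mapped to
0-based, half-open sample index ranges. A constant trace yields an empty
segment list, not an error.

## EMD and EEMD

Empirical mode decomposition repeatedly *sifts* the signal: cubic-spline
envelopes are fitted through the local maxima and minima, their pointwise
mean is subtracted, and the process repeats until the component satisfies
the IMF conditions. Numerical choices (the literature leaves them open):

* **Envelope boundaries** — two extrema are mirrored across each end of
  the series before fitting a natural cubic spline (linear extrapolation
  outside the knots). Without mirroring the splines swing wildly at the
  edges.
* **Sifting stoppage** — a Cauchy-type criterion
  `Σ(d_prev − d_new)² / Σ d_prev² < 0.2`, combined with the IMF condition
  that extrema and zero-crossing counts differ by at most one, capped at
  100 iterations.
* **Extraction stop** — when the remainder has fewer than two maxima or
  minima (it is then monotonic up to flat runs) or `max_imfs` (12) is
  reached.

The sifting core is implemented in C++ for speed; the test suite contains
an independently coded pure-R sifting loop (via `stats::splinefun`) and
asserts agreement below 1e-8, as well as exact reconstruction
(`Σ IMFs + residual = input` to 1e-10 relative) on every decomposition.

EEMD runs EMD on `ensemble_size` noise-added copies (white noise SD =
`noise_std_fraction · sd(x)`, defaults N = 100, fraction 0.2 — common
practice) and averages IMFs by index, padding missing trailing IMFs with
zeros. With zero noise it reduces *exactly* to EMD. Averaged EEMD output
reconstructs the input only up to an O(noise/√N) remainder — this is a
property of the algorithm, not a defect — and the tests assert the error
shrinks with N. `detrend_and_clean()` subtracts the (mean) residual, i.e.
the monotonic drift, and can optionally drop the first high-frequency IMFs;
by default it drops none, because only the trend removal is a documented
requirement of the analysis and additional mode removal is a judgement
call left to the user.

## State indicators

`compute_features()` returns, per segment and channel: mean (MV),
straightened average (SA = mean |x|), RMS, peak (PV), peak-to-peak (PPV),
crest factor CF = PV/RMS, impact factor IF, shape factor SF, variance
(N−1 denominator), kurtosis, and the impulse-sensitive moment ratios
M6A = μ₆/μ₂³ and M8A = μ₈/μ₂⁴ (population 1/N moments inside the ratios,
as is conventional for these indicators). Impulse-rich signals raise the
even-moment ratios far above their Gaussian reference values (3, 15, 105)
— that is the diagnostic premise, and the tests verify it on matched
HC/OA signal pairs.

One deliberate deviation from the literal formulas: IF and SF are defined
with the *signed* mean in some sources, which collapses to zero for
oscillatory signals and makes the ratios explode. The package uses the
straightened average SA as the denominator (standard vibroacoustics
practice); `literal_mean = TRUE` restores the signed-mean reading.
Degenerate (constant) segments report the undefined ratios as `NA` with a
warning and are excluded from feature tables rather than imputed.

## NCA feature selection

The selection weights are learned by maximising the regularised
leave-one-out soft nearest-neighbour objective

F(w) = Σᵢ pᵢ − λ Σₗ wₗ²,  with  D_w(xᵢ,xⱼ) = Σₗ wₗ² |xᵢₗ − xⱼₗ|,
κ(z) = exp(−z/σ),

by projected gradient ascent (non-negativity by clipping, backtracking
step halving, all-ones start). The analytic gradient is verified against
finite differences to 1e-5. Features are standardized first — the weighted
distance is otherwise scale-dependent — and σ defaults to 1 on that scale.
Selection keeps features with weight above `T = 0.02 · max(w)`.

Two practical notes. First, the objective rewards *any* weight growth that
sharpens the soft-neighbour assignment, so with weak regularisation noise
features can acquire substantial weights; useful λ values for cohort-sized
data (N ≈ 100) sit around λ·N ≈ 50–200, and the default cross-validation
grid spans 5–200 in units of 1/N_t. Second, CV loss curves are often flat
across that range (ties resolve to the smallest λ), so tuned selections
tend to be permissive — they keep most genuinely informative measures plus
the occasional borderline one, much as cohort analyses of this kind retain
7–9 of the 12 candidate measures. Where a sparse, stable selection matters
more than squeezing CV loss, a fixed λ of about 2/N_t·N (i.e. λ ≈ 2 on
standardized data at N = 100) suppresses the noise features reliably; the
recovery tests use that setting.

## Classifiers

Variants are labels over chains — variant I = CKC, II = OKC, III = both
chains concatenated (the mapping is an explicit configuration entry because
naming conventions for such variants differ between reports). Inputs are
`[age, sex(M=0/F=1), BMI]` plus the selected measures, channels averaged
per knee by default (`aggregate = "channel"` keeps medial/lateral separate
columns). For variant III, selection runs over the 24 concatenated
chain-specific columns.

The MLP is a single-hidden-layer network trained by BFGS (via
`stats::optim`) with analytic gradients, several seeded restarts, and the
activation/error combinations used in classical neural-network packages:
logistic or linear hidden units; softmax, "exponential" (exp renormalized
across the two outputs — algebraically a softmax, which guarantees valid
probabilities) or linear outputs; sum-of-squares or cross-entropy error.
Weight initialisation is uniform(−0.5, 0.5) scaled by fan-in. The RBF
network uses Gaussian units centred by k-means (the training points
themselves when `n_hidden = n_train`, giving exact interpolation at zero
ridge), widths from nearest-centre spacing, and an output layer fitted by
least squares (linear) or binomial IRLS (softmax). `auto_search()` trains a
candidate grid and keeps the best validation-accuracy network per kind,
ties to fewer hidden units.

Data are split 70/15/15 (training gets `round(0.7n)`, the remainder splits
`floor/ceil` between test and validation), stratified by class.

## Evaluation

`roc_curve()` enumerates one point per distinct score cutoff (ties
grouped); `auroc()` integrates trapezoidally, which equals the tie-corrected
pairwise-comparison probability exactly — the tests assert equality against
exhaustive enumeration on small sets. The reported operating threshold
maximises Youden's J = TPR − FPR over midpoints between consecutive
distinct scores (ties to the lower cutoff; with perfectly separating scores
this is the midpoint of the inter-class gap). Which probability cutoff a
clinical report means by "ROC threshold" is rarely stated; Youden's J is
the conventional choice and produces cutoffs in the 0.5–0.65 range typical
of such tables. Confusion tables report per-class totals, correct and
incorrect counts, and percentages rounded to two decimals.

## Problem sizes used by tests and the acceptance script

The generator's scientific defaults (4 cycles of 4 s, EEMD ensemble 100)
describe a realistic examination but are unnecessarily heavy for automated
verification. The test suite and `scripts/acceptance.R` therefore run the
same code paths at reduced sizes, chosen once: 1 cycle of 1 s with 0.5 s
rests, EEMD ensemble 2–4, and (for the end-to-end recovery check) the CKC
chain with an MLP of 9 hidden units over 10 seeds on the full 33 HC / 34 OA
cohort. At the default strong impulse effect these settings separate the
groups essentially perfectly, so the end-to-end thresholds (mean test
accuracy ≥ 90%, AUROC ≥ 0.95) are comfortably met; they verify pipeline
correctness, not clinical performance.

## Known limitations

* EEMD output is an ensemble mean: completeness holds exactly for EMD and
  for the zero-noise limit only.
* The generator's group difference is carried almost entirely by the
  impulse process; demographic covariates alone already separate the
  groups strongly (age differs by ~32 years between the default cohorts),
  which is faithful to the cohort design but means demographics-only
  baselines are far from chance.
* NCA selection inherits the tie-to-smallest-λ rule; on flat CV loss
  curves it is permissive rather than sparse.
* No frequency-domain features, no CEEMDAN-family decompositions, no
  confidence intervals on AUROC.
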