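---
title: "Estimating the channel capacity of GPCR calcium signaling in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the channel capacity of GPCR calcium signaling in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chancap)
```

## The question and the model

When a Gq-coupled receptor such as the muscarinic M3R is stimulated with an
agonist (acetylcholine), the cell answers with a transient rise of
intracellular calcium whose peak height grows with the agonist
concentration over the cell's dynamic range. Treating the pathway as a
communication channel — input: the agonist concentration $c$; output: the
calcium peak response $r$ — its *channel capacity*
$C = \max_{P(c)} I(r; c)$ measures, in bits, how many agonist levels the
cell can distinguish reliably. A capacity of 1 bit means an on/off sensor;
$n$ bits resolve $2^n$ levels.

`chancap` estimates $C$ per cell from repeated-stimulation recordings in
which each cell is pulsed $K$ times at each of $N$ ascending
concentrations. The response model is additive in log space:

$$ r_{ijk} = \mu_i(c_j) + e_{ik}(c_j), $$

where $r_{ijk}$ is the log peak response of cell $i$ to the $k$-th pulse of
concentration $c_j$, $\mu_i(c_j)$ is that cell's mean log response, and the
noise $e$ is shared across cells but specific to each concentration. The
replicate residuals (each log response minus its within-cell,
within-concentration mean) are symmetric and heavy-tailed, and are modeled
by a scaled Student t density with per-concentration scale $\sigma_j$ and
degrees of freedom $\nu_j$, fitted by maximum likelihood on the residuals
pooled across cells.

Given $\mu_i(\cdot)$ and $(\sigma_j, \nu_j)$, the conditional output
density $P_i(r \mid c)$ is fully specified and the capacity is a concave
maximization over the input distribution. Two estimates are reported per
cell:

* **lower bound** — the input support is restricted to the $N$ tested
  concentrations, so the estimate can never exceed $\log_2 N$
  ($\log_2 7 \approx 2.807$ bits for the default design);
* **interpolated** — $\mu_i$, $\sigma$ and $\nu$ are interpolated
  piecewise-linearly in $\log_{10} c$ between the tested knots and the
  optimization runs over a fine concentration grid spanning the tested
  range, relaxing the finite-alphabet restriction.

## Peak extraction from raw traces

Raw inputs are per-cell Fura-2 340/380 ratio traces sampled at 1 frame/s.
The extraction stage mirrors the classical workflow:

1. *Background removal.* The recording background rises slowly; it is
   estimated as a smoothed rolling minimum with a window longer than one
   pulse period (default 181 s against the 120 s period), subtracted, and
   the corrected trace recentred on its 20th percentile so inter-pulse
   intervals sit near zero. The rolling-minimum estimator is our choice: it
   is parameter-light and robust to monotone drift.
2. *Peak detection.* The $x = N \times K$ expected peaks are searched.
   Prominent maxima (above 6 baseline-noise MADs, where the noise scale is
   read from the lower half of the corrected trace) anchor a median time
   offset against a template — the schedule itself, or the detected peak
   times of a representative cell. Every pulse's height is then the local
   maximum of the corrected trace within ±12 s of its projected time;
   pulses without an independent detection (typically early
   low-concentration pulses buried in background) are flagged
   `extrapolated` and placed at the projected time. Fewer than two
   prominent peaks make the template unanchorable and the cell is dropped.
3. *Reference selection.* The original workflow had the user pick the most
   representative trace. For reproducibility this is automated: the cell
   with the most independently detected peaks wins (ties: higher median
   peak height, then lowest cell id), and a manual override is available.
4. *Artifact removal.* Within each (cell, concentration) group of at least
   3 peaks, log heights deviating from the group median by more than 5
   group MADs are flagged `artifact_removed` — a reproducible surrogate for
   removal by eye. Heights are stored as natural-log peak heights, floored
   at $10^{-3}$ of the cell's maximum corrected amplitude so the log is
   always defined; capacities are converted to bits only at reporting time.

## Noise model

The scaled-t log-likelihood is maximized over $(\log \sigma, \log \nu)$
with L-BFGS-B, $\nu \in [0.5, 200]$, from three starts
($\nu_0 \in \{2, 5, 30\}$, $\sigma_0$ moment-matched); the best optimum is
kept, and tests verify it against an exhaustive $(\sigma, \nu)$ grid
search. Degenerate inputs (constant residuals) are rejected. Two
deliberate properties, both inherited from the original procedure:

* residuals from groups with fewer than 2 retained replicates are excluded;
* the group-mean subtraction removes $1/K$ of the noise variance, and this
  deflation is **not** corrected. With $K = 5$ the fitted scale is biased
  low by a factor $\sqrt{4/5} \approx 0.894$, which propagates into a
  capacity inflation of roughly $\log_2\!\sqrt{K/(K-1)} \approx 0.16$ bits
  (see *Limitations*).

## Capacity solver

Mutual information is computed by deterministic quadrature: the output axis
is discretized on a uniform grid spanning every conditional mean ±8 times
its 99.9% noise quantile, densified automatically so the spacing never
exceeds a quarter of the smallest $\sigma$ (a fixed grid cannot resolve
near-noise-free conditionals); each conditional is checked to carry at
least 0.999 of its mass inside the grid and renormalized.

The capacity-achieving input distribution is found by Blahut–Arimoto, which
is globally convergent for this concave problem. Two refinements keep fine
interpolation grids fast without changing what is certified: the
multiplicative update is overrelaxed ($p \propto p\,e^{\gamma D}$ with an
adaptive $\gamma$ that falls back to the plain update whenever the
objective would decrease, so the accepted objective sequence is
non-decreasing), and iteration runs on an active set of inputs whose weight
has not collapsed, with periodic Kuhn–Tucker checks over the full support
that re-admit violators. Convergence is declared only when the
full-support capacity gap falls below $10^{-4}$ bits (iteration cap 5000,
reported with a warning when hit); the gap is a valid optimality
certificate for the returned distribution regardless of the path taken.
Unit tests pin the solver to exhaustive simplex grid searches on 2- and
3-input channels.

The interpolated support is the union of a nominal $M = 101$-point uniform
$\log_{10} c$ grid and the tested knots, so the tested support is a subset
of the interpolated one and the interpolated estimate can never fall below
the lower bound (beyond solver tolerance). Sensitivity to $M$ is small: on
a test cell, $M \in \{51, 101, 201\}$ agree within 0.02 bits. $\nu$ is
interpolated linearly like $\sigma$ and $\mu$; there is no extrapolation
outside the tested range. EC50 is read off the normalized profile
$(\mu - \min\mu)/(\max\mu - \min\mu)$ as the first crossing of 0.5,
interpolated in $\log_{10} c$; cells with flat or non-crossing profiles
keep their capacity estimates but are excluded from the EC50 report.

## Adaptation

Repeated stimulation desensitizes the response by a little under 1% per
pulse. Three tools quantify and handle this:

* `consecutive_correlation` pools within-cell pairs of consecutive
  responses and regresses response $n{+}1$ on response $n$ **on the linear
  scale** — under a constant multiplicative decay $d$ the noise-free slope
  equals $d$, whereas in log space it would be exactly 1 — and tests
  slope = 1.
* `fit_decay` regresses log response on pulse index with per-cell
  intercepts (cells differ in strength; pooling without intercepts invites
  Simpson-type bias — a pooled variant is available) and reports the
  per-pulse decay $1 - e^{\hat\beta}$ with a 95% CI, plus the implied
  20-pulse drop $1 - e^{20\hat\beta}$ ($1 - 0.99^{20} \approx 18.2\%$ for
  $d = 0.99$).
* `adaptation_correct` subtracts, from every log response at a given pulse
  number, the across-cell median of the replicate residual at that pulse.
  The corrections are centred within each concentration block: Eq.-5
  residuals are group-mean-centred, so their per-pulse medians are
  within-block quantities anyway (raw and centred corrections coincide
  exactly in the noiseless case), and centring makes the operation exactly
  idempotent and profile-preserving. Pulses with fewer than 3 residuals
  are left uncorrected with a warning.

## The synthetic-data generator

The generator produces datasets with exactly the statistical structure the
analysis assumes, so every stage is testable without any external data.
Defaults encode the study conditions; where the protocol fixes a value it
is used as-is, and the remaining choices were made once, on dose-response
grounds, and are listed here:

* design: 100, 250, 500, 750, 1500, 3000, 10000 nM; $K = 5$; 10 s pulses;
  110 s gaps; 1 frame/s; 8 s rise to peak (protocol: 7–9 s);
* per-cell mean response: 4-parameter log-logistic (Hill) curve in
  $\log_{10} c$ — baseline log response $\mathcal{N}(\log 0.05, 0.3)$,
  span $\mathcal{N}(3.4, 0.3)$ log units, Hill slope uniform on
  $[0.8, 1.8]$, and $\log_{10}$EC50 uniform across the tested range so
  dynamic ranges are shifted along the concentration axis, as observed;
  the distribution of plateau heights is not constrained by the source
  data and is exposed as a parameter rather than asserted;
* noise: scaled-t with $\sigma$ falling linearly from 0.30 to 0.10 log
  units and $\nu$ rising from 3 to 10 across the ascending concentrations
  — heavier relative noise near the detection floor, the
  $\nu \approx 3\text{–}10$ heavy-tailed regime throughout;
* desensitization: $d = 0.99$ applied additively in log space as
  $(\text{pulse} - 1)\log d$ over the global ascending pulse schedule;
* traces: linear 8 s rise to the peak height, exponential decay with
  $\tau = 20$ s, baseline 0.3 with a rising drift of $5\times10^{-5}$ per
  frame, Gaussian measurement noise (sd 0.003);
* reproducibility: one master seed; each cell's draws come from a
  deterministic substream, so adding cells never perturbs existing ones.

The shipped repeated-stimulation (adaptation) dataset emulates the
corresponding preliminary experiment: cells that respond at 250 nM (EC50s
drawn at or below the stimulus) with the response-regime noise of the
defaults ($\sigma = 0.10$, $\nu = 10$). One caveat is worth stating: a
consecutive-response correlation as high as 0.999 on the linear scale
implies within-cell noise of only ~1–2% CV, noticeably smaller than what
heavy-tailed noise compatible with ~2-bit capacities produces; the
synthetic correlation therefore lands near 0.9 rather than 0.999, and no
parameter was tuned to force agreement.

Each cell's true capacity (discrete and interpolated) is computed from the
true $\mu_i$ and noise parameters by an independent quadrature — Simpson
weights on a wider grid and a separately coded maximization loop — and
serves as the cross-module oracle for the estimation path.

What the generator does **not** emulate: photobleaching, cell movement,
segmentation error, pulse-shape variability, correlated (non-i.i.d.)
residuals, and state-dependent desensitization. Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
assumed model, not robustness of the model itself on real recordings.

## Problem sizes and tolerances

The shipped analyses use 60-cell populations (25 cells × 20 pulses for
adaptation), a 101-point interpolation grid, an output quadrature of at
least 2001 points, a $10^{-4}$-bit solver gap, and a 50-residual floor per
noise fit; recovery experiments in the test suite use up to 100 cells and
$10^5$ residual draws. These sizes give stable population means (Monte
Carlo error well below the effects studied) while keeping any single
analysis in the minutes range on one core.

## Limitations

* **Plug-in bias.** Capacity is estimated by plugging in $\hat\mu_i$ from
  $K = 5$ replicates and the fitted noise. The residual-variance deflation
  described above inflates the population mean capacity by ~0.16 bits, and
  profile jitter adds a smaller upward bias (~0.04 bits at the default
  noise). Both are faithful to the original procedure; recovery against
  ground truth is therefore benchmarked with the generator's known noise
  model, and the refit bias is reported alongside it by the acceptance
  script.
* The finite output grid and the $[c_1, c_N]$ interpolation range cap the
  interpolated estimate at $\log_2 M'$ bits for an $M'$-point support and
  ignore any response structure outside the tested range; cells with EC50
  near the edges of the tested range are underestimated.
* The channel is treated as memoryless; desensitization is removed (or not)
  as a preprocessing step rather than modeled as channel memory.
* Artifact flagging (5 MADs) and the automated reference choice are
  reproducible surrogates for manual steps of the original workflow and may
  disagree with it on borderline peaks.
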