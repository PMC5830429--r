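# chancap

How much information does a G-protein-coupled receptor pathway transmit in
a single cell? `chancap` answers this for calcium responses to repeated
agonist stimulation: it treats the pathway (agonist concentration in,
calcium peak response out) as a noisy communication channel and estimates
each cell's **channel capacity** — the maximum, over input distributions
$P(c)$, of the mutual information

$$ I(r;c) = \iint P(r\mid c)\,P(c)\,
   \log_2\frac{P(r\mid c)}{P(r)} \, \mathrm{d}r\,\mathrm{d}c , $$

in bits. It is written for experimentalists and modelers working with
single-cell dose–response recordings (e.g. Fura-2 ratio imaging of
muscarinic M3R–Gq–PLCβ–IP₃–Ca²⁺ signaling in HEK293 cells, the system the
default protocol encodes: 7 ascending acetylcholine concentrations from
100 nM to 10 µM, 5 pulses of 10 s each, 110 s apart).

The model: the log peak response of cell $i$ to the $k$-th pulse of
concentration $c_j$ is

$$ r_{ijk} = \mu_i(c_j) + e_{ik}(c_j), $$

with a cell-specific mean dose–response $\mu_i$ and heavy-tailed noise
$e$ shared across cells, modeled per concentration as a scaled Student t
(scale $\sigma_j$, degrees of freedom $\nu_j$) fitted by maximum
likelihood to the replicate residuals. Capacity is maximized by
Blahut–Arimoto iteration on a quadrature-discretized output, twice per
cell: restricted to the tested concentrations (a **lower bound**, capped
at $\log_2 7 \approx 2.81$ bits) and on a fine concentration grid with
$(\mu_i, \sigma, \nu)$ interpolated piecewise-linearly in $\log_{10} c$
(the **interpolated** estimate). The package also covers the surrounding
workflow: peak extraction from raw ratio traces (background removal,
template-aligned detection of the 35 expected peaks, artifact exclusion),
per-cell EC50s, desensitization analysis (consecutive-response
correlation and slope, per-pulse decay from log-space regression), a
median-residual adaptation correction, and a synthetic-data generator that
reproduces the assumed statistical structure with known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data: `01_simulate.R` (datasets), `02_extract_peaks.R` (trace round trip),
`03_fit_noise.R` (scaled-t noise model), `04_capacity.R` (per-cell
capacities), `05_adaptation.R` (desensitization and correction). Running
them in order prints, for a 60-cell population at the default conditions
(seed 20260):

```
$ Rscript analysis/04_capacity.R
cells estimated: 60
lower bound:   1.69 +/- 0.25 bits (mean +/- sd)
interpolated:  1.98 +/- 0.35 bits (mean +/- sd)
discrete ceiling for 7 inputs: log2(7) = 2.807 bits
...
$ Rscript analysis/05_adaptation.R
consecutive responses (n=475 pairs): r = 0.9322, slope = 0.9264
  test of slope = 1: p = 1.06e-05
per-pulse decay: 1.05% (95% CI 0.87% - 1.22%), p = 8.89e-28
implied drop over 20 pulses: 19.0%
mean interpolated capacity: 1.985 bits raw, 1.998 corrected
adaptation correction changes the mean capacity by +0.7%
```

Reading: a typical synthetic cell reliably distinguishes about
$2^{1.98} \approx 4$ agonist levels; the interpolated estimate exceeds the
lower bound for every cell because the tested concentrations are a subset
of its input support. The regression slope below 1 and the ~1% per-pulse
decay (the generator's truth is exactly 1%) quantify desensitization;
correcting it nudges capacity up. The same machinery runs on real data:
point `run_config(traces_file = ...)` (columns `time_s, cell_id, ratio`)
or `run_config(peaks_file = ...)` (columns `cell_id, concentration_nM,
replicate, pulse_index, peak_log_response`) at your recordings and call
`run_pipeline()`.

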