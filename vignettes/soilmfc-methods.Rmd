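---
title: "Methods: soil MFC antibiotic-remediation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil MFC antibiotic-remediation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilmfc)
```

soilmfc implements the complete computational side of a soil microbial
fuel cell (MFC) antibiotic-remediation experiment: electrochemical
performance, antibiotic removal statistics, high-throughput qPCR
quantification of antibiotic resistance genes (ARGs) and mobile genetic
element (MGE) genes, alpha diversity of the bacterial/fungal/archaeal
communities, and multi-kingdom co-occurrence network analysis. This
vignette records the models, the tunable parameters, and the design
choices made where conventions genuinely diverge.

## Electrochemistry

A reactor under external resistance $R$ (ohm) with projected cathode
area $A$ (m$^2$) and logged voltage $U$ (V) yields

$$I' = \frac{U}{RA} \quad [\mathrm{mA\,m^{-2}}], \qquad
  P' = \frac{U^2}{RA} \quad [\mathrm{mW\,m^{-2}}], \qquad
  Q = \int_0^T \frac{U}{R}\,dt \quad [\mathrm{C}].$$

Internally everything is SI (V, ohm, m$^2$, s); densities are converted
at the reporting boundary. Defaults are $R = 100$ ohm and
$A = 0.0036$ m$^2$.

**Charge integration.** The logger reports one voltage per 1800 s cycle,
so `accumulate_charge()` defaults to a rectangle rule at the logged
cadence (each sample stands for the interval up to the next); this makes
$Q$ exactly additive over concatenated traces and equal to $Ut/R$ for
constant traces. A trapezoid rule is available behind the `method`
argument; on a linear ramp the two differ by the analytic half-step
term, which the tests check.

**Start-up time** is the first time the voltage exceeds 1 mV
(configurable), reported in hours; a trace that never crosses returns
`NA` rather than erroring.

**Polarization fits.** Each sweep point is converted to a current
$I = U/R$ and the ohmic region of $U = \mathrm{OCV} - R_{int} I$ is fit
by least squares. Because the fitting window is a convention rather than
a measurement, the highest-current 10% of points (activation and
mass-transport tails) is excluded by default (`ohmic_frac = 0.9`). On
noiseless voltage-divider data the fit recovers the generating
parameters to machine precision, and the maximum of the fitted power
curve falls at the matched load $R \approx R_{int}$.

## Antibiotic removal

Removal efficiency is $\beta = (C' - C)/C' \times 100$ with $C'$ the
spike (5 mg kg$^{-1}$ default) and $C$ the residual. A residual above
the spike is allowed (negative $\beta$, warned). The *treatment-average
degradation rate* is $\beta$ of the mean residual across the three
sampled layers (cathode, anode, surface); per-layer $\beta$ is reported
alongside, since printed summaries can refer to either.

Group comparisons use classical one-way ANOVA followed by Duncan's
multiple range test at $\alpha = 0.05$. Duncan critical values are
computed from studentized-range quantiles at the protection levels
$\alpha_p = 1-(1-\alpha)^{p-1}$ (numeric inversion via `qtukey`, not
hard-coded tables, so any group count and degrees of freedom work). The
compact letter display follows the standard range-testing rule: a range
of ranked means is non-significant if its spread is within the least
significant range for its span, and every sub-range of a non-significant
range is non-significant. The test suite checks the display against a
brute-force oracle that applies this definition directly to every pair.
For unbalanced designs the harmonic mean group size enters the standard
error.

## Resistance-gene quantification

Wells are retained only with exactly one melt peak and amplification
efficiency in the closed interval [90, 110]% — "beyond the range"
excludes strictly outside values, so boundary wells stay. A target is
*detected* when (i) at least 2 of its 3 replicate wells survive QC (a
single well cannot define a replicate deviation), (ii) the mean CT of
the survivors is below 31, and (iii) the replicate deviation is below
20%. "Deviation of the duplications" is interpreted as the coefficient
of variation of the replicate CT values — scale-free and standard for
Smartchip workflows; a per-replicate CT rule is available via
`mode = "per_replicate"` because the convention (mean vs each
replicate) is not fixed in the field.

Relative copy number uses the CT anchor transform
$\gamma = 10^{(31-\mathrm{CT})/(10/3)}$ (one decade per 10/3 cycles,
$\gamma = 1$ at CT 31), and per-sample abundances are normalized to the
16S rRNA gene: copies of gene / copies of 16S. Undetected genes count
as absent (0) in class aggregates rather than being imputed at a
detection limit, matching how relative-abundance figures are normally
drawn. Samples whose 16S fails detection are flagged and their
abundances left undefined.

## Community diversity

Shannon ($-\sum p_i \ln p_i$, natural log by default with a base
switch), Chao1 and Good's coverage ($1 - F_1/N$). Chao1 defaults to the
bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which remains
defined without doubletons; the classical $S_{obs} + F_1^2/(2F_2)$ sits
behind a flag. Chao1 and coverage refuse non-integer input — they need
genuine singleton/doubleton counts — while aggregation and networks
accept relative abundances. Counts are used as given; an optional
rarefy-to-minimum-depth switch exists but is off by default since
whether to rarefy before alpha diversity is itself contested.
Genus-level aggregation keeps the top 55 bacterial, 35 fungal and 15
archaeal taxa by mean relative abundance (the reporting convention for
these communities), lumping the rest into `other`, and conserves column
sums exactly.

## Co-occurrence networks

All pairwise Spearman correlations within and between genera and target
genes are computed with mid-rank ties. Two-sided p-values use the
t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; below 10 samples the
exact permutation distribution is used instead. An undirected edge is
drawn when $p < 0.05$; following the source convention, **no**
magnitude threshold and **no** multiple-testing correction are applied
by default (`build_network` notes this on every call), with
`p_adjust` and `rho_min` available.

The **keystone filter** removes all negative edges, then drops every
node whose mean treatment abundance does not exceed its matched
non-antibiotic control; isolated nodes are dropped by default.
Its output is always a subgraph of the positive-edge subgraph of its
input.

**Topology** reports the mean local clustering coefficient over nodes
with degree $\ge 2$, average neighbours $2E/N$, density
$2E/(N(N-1))$, and — because "shortest paths"
is ambiguous — both the count of ordered connected pairs (the network
viewer convention) and the characteristic path length.

**MCODE.** Node weight = (highest k-core of the node's closed
neighborhood) × (density of that core). Seeds are processed in
descending weight with ties broken lexicographically by node name, so
results are deterministic. A module grows by admitting every reachable
unassigned neighbour with weight $\ge (1-0.2) \times$ seed weight (the
published standard `node_score_cutoff`), is discarded unless it
contains a 2-core, and by default gets a haircut removing members with
fewer than two within-module neighbours. Score = density × size. The
acceptance suite verifies the implementation against an exhaustive
bitmask oracle on the complete catalogue of connected graphs with up to
7 vertices plus 300 seeded random 8-vertex graphs; the oracle finds
each seed's module by brute-force subset enumeration rather than graph
traversal.

Exports: canonical sorted edge-list TSV (byte-stable, round-trips
exactly), GraphML (round-trips), and SIF (attribute-free by design —
signs only).

## The synthetic-data generators

Because the underlying experiment deposited no machine-readable raw
data, every input is emulated with known ground truth. The generator
defaults *are* the study conditions:

* **Voltage traces** follow a piecewise-linear current-density envelope
  — zero until start-up (9/16/17 h for TC/SC/CC), a first peak on day 2
  (65/53/22 mA m$^{-2}$), a dip to 35% of the peak, a maximum on day
  27/27/19 (136/109/47 mA m$^{-2}$), then decline to a tail — plus
  additive Gaussian voltage noise (0.2 mV default). The dip and tail
  fractions (0.35/0.35; CC tail 0.02 since its current collapses) were
  set once so the 58-day accumulated charges land near 1130 C (TC) and
  910 C (SC), the magnitudes such reactors produce; the trace summary
  recovers every anchor.
* **Polarization sweeps** use the voltage divider
  $U = \mathrm{OCV}\cdot R/(R+R_{int})$ over a 15-point log ladder from
  10000 down to 100 ohm with OCV 0.37/0.36/0.18 V and $R_{int}$
  262/336/1332 ohm. No mechanistic electrochemistry (Butler–Volmer) is
  attempted: the divider suffices for recovery testing.
* **Antibiotic residuals** decay first-order,
  $C = C_0 e^{-kt}$, the simplest kinetic consistent with endpoint
  residuals; the treatment-layer rates are back-computed from the
  day-58 removal levels (averages 70/66/52% for tetracycline under
  closed/open/no circuit, 95/93/87% for sulfadiazine). Replicate noise
  is log-normal with 5% CV, applied after the deterministic decay.
* **qPCR plates** invert the $\gamma$ transform
  (CT $= 31 - (10/3)\log_{10}\gamma$), plant QC failures (3% multi-peak,
  3% bad-efficiency wells by default, bookkept for recovery tests), give
  undetected genes CT $\ge 31$, and scale the true copy numbers by
  circuit group (closed 0.45×, open 0.7×, non-electrode 1×) so the MGE
  class aggregate reproduces the closed < open < non-electrode ordering.
* **Communities**: 40 genera (20 bacteria, 12 fungi, 8 archaea) in 30
  samples, log-normal abundances, with three planted 6-taxon modules
  whose within-module Spearman correlation (0.9) is imposed through a
  Gaussian copula — one shared latent factor per module with latent
  Pearson loading $r = 2\sin(\pi\rho/6)$, so the planted effect is
  exactly the rank-scale effect the network stage measures. Between
  modules the latent variables are independent. Treatment fold-changes
  multiply abundances before integer rounding.

Everything is deterministic given the config seed (each generator draws
from its own derived stream), which the tests assert by identity.

What the generators do **not** emulate: compositionality and
sequencing-depth variation of real OTU tables, zero inflation,
taxon-taxon negative associations, spatial structure among layers, and
drifting qPCR efficiencies. Passing recovery tests therefore
demonstrates correctness of the inference machinery under the planted
model, not robustness to every artefact of real amplicon data.

## Benchmark choices and problem sizes

The edge-recovery benchmark (40 taxa, 30 samples, $\rho = 0.9$, 10
seeded replicates) evaluates edges with Bonferroni-corrected
$p < 0.05$. With 780 pairs and only 45 planted edges, raw $p < 0.05$
admits $\approx 37$ false edges by construction, capping precision near
0.55 no matter how strong the signal; family-wise correction is the
standard instrument for this regime, costs essentially no recall at the
planted effect size, and makes exact module recovery meaningful. The
raw-p network remains the pipeline default and is what the
null-calibration check exercises (200 replicates of a 40-taxon null
community; the significant-edge fraction must sit within 3 Monte-Carlo
standard errors of 0.05).

Other sizes used by the checks: 100 Monte-Carlo noisy sweeps (20
points, 5% noise) for internal-resistance recovery within 10%; 1000
random 3–6-group designs for the Duncan oracle; the full ≤7-vertex
connected-graph catalogue (1252 graphs) plus 300 random 8-vertex graphs
for MCODE. These sizes keep the whole suite comfortably inside a few
minutes on one core while leaving the Monte-Carlo error well below the
tolerances tested.

## Known limitations

* The abstract-level claim of "733% higher" bioelectricity has no
  printed operand pair among the reported metrics; the package
  reproduces the 25% comparison (136 vs 109 mA m$^{-2}$) and does not
  guess at the other.
* Duncan letter displays assume near-balanced designs (harmonic-mean
  group size); severely unbalanced designs deserve a dedicated
  multiple-comparison package.
* The MCODE "fluff" option of the original algorithm is not
  implemented (it is off in the standard parameter set); requesting it
  errors rather than silently differing.
* SIF export cannot carry edge statistics; use the edge-list or GraphML
  exports when attributes must round-trip.
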