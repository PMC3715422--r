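---
title: "Inferring partial allelic inactivation from RNA-FISH nucleus counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring partial allelic inactivation from RNA-FISH nucleus counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishact)
library(dplyr)
```

## The measurement and the model

RNA-FISH against nascent transcripts scores, for each nucleus, how many
alleles of a locus are transcribing at the moment of fixation. In a diploid
homogametic cell (ZZ male bird, XX female monotreme) a sex-linked test probe
can show two, one or zero signals. Two processes generate one- and
zero-signal nuclei:

* **detection failure** — a transcribing allele missed by the probe, with
  per-allele detection probability `p` (the hybridization efficiency), and
* **silencing** — in some fraction `s` of nuclei the allele on one
  chromosome is transcriptionally inactive.

`fishact` separates the two. Everything downstream rests on three modelling
commitments:

1. **The diploid-control gate.** Only nuclei showing exactly two signals
   from an autosomal control probe are scored (`filter_diploid()`). This
   removes polyploid nuclei and nuclei the probe mix failed to penetrate.
   Nuclei with one control signal but any number of test signals are
   excluded with everything else that fails the gate; the package never
   special-cases them.
2. **The binomial detection null.** If both alleles transcribe in every
   nucleus and detections are independent, signal counts are distributed
   `(p², 2pq, q²)` for two, one and zero signals. `p` is probe-specific and
   estimated in the heterogametic sex, where the locus is single-copy and
   every nucleus should show exactly one signal, so `p̂ = n1/(n1+n0)`
   (`estimate_efficiency()`). Two-signal heterogametic nuclei are an anomaly
   (warned, excluded from the estimate).
3. **Per-nucleus, non-heritable silencing.** The mixture model for
   homogametic counts is: with probability `s` one allele is silenced
   (signals ~ Binomial(1, p)), otherwise both transcribe
   (signals ~ Binomial(2, p)). Silencing is drawn independently per nucleus —
   daughter cells with discordant activity states are observed in these
   fibroblast cultures, so no lineage structure is modelled.

Under the mixture, the expected one-signal fraction is
`f1 = 2pq + s·p(2p−1)`, which gives the method-of-moments estimator used
throughout (`estimate_silencing()`):

```
ŝ = (f1_obs − 2pq) / (p(2p − 1)),  clamped to [0, 1]
```

It is unbiased under the generative model and requires `p > 0.5`, which every
usable FISH probe satisfies (panel efficiencies run 0.94–1.0).

## The two-stage test

`test_inactivation()` is the screening test: Pearson χ² of the observed
(n2, n1, n0) against `n·(p², 2pq, q²)`, 2 df. At `p` near 1 the expected
zero-signal count drops below 1, which both breaks the χ² approximation in
the tail and conflates technical dropout with biology. The package therefore
keeps all three categories (emitting a small-expected-count warning) but
treats the test as secondary.

The primary inference is `adjust_and_retest()`:

1. zero-signal nuclei are removed and the (two, one)-signal table
   renormalized;
2. the observed category fractions are moved toward the renormalized expected
   fractions by the experimental error rate — conceding that this much of the
   category frequency could be artefact;
3. a 1-df Pearson χ² is applied to the adjusted table.

The error rate comes from `estimate_error()`: autosomal loci are biallelic in
essentially every nucleus, so pooling all autosomal experiments,
`missed = Σ(2·n0 + n1)` signals out of `2·Σ n_scored` expected. Treating the
missed count as Poisson, the upper exact 95% limit (Garwood construction,
`poisson_exact_ci()`: `½·χ²(α/2, 2k)` to `½·χ²(1−α/2, 2k+2)`) divided by the
expected signal count is the conservative bound used for the adjustment. The
exact interval is deliberately conservative — analytic coverage is ≥ 95% at
every rate, which is the right direction for an error bound that feeds a
robustness argument.

Two readings of "shift the observed values by x% toward expected" are
arithmetically defensible; both are implemented. The default (`method =
"shift"`) moves each observed fraction `x` percentage points toward its
expectation, clamped so it never overshoots; `method = "scale"` shrinks the
gap by the relative factor `x`. The percentage-point reading is the default
because it reproduces the worked arithmetic the procedure was defined by
(an observed fraction 0.300 with expectation 0.0952 and rate 0.0155 adjusts
to 0.2845) and because it is the more conservative of the two at realistic
rates. `robustness_sweep()` re-tests over a rate grid — a locus that stays
significant under a 5-point shift cannot be explained by any plausible level
of missed hybridization.

Multiplicity is handled by Bonferroni (`bonferroni()`), with the family size
defaulting to the number of loci tested in the run — the natural family for
a per-species panel — and configurable because published analyses of this
design do not state their family explicitly. Significance is declared at
α = 0.01 after correction. No continuity correction is applied anywhere.

## Coordination of neighbouring loci

Two-color experiments on closely linked gene pairs ask two questions.

*Is there one shared active chromosome?* Among nuclei monoallelic for both
loci, signals from the same chromosome co-locate; `colocation_fraction()`
reports the fraction. The scorer supplies the boolean (image-distance
thresholding is upstream of this package); the simulator emits it with
fidelity γ for same-chromosome signals and never for opposite-homologue
signals.

*Is silencing coordinated?* Under gene-by-gene independence the expected
jointly biallelic fraction is the product of the marginal 2-active fractions
(`expected_joint_biallelic()`), with marginals taken from the single-probe
experiments rather than the pair experiment itself — the pair experiment
then provides an out-of-sample test. `test_coordination()` applies a 1-df χ²
on the (joint-biallelic vs not) split over **all** scored diploid nuclei;
renormalizing to nuclei expressing at least one allele of both genes would
change the denominator, but the published worked arithmetic for this design
uses all scored nuclei, and we match it. `classify_regime()` calls
`coordinated_escape` only for a significant *excess*; a significant deficit
is flagged as anti-coordination (the model offers no mechanism for it) but
classified `independent_escape`.

## The generative simulator

`simulate_population()` exists so that every stage of the pipeline is
testable with known ground truth; no raw per-nucleus data from the original
experiments is published. Per cell: ploidy (tetraploid with probability
`tetraploid_fraction`, doubling every allele count before detection, so the
control gate catches these cells whenever control detection is near 1); one
constitutively active chromosome and one inactivatable homologue in the
homogametic sex; per-locus silencing on the inactivatable copy with
probability `s`, coupled across declared pairs (locus B copies locus A's
state with probability ρ — exactly interpolating the independent ρ = 0 and
fully regional ρ = 1 regimes, and analytically tractable); pseudoautosomal
loci silenced on the inactivatable/Y side with the same `s` in both sexes;
single-copy sex-specific loci in the heterogametic sex; detection
Binomial(`alleles`, `p`).

Default study conditions follow the published setting: `study_panel_config()`
fixes 11 chicken-Z-like loci with silencing spanning 0.15–0.51 (efficiencies
0.95–1.0), 19 platypus-X-like loci spanning 0.25–0.62 (efficiencies
0.94–1.0, fourteen of them on X5), nine PAR-like loci with silencing
0.16–0.47, twelve autosomal loci with `s = 0`, two ρ = 0 chicken pairs and
three ρ = 1 platypus pairs, γ = 0.96, and 200 nuclei per hybridization per
sex (the experiments scored ≥ 100). The tetraploid fraction defaults to
0.05: published image panels show occasional 4n nuclei but no frequency
estimate exists, so this is a fixture choice — large enough to exercise the
control gate, small enough to stay realistic for early-passage fibroblast
cultures. Control-probe efficiency defaults to 0.99, consistent with
autosomal controls showing two signals in ≥ 95% of nuclei.

What the simulator does **not** emulate: spot-detection noise correlated
within a nucleus, spatial structure (co-location is reduced to the γ
Bernoulli), cell-cycle stage, lineage (silencing is redrawn per nucleus),
and any chromatin mechanism. Passing tests therefore demonstrate that the
statistics recover the parameters of this idealized process at the study's
sample sizes — not that the biological model is correct.

## Numerical and design choices

* **Seeds.** Every stochastic routine takes an explicit integer seed;
  identical seed and configuration reproduce output bit for bit. Replicated
  studies derive replicate seeds as `seed + r`.
* **Degenerate inputs.** `p = 1` with observed one- or zero-signal nuclei
  makes the 2-df statistic infinite; it is reported as `p_value = 0` with a
  `degenerate` flag rather than an error. Zero-expected categories with zero
  observations carry no information and are dropped from the statistic. An
  all-zero (n2 + n1 = 0) table cannot be adjusted and errors.
* **PAR loci in `score_panel()`.** Their efficiency cannot be calibrated
  from heterogametic nuclei (two alleles in both sexes), and the original
  design does not state how PAR efficiencies were obtained; they are tested
  (in both sexes) only when the caller supplies an efficiency or opts into
  the pooled mean of the sex-specific probes (`pooled = TRUE`). Sex-specific
  loci always use their own heterogametic estimate; the pooled fallback is
  off by default.
* **Power is quoted at the stated efficiency.** The power property (≥ 0.9 at
  `s = 0.15`, n = 200, p = 0.95, 11-fold Bonferroni, 1.55% adjustment) is an
  operating characteristic of the test given the probe's efficiency.
  Re-estimating `p` from a same-size heterogametic sample adds calibration
  noise and costs roughly nine points of power at this weakest-effect
  corner; with the several-hundred-nucleus calibration samples the design
  actually uses, the gap closes. This is a known limitation, not a test
  artifact.
* **Problem sizes.** The test suite and acceptance script use 200–2000
  nuclei per experiment, 30–500 Monte-Carlo replicates, and 10,000–100,000
  nuclei for law-of-large-numbers checks — sizes at which binomial standard
  errors sit comfortably inside the asserted tolerances.
* **Printed pair p-values.** The worked coordination arithmetic (expected
  45.6% from marginals 0.76 × 0.60) reproduces exactly, and the
  significance *pattern* of the published pair table reproduces, but its
  printed non-significant p-values (0.201, 0.776) are not what a plain 1-df
  Pearson χ² yields on those frequencies (which gives p ≈ 0.98 and 0.94).
  The computation behind those two numbers is ambiguous; the package does
  not target them.

## Limitations

Beyond the simulator's idealizations: the efficiency estimate treats `p` as
fixed per probe, ignoring slide-to-slide variation; the error bound pools
all autosomal experiments into one Poisson count, assuming a common error
rate across probes and sexes; and the coordination test conditions on
marginals estimated from separate experiments without propagating their
sampling error. All three simplifications match the original analysis design
and are conservative at the sample sizes involved, but they matter if the
package is pointed at much smaller experiments.
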