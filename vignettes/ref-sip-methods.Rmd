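---
title: "Methods: REF scoring of DNA-SIP gradients and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: REF scoring of DNA-SIP gradients and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipref)
```

## The problem

DNA stable-isotope probing (DNA-SIP) identifies which members of a
microbial community assimilate a particular substrate. Organisms that
incorporate a heavy isotope (here ^13^C from labeled bicarbonate) build
denser DNA, which bands lower in a CsCl density gradient after isopycnic
ultracentrifugation. Comparing the heavy region of a ^13^C-fed gradient
against a ^12^C-fed control separates true incorporation from the
confounding effect of genomic GC content, which also raises buoyant
density (BD).

`sipref` implements the inference chain used to find active
bicarbonate-assimilating bacteria in biological soil crusts (BSC) and the
soil beneath them (US), across a resuscitation phase (RP) and a sustained
hydration phase (SHP) after wetting:

1. **Stratification** of gradient fractions into *light* and *heavy* pools
   at a BD threshold of 1.7274 g/mL.
2. **Pooling** of fraction-level OTU counts into four relative-abundance
   profiles (^13^C-heavy, ^13^C-light, ^12^C-heavy, ^12^C-light).
3. **Scoring** each OTU with the relative enrichment factor
   \[
   \mathrm{REF} =
   \frac{\text{heavy}_{13C}/\text{light}_{13C}}
        {\text{heavy}_{12C}/\text{light}_{12C}},
   \]
4. **Calling** an OTU active when REF > 1.0 *and* its whole-community
   relative abundance exceeds 1.0% (both strict).
5. **Classifying** active OTUs as HCO~3~^−^-*fixers* (independent evidence
   of autotrophy) or HCO~3~^−^-*transformers* (heterotrophs presumed to
   acquire label through cross-feeding), and summarizing groups:
   fixer community share, fixer share of labeled OTUs, active counts, and
   relative biomass (RA × C, with C the extractable DNA concentration in
   µg per g soil).

A synthetic gradient simulator with known labeled taxa makes the whole
chain testable end-to-end without sequencing data, and a packaged table of
the published per-OTU results lets the summary statistics be reproduced
exactly.

## Stratification and pooling

The published analysis assigns fractions with BD > 1.7274 g/mL to heavy
DNA and < 1.7274 g/mL to light DNA, while describing the ^13^C
accumulation as starting in a fraction whose BD range *begins at* 1.7274.
`stratify_fractions()` therefore takes an `equality_rule` (default
`"heavy"`): a fraction exactly at the threshold joins the heavy pool.

`pool_counts()` computes a pooled abundance as a weighted mean of
per-fraction proportions. The default weight is each fraction's DNA
quantity, emulating the study's physical pooling of fraction DNA before a
single sequencing run per pool; `"counts"` weighting (equivalent to
summing raw reads) and `"equal"` weighting are offered for purely
in-silico reanalyses. The true physical pooling volumes are unrecoverable
from a published study, which is why the weighting is exposed rather than
fixed. Fractions with zero reads carry no weight, so pooled vectors always
sum to 1.

## REF zeros and the detection floor

REF involves three denominator-side components (`light_13C`,
`heavy_12C`, `light_12C`). If any of them is zero the ratio is undefined:
`compute_ref()` returns `NA` and the taxon can never be called active. No
pseudocount is applied by default, because pseudocounts change rankings
and should be a deliberate choice.

There is, however, a structural blind spot worth understanding. With a
within-taxon band spread of 0.004 g/mL and a full-labeling shift of
0.036 g/mL, a taxon at atom-fraction excess (AFE) 0.9 moves its band about
eight standard deviations. Such a taxon cannot simultaneously leave reads
in the ^13^C-light pool and in the ^12^C-heavy pool — whichever side of
the threshold its unlabeled band sits on, one of those two components is
an exact zero, REF is undefined, and the strongest incorporators become
invisible to the score. Real experiments are rescued by partial population
labeling and gradient smearing; an idealized single-band model is not.

The package's answer is a *detection floor* (`detection_floor` in
`compute_ref()`, `ref_results()` and `run_sip_pipeline()`): zeros in the
three denominator-side components are replaced by a floor interpreted as
one read-equivalent (1/depth, e.g. `1/50000`). The floor is asymmetric by
design — a zero **numerator** (`heavy_13C`) is never floored and yields
REF = 0 — so a taxon undetected in the ^13^C-heavy pool can never be
promoted to "enriched" by the substitution; the floor only bounds, from
below, the enrichment of taxa that *are* detected there. Analyses of
strongly labeled scenarios (and the recovery and monotonicity checks in
the test suite) enable the floor; null-calibration analyses leave it off.
The default remains off.

## The gradient simulator

`simulate_gradient()` is a statistical emulation of isopycnic
ultracentrifugation, not a hydrodynamic model:

* Unlabeled band center from the Schildkraut GC–density relation
  BD = 1.660 + 0.098·GC (g/mL); labeling adds 0.036·AFE.
* Each taxon's DNA is a normal band (sd 0.004 g/mL) integrated over
  twelve equal-width bins spanning 1.690–1.775 g/mL. The band is
  renormalized to its in-gradient part, so per-taxon mass is conserved
  exactly; a taxon whose band lies entirely outside the gradient is an
  error naming that taxon. Bins are half-open `[low, high)` with the
  densest bin closed; fraction 1 is the densest, so heavy DNA
  accumulates at low fraction indices, matching the field convention.
* Sequencing is multinomial per fraction at a fixed depth (default
  50,000 reads), with probabilities proportional to per-taxon mass in
  that fraction. This is the simplest noise model that preserves
  relative-abundance semantics; there is no PCR or compositional bias
  term. A fraction containing no DNA yields zero reads.
* `simulate_experiment()` pairs a ^13^C run with a ^12^C control (the
  same community with all AFE forced to 0), plus an unfractionated
  whole-community sample supplying the community relative abundances used
  by the activity threshold. All three draws take deterministically
  derived sub-seeds from the experiment seed, so a seed plus a
  configuration reproduces byte-identical tables; the two runs are
  stochastically independent, as two tubes in a centrifuge are.

All physical constants live in `gradient_config()` and none of the
scoring stages depend on them.

## The default synthetic community

`sim_community()` draws 50 taxa with lognormal abundances and a bimodal
GC distribution: ~90% of taxa from a low-GC mode (normal, mean 0.45,
sd 0.04, clipped to [0.33, 0.55]) and ~10% from a high-GC mode (mean
0.67, sd 0.015, clipped to [0.62, 0.72]). This mirrors a crust community
in which low-GC phototrophs and proteobacteria dominate and a minority
actinobacteria-like guild carries high-GC genomes. Labeled taxa get a
fixed baseline abundance (default 3%) so that sensitivity measures the
REF score, not the abundance filter.

The bimodal shape is also a calibration decision, made once from the
gradient arithmetic before any simulation was run. Under the null (no
labeling), any taxon detected in all four pools has P(REF > 1) exactly
1/2 — the score is a ratio of two independent, identically distributed
ratios — so the false-positive rate among abundant taxa is half the
fraction of abundant taxa that straddle the heavy boundary. Keeping the
dominant mode about 3 band-widths below the boundary confines straddling
to the high-GC guild and keeps the null false-positive rate among
abundant taxa under 10%, which the calibration analysis
(`analysis/05_calibration.R`) verifies by simulation (measured: ~9%,
pooled over 50 seeds; pooled median REF ≈ 0.99).

A consequence worth stating: the published gradients peak at
BD 1.7186–1.7219 (their "Fraction 10"), about 1.7 band-widths below the
boundary. A community centered there would put most taxa's null REF in
the defined range and could not satisfy the 10% null bound under this
noise model. The default community therefore centers slightly lower
(BD ≈ 1.704), and the simulated ^12^C peak falls one bin further into
the light side of this package's equal-width binning. The qualitative
peak structure — a unimodal ^12^C peak well into the light region, ^13^C
accumulation beyond the threshold — is preserved; matching the published
fraction *indices* exactly is ill-posed anyway because the published
fraction widths differ from the simulator's equal-width bins.

## What the simulator does not emulate

Passing the synthetic checks shows the chain is internally correct, not
that real data will behave as cleanly. Not modeled: partial population
labeling (each taxon is a single band, fully shifted by its AFE),
PCR/primer and compositional bias, chimeras, cross-fraction
contamination, gradient deformation, replicate-level variation (the study
pooled replicate DNA before ultracentrifugation, so the simulator emits
one gradient per treatment), and read-level error (no FASTQ simulation).
The activity thresholds themselves are the study's deliberately loose
screening criteria; on real data they admit weakly supported calls, which
is why the trophic classification is conservative.

## Trophic classification

`classify_trophic()` looks a semicolon-delimited lineage up in a
user-supplied reference of annotated lineages. An exact match wins;
otherwise the deepest shared lineage prefix with any annotated entry
decides (the phylogenetic-neighbor heuristic for unclassified taxa); if
nothing matches, or neighbors disagree at the matched depth, the
conservative default applies: a labeled taxon without autotrophy evidence
is a transformer. `"unknown"` is available as a default for non-study
uses. The packaged study table carries the published fixer/transformer
assignments as data; the package recomputes summaries from them, it does
not re-derive the annotations.

## Numerical choices

* Equality at the BD threshold: heavy by default, configurable
  (`equality_rule`), because the two published phrasings conflict.
* Active calls are strict inequalities on both thresholds; results are
  ordered by descending REF with ties broken by taxon id, so output is
  deterministic.
* Percentages are computed unrounded and rounded half away from zero to
  two decimals only at the presentation layer (`reproduce_summaries()`,
  summary JSON).
* Community abundances passed to `ref_results()` may be counts (sum > 1;
  normalized internally) or relative abundances (taken as given).
* Whole-community "original sample" libraries (phase `OS`) are accepted
  by the metadata reader for community description, but REF is only ever
  computed from a paired ^12^C/^13^C treatment.

## Problem sizes used by the tests

The test suite and the acceptance script run the chain at the defaults
the package documents: 50-taxon communities, 12 fractions, 50,000 reads
per fraction; 50 seeds for null calibration, 12 seeds for recovery, 20–25
seeds for the monotonicity and spurious-enrichment properties. These
sizes give the summary statistics stable second digits while keeping a
full run in the order of seconds.

## Reproducing the published summaries

`load_fixture()` ships the 23 printed per-OTU rows (17 unique OTUs).
`reproduce_summaries()` recomputes from them: US fixer community shares
2.34% (RP) and 17.04% (SHP); fixer shares of labeled OTUs 87.5% (BSC) and
50.0% (US); active-OTU counts 11 (RP), 8 (SHP), 17 (union). The two BSC
community shares recompute to 5.72% and 9.62% against printed values of
5.71% and 9.71%: the first is a rounding artifact of the two-decimal
inputs, the second cannot be reconciled from the published per-OTU values
alone (an unlisted contributing OTU or different rounding); both the
recomputed and printed numbers are reported, and only the four exactly
reproducible percentages are asserted exactly.

The published biomass values (1.96, 3.39, 0.21, 1.94 µg/g) require
per-sample DNA concentrations that are not part of the published main
text; `relative_biomass()` implements RA × C and is tested for its
algebraic properties (units, additivity over group members) instead.

## Known limitations

* REF is a screening statistic, not an estimator of isotope enrichment;
  it has no error model and the package deliberately adds no
  multiple-testing machinery, mirroring the source analysis. For
  quantitative atom-fraction-excess estimation, use a qSIP framework.
* With the default zero policy, fully labeled low-abundance taxa are
  undetectable (undefined REF); the detection floor recovers them at the
  cost of admitting taxa detected in the ^13^C-heavy pool only — on real
  data, enable it knowingly.
* The null calibration holds for communities whose bulk sits clear of
  the stratification boundary; a community dominated by high-GC taxa
  near the boundary will show an elevated false-positive rate at these
  loose thresholds, on simulated and real data alike.
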