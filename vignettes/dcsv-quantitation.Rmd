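---
title: "Spectral-count quantitation of secretory-vesicle proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count quantitation of secretory-vesicle proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsvquant)
```

## The problem

Dense-core secretory vesicles (DCSV, the chromaffin granules of the
sympathoadrenal system) store and release peptide hormones,
catecholamines, and related chemical messengers. Profiling their proteome
by GeLC-MS/MS — soluble and membrane fractions run in replicate gel lanes,
each lane cut into molecular-weight slices, each slice digested with
trypsin and run on LC-MS/MS — produces tens of thousands of
peptide-spectrum matches (PSMs) that must be filtered, mapped to a
non-redundant protein list, and turned into relative abundances before
any biology can be read off. `dcsvquant` implements that analysis chain
as composable, tested R functions, together with a synthetic-data
generator that reproduces the statistical structure of the design
(2 fractions × 4 replicate lanes × 8 slices) so every stage can be
validated without raw mass-spectrometry data.

## Identification: per-charge thresholds, rescue, and decoy FDR

A PSM carries a search score, a matched-intensity percentage (%SPI), and
a precursor charge. Acceptance is graded by charge: score ≥ 13 with
%SPI ≥ 70 for +1 and +2 precursors, score ≥ 16 with %SPI ≥ 70 for +3
(`threshold_set()`). A rescue rule admits additional PSMs with
score ≥ 10 and %SPI ≥ 70 when the protein they map to is supported by at
least two *distinct peptide sequences* at that level — peptide-level
evidence, not PSM counting, because two spectra of the same peptide are
not independent support. Rescue eligibility is computed over primary
acceptances and rescue candidates jointly.

Confidence is estimated by the target-decoy strategy: the database is
doubled with decoys built by twice-shuffling every target sequence
(`shuffle_decoy()`, preserving length and composition), and
`compute_fdr()` reports FDR = decoy identifications / target
identifications at the thresholds, per charge (+2 and +3 separately) and
in total, together with score histograms binned at one score unit
(left-closed bins starting at zero, so integer-boundary scores bin
unambiguously). `threshold_search()` inverts the computation: it scans
integer score cuts per charge for the smallest cut meeting an FDR goal.

Decoy PSMs take part in FDR estimation only; they are excluded from
inference and quantitation, as in standard target-decoy practice.

## Inference: single-linkage clustering and parsimony

Proteome databases contain isoforms that share most tryptic peptides.
`cluster_proteins()` links two proteins when their global sequence
identity is at least 95% over at least 90% coverage and takes connected
components (single linkage). Design choices worth stating:

* **Alignment scoring.** Identity is computed from a global alignment
  that maximises the number of identical aligned positions (match +1,
  mismatch 0, gaps free), with a deterministic diagonal-first traceback,
  implemented in C++. The denominator is the number of aligned columns
  after trimming terminal overhangs. Free gaps under-penalise nothing we
  care about here: the criterion only has to separate near-identical
  isoforms (identity ≈ 0.95–1) from unrelated sequences (identity
  ≈ 0.1–0.15 under this scoring), and a fixed tie-break makes the value
  well-defined and testable against an independent reference.
* **Coverage denominator.** "90% of the sequence length" is ambiguous for
  unequal lengths; the shorter sequence is used, matching the default
  behaviour of the clustering tools common in this field.
* **Seeding.** All-vs-all alignment is avoided with a BLAST-like shared
  8-mer prefilter: a pair at ≥95% identity over ≥90% of a ≥50-residue
  span must share an exact 8-mer, so the prefilter cannot lose true
  edges at the thresholds used.
* **Representatives.** Longest member, ties broken by smallest
  accession; cluster labels are representative accessions, which makes
  the output invariant to input order.

`minimal_protein_set()` then solves the parsimony problem: the smallest
protein set explaining every identified peptide, admitting isoforms only
when unique peptides require them. Minimum set cover is NP-hard in
general; the implementation is exact (subset enumeration in increasing
cardinality) up to 15 candidate proteins and falls back to greedy cover
above that, with ties broken toward cluster representatives, then longer
sequences, then accession order, followed by an irredundancy sweep.
Evidence instances arising after clustering are overwhelmingly small and
decomposable, so the exact route covers practical use; the greedy route
is retained (and separately tested) for large pathological inputs.

## Quantitation: NSAF, replicate rule, Diff-NSAF

The normalized spectral abundance factor for protein K in one
fraction-replicate run is

$$\mathrm{NSAF}_K = \frac{(\mathrm{SpC}/MW)_K}{\sum_I (\mathrm{SpC}/MW)_I},$$

where SpC is the spectral count summed over the 8 gel slices and MW the
molecular weight computed from sequence with average residue masses (a
consistent size proxy is all that is needed). Each run is normalized
independently, so NSAF sums to exactly 1 per sample.

Quantitation rules:

* A protein is **quantitated** in a fraction when observed in ≥ 3 of the
  4 replicate runs. Means are taken over the observed values; standard
  deviations over all 4 values with a zero filled in for each missed
  run, so missingness widens the uncertainty instead of vanishing.
* **Total NSAF** is recomputed from pooled soluble + membrane counts per
  replicate index — not averaged from the two fraction NSAFs — which
  keeps the normalization exact.
* **Only strictly accepted PSMs are counted.** Rescued PSMs support
  identification but not abundance: the rescue score band sits about one
  standard deviation above the null score mode, so rescued matches carry
  a false-match floor that would dominate the counts of low-abundance
  proteins while contributing little to well-measured ones.
* **Shared peptides** between retained proteins are credited to each
  (flagged in a message). Parsimony makes these rare; distributing
  shared counts (dNSAF-style) is deliberately out of scope.
* **Diff-NSAF** = (soluble − membrane mean NSAF) × 10³ drives the
  four-way class used in network figures: green (predominantly soluble),
  red (predominantly membrane), yellow (relative difference
  |S − M|/(S + M) < ε), grey (quantitated in neither fraction). The
  equal-distribution band has no published numeric cutoff; ε = 0.2 is the
  default and is configurable.

For distribution-level statistics (`ln_stats()`), NSAF values are
transformed to the natural log scale with non-measurements excluded,
normality of the soluble, membrane and total sets is checked with both
the D'Agostino-Pearson omnibus test (implemented here from the standard
skewness and kurtosis z-transforms, since no installed package provides
it; verified against an independent implementation) and Shapiro-Wilk,
and ln-soluble is compared with ln-membrane by the classical
equal-variance two-sample Student's t-test (Welch available behind a
flag). Constant or short inputs are reported as degenerate rather than
raising errors.

`category_summary()` sums member NSAFs per functional category within
every replicate and reports mean ± s.e.m. of the per-replicate sums.
`purity_estimate()` anchors contamination to the granule matrix protein
chromogranin A, assumed to compose ~46% of vesicle protein: each
contaminant organelle marker contributes
(NSAF marker / NSAF CgA) × 46%, and purity is 100 minus the summed
contamination, floored at zero.

## Network export

`node_attributes()` emits one row per protein (symbol, Diff-NSAF, colour
class, category, quantitation flag) for import into network tools;
identified-but-unquantitated proteins are grey, unresolvable accessions
are kept under their accession with a grey class. `read_edges()` accepts
two-column TSV or SIF edge lists — edges are inputs, never fetched from a
live service, for reproducibility. `kinase_partition()` splits the union
of two seed sets' direct neighbourhoods (e.g. PKA- and PKC-interacting
proteins) into A-only, B-only and shared interactors; seed subunit
symbols are user-supplied since no fixed subunit set is canonical.

## The synthetic generator: what it emulates, and what it does not

`generate_proteome()` + `generate_psms()` define the study conditions
every test runs under:

* **Proteome.** Default 200 proteins in 170 clusters (so ~30 isoform
  members), mean length 400 residues, uniform residue usage. Isoform
  members differ by 0.5–2% point substitutions, keeping within-cluster
  identity above 95% while leaving some peptides unique to members.
* **Abundance.** Log-uniform molar abundances spanning 10⁵, matching the
  dynamic range such organelle measurements display. Each protein has a
  soluble propensity θ ~ Beta(0.6, 0.6), giving both fraction-specific
  and shared proteins.
* **Counts.** Per run, per-protein counts are independent Poissons with
  expectation proportional to abundance × number of detectable tryptic
  peptides (7–30 residues, the standard observability window) split by
  θ — a multinomial count model conditional on run depth (default
  10⁴ signal PSMs per fraction-replicate; deep runs use 10⁵). The
  peptide-count factor makes spectral counts length-dependent, which is
  exactly what NSAF's MW division corrects; a dropout with probability
  exp(−expected count) adds the replicate missingness the 3-of-4 rule
  exists for.
* **Scores.** Correct matches draw scores from Normal(20, 4²), random
  matches from Normal(8, 2²), both clamped at zero and shifted +2 for +3
  precursors — placing the 13/16 thresholds between the modes. %SPI is
  Uniform(55, 100) for correct and Uniform(0, 100) for random matches.
  Random matches are injected at rate 0.1 of depth against both the
  target database (labelled `is_noise`, the ground truth that lets tests
  compare estimated FDR with the realized false-match fraction) and the
  decoy database, in equal expectation — the equality that makes the
  decoy count an unbiased estimate of the false-target count.
* **Slices.** Proteins map to 8 equal-probability molecular-weight bands
  with 10% spill-over to adjacent bands; no migration physics.
* **Markers.** The most abundant singleton-cluster protein is tagged as
  the granule matrix (CgA analogue) anchor and three low-abundance
  singleton proteins as mitochondrial/lysosomal/ER contaminants.
  Markers are restricted to singleton clusters because organelle
  contaminants are unrelated sequences and must not inherit
  shared-peptide counts from isoform clusters.

Not emulated: spectrum-level structure (m/z, retention time),
chromatography, inter-run batch effects, correlated noise between
fractions, or real amino-acid composition biases. Passing tests
therefore demonstrate the correctness of the computation and its
statistical behaviour under this model — not that the thresholds are
optimal for any particular instrument.

One subtlety the generator itself creates: after parsimony, a cluster
representative's counts pool its whole isoform cluster, so the quantity
it estimates is the cluster aggregate. `cluster_truth()` provides the
matching ground truth (summed abundance, abundance-weighted θ), and the
parameter-recovery tests compare against it. At depth 10⁵ with the
default proteome, Spearman correlation between cluster-truth abundance
and mean total NSAF exceeds 0.99, and proteins with θ ≥ 0.9 (≤ 0.1) are
classified green (red) in 100% of quantitated cases across the seeds
tested.

## Numerical and interface choices

* All tables are tab-separated with header rows; outputs are written to
  a temporary file and renamed, so a failed run never leaves a partial
  file.
* All randomness flows from the seed in `synthetic_config()`; PSM
  generation uses seed + 1 and decoy shuffling seed + 2 so stages draw
  from separate streams but one integer determines the whole run, making
  `run_pipeline()` byte-identical across reruns.
* Score histogram bins are left-closed, right-open, width 1, starting at
  0. Zero passing targets yields FDR = NaN with a warning, never a
  division error. Samples with no counts yield NA NSAF columns with a
  warning.
* Problem sizes used by the test-suite: digest/decoy properties at 10³
  random sequences, parsimony oracles at ≤ 12 proteins × ≤ 25 peptides
  (200 instances), recovery at 200 proteins × depth 10⁵ × 3 seeds, and
  the determinism check at depth 10⁴ — sizes at which every check runs
  in seconds to a few minutes on a laptop while keeping the statistical
  assertions sharp.

## Known limitations

* Shared-peptide counts are duplicated, not distributed; with many
  retained isoforms NSAF totals can double-count evidence (the message
  emitted by `count_matrix()` reports how often this occurs).
* The classical equal-variance t-test is reported because that is the
  named method in this analysis tradition; for unequal group sizes and
  variances prefer `welch = TRUE`.
* The purity formula is a ratio estimate anchored on an assumed CgA mass
  fraction; it propagates no uncertainty.
* `threshold_search()` scans integer cuts only, matching the histogram
  resolution of the FDR report.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(synthetic_config(depth = 1e4, seed = 1))
res <- run_pipeline(cfg, out_dir = "dcsv_run")
res
res$fdr
head(res$quant_table$quant)
res$purity
```
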