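# dcsvquant

Label-free quantitative proteomics of dense-core secretory vesicles
(DCSV, chromaffin granules) — and of organelle proteomes profiled the
same way: soluble and membrane fractions separated by SDS-PAGE in
replicate lanes, each lane cut into molecular-weight slices, each slice
trypsin-digested and run on LC-MS/MS. The package turns the resulting
peptide-spectrum matches (PSMs) into a decoy-validated, minimally
redundant, quantitative protein inventory, for proteomics analysts who
have search-engine exports (or want a fully synthetic testbed) rather
than raw spectra.

## What it computes

1. **Identification** — per-charge score/%SPI filtering (score ≥ 13,
   %SPI ≥ 70 for +1/+2; score ≥ 16 for +3) with a two-peptide rescue
   rule (score ≥ 10), and decoy-based false discovery rates from
   score-binned histograms:
   FDR = decoy identifications / target identifications.
2. **Inference** — single-linkage clustering of the protein database
   (> 95% identity over ≥ 90% coverage) and the smallest
   minimally-redundant protein set explaining all peptides, exact on
   small instances, greedy with an irredundancy sweep on large ones.
3. **Quantitation** — normalized spectral abundance factors per
   fraction-replicate run,

   NSAF_K = (SpC/MW)_K / Σ_I (SpC/MW)_I,

   the 3-of-4 replicate rule with zero-filled standard deviations,
   ln-scale normality checks (D'Agostino-Pearson and Shapiro-Wilk) and
   Student's t comparison of fractions, soluble-membrane differential
   classes (Diff-NSAF × 10³: green/red/yellow/grey), per-category NSAF
   sums, abundance ratios, and a chromogranin-A-anchored organelle
   purity estimate.
4. **Network export** — node-attribute tables carrying the Diff-NSAF
   colour classes for network tools, plus kinase-neighbourhood
   partitioning (e.g. PKA-only / PKC-only / both interactors).
5. **Synthetic data** — a generator emulating the whole design
   (2 fractions × 4 replicate lanes × 8 slices, isoform clusters,
   log-uniform abundances over 10⁵, target/decoy score distributions,
   replicate dropout) with ground truth for every stage.

## Worked example

```r
library(dcsvquant)

cfg <- pipeline_config(synthetic_config(depth = 1e4, seed = 1))
res <- run_pipeline(cfg)
res
#> Pipeline result: 96051 PSMs -> 50453 accepted + 2834 rescued -> 184 proteins identified, 122 quantitated
#> FDR (total): 0.000297
#> Estimated purity: 99.9%

res$fdr
#> Decoy-estimated FDR at thresholds (score >= 1:13, 2:13, 3:16; %SPI >= 70)
#>  charge n_target_pass n_decoy_pass          fdr
#>       2         30345           14 0.0004613610
#>       3         15065            0 0.0000000000
#>   total         50453           15 0.0002973064
```

96,051 simulated PSMs pass through the charge-graded filter (50,453
strict acceptances, 2,834 rescued by the two-peptide rule); parsimony
inference retains 184 proteins of which 122 meet the 3-of-4 replicate
rule in at least one fraction. The decoy estimate of the false discovery
rate at these thresholds is ~0.03%, and the three contaminant organelle
markers put vesicle purity at 99.9%.

```r
head(res$quant_table$quant[, c("id", "mean_total", "diff_nsaf_scaled", "dist_class")], 3)
#>        id mean_total diff_nsaf_scaled dist_class
#> 1 SYN0001   0.001048           -1.311        red
#> 2 SYN0002   0.003032           -6.442        red
#> 3 SYN0003   0.000000               NA       grey
```

Per protein: mean total NSAF (fraction of the run's size-corrected
spectral counts), the soluble-minus-membrane difference × 10³, and the
distribution class (red = predominantly membrane, green = soluble,
yellow = both, grey = identified but not quantitated).

Loading the reference NSAF table of the prohormone-processing pathway
(shipped with the package) reproduces its stoichiometry:

```r
tab <- read.delim(system.file("extdata", "prohormone_nsaf.tsv", package = "dcsvquant"))
abundance_ratio(tab, "PCSK2", "PCSK1")   # PC2 : PC1/3  = 3.12
abundance_ratio(tab, "CPE",   "PCSK1")   # CPE : PC1/3  = 6.04
```

## Documentation

The methods vignette (`vignettes/dcsv-quantitation.Rmd`) describes the
statistical model, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
known limitations.
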