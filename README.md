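# nucshift

Analysis tools for studies that link neuronal stimulation to changes in the
**nuclear proteome** and the **activity-dependent transcriptome** of
cultured neurons. The package is aimed at labs running nucleus-targeted
proximity-labeling (APEX2) TMT proteomics together with stratified bulk
RNA-seq of stimulated (bicuculline, *Bic*) versus silenced (tetrodotoxin,
*TTX*) cultures, and at anyone who wants a tested, scriptable
re-implementation of that workflow's statistics.

## What it computes

**TMT proximity proteomics.** PSM-level reporter intensities are
run-normalized on the silenced (TTX) reference channels, summarized into
protein log2 abundances by Tukey two-way median polish, and contrasted with
pooled-variance t tests and Benjamini-Hochberg adjustment. Two gates follow:
proteins *enriched above the no-APEX negative control* (log2 FC > 3 and
adjusted p < 0.05) and, among those, *activity-regulated* proteins
(|log2 FC| > 0.5 and raw p < 0.05, Bic vs TTX).

**Stratified differential expression.** Gene counts are analyzed per
sample-type stratum (PDCD4 WT or degradation-resistant S71A mutant, with or
without cycloheximide, CHX) by a negative-binomial log-link regression

    log mu = log(size factor) + batch + treatment

with median-of-ratios size factors, pooled method-of-moments dispersions and
a Wald test of the treatment coefficient (t reference with the pooled
moment df), BH-adjusted within each stratum.

**PDCD4 change-index target calling.** Activity-dependent genes
(adjusted p < 0.05 in the WT no-CHX stratum) are filtered for
CHX-insensitivity (significant, same-direction change under CHX; discordant
genes excluded), scored with the change index

    change index = |S - W| / |W|

where *W* and *S* are the Bic-vs-TTX log2 fold changes in the WT and S71A
no-CHX strata, and called putative PDCD4 targets when the index exceeds
0.75. The S71A-stratum categorization (up / no change / down per activity
direction) and fold-change-profile clustering for heatmaps are included.

**Quantification statistics.** Per-cell intensity normalization to the
control-condition median (per replicate), cotransfection-marker ratios,
Western loading-control/basal ratios, qPCR relative expression
E^dCt / GeoMean(housekeeping), and an exact-or-approximate two-sided
Mann-Whitney U test with Bonferroni correction.

**Synthetic data.** Seeded generators plant activity-dependent,
CHX-sensitive and PDCD4-dependent gene classes in NB counts, nuclear
enrichment and activity shifts in TMT reporter tables, and condition-median
structure in per-cell intensities — each with truth labels, so every stage
of the pipeline can be scored with `evaluate_recovery()`.

## Worked example

```r
library(nucshift)

# a full synthetic study: 5,000 genes, 8 sample types x 3 batches,
# 1,000 activity genes of which 200 are PDCD4-dependent (attenuation 0.1)
sim <- simulate_rnaseq_counts(rna_sim_config(), seed = 1)
report <- run_pipeline(sim$counts, sim$design, truth = sim$truth)
print(report)
#> nucshift pipeline report
#>   genes classified:       4997 (untestable excluded: 3)
#>   activity-dependent:     1012 (511 up, 501 down)
#>   CHX-insensitive:        476 (discordant excluded: 2)
#>   putative PDCD4 targets: 166
#>   target recovery:        precision 0.994, recall 0.825
```

The report counts read top-down through the cascade: of ~5,000 classified
genes, 1,012 change significantly with activity in the WT no-CHX stratum
(the truth planted 1,000); 476 of them also change, in the same direction,
under translation blockade (the truth planted 500 CHX-insensitive activity
genes); and 166 of those have a change index above 0.75, i.e. their
activity response is largely abolished when PDCD4 cannot be degraded —
capturing 165 of the 200 planted targets (recall 0.825) with 1 false call
(precision 0.994).

The proteomics arm works the same way:

```r
tsim <- simulate_tmt_psms(tmt_sim_config(), seed = 1)
res <- tmt_enrich(tsim$reporter_table)
length(res$enriched)   # proteins above the no-APEX control gate
#> [1] 292
ev <- evaluate_recovery(res$enriched, tsim$truth, label_col = "nuclear")
sprintf("gate sensitivity %.3f, FDP %.3f", ev$recall, ev$fdp)
#> [1] "gate sensitivity 0.973, FDP 0.000"
```

Input from files rather than simulation: `read_counts_matrix()` +
`read_sample_design()` feed `run_pipeline()`; `read_psm_table()` (PSM table
plus channel map) feeds `tmt_enrich()`. All outputs are plain TSV with
deterministic row order.

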