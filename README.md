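# epmotif

Predicting gene expression class from proximal flanking DNA, and mining
the fitted models for expression-predictive motifs (EPMs).

## What this package is for

For a genome with gene annotations and expression estimates (TPM tables),
`epmotif` asks how much of a gene's expression level is encoded in the
sequence immediately around it. Genes are labelled *low* / *medium* /
*high* by the quartiles of `logMaxTPM = log10(max TPM + 1)`, and a compact
1D convolutional neural network is trained to separate low from high genes
using only the fused flanking sequence — 1 kb promoter + 500 nt 5'UTR
upstream and 500 nt 3'UTR + 1 kb terminator downstream, joined by a 20 nt
`N` spacer into a 3020 nt one-hot input:

```
p(high | sequence) = CNN( onehot( promoter ++ 5'UTR ++ N20 ++ 3'UTR ++ terminator ) )
```

Validation is leave-one-chromosome-out, with homologous validation genes
(BLAST-style hits at e < 0.001 and bit score > 50) removed from the
validation sets so gene families cannot leak across the split, and
class-balanced training sets. A shuffled-sequence control (SSC) trains the
same model on composition-preserving shuffles.

The fitted classifier is then interpreted: per-nucleotide contribution
scores are backpropagated with the rescale rule against shuffled
references (contributions sum exactly to `f(x) - mean f(ref)`),
high-importance windows (seqlets) are aggregated into EPMs — contribution
weight matrices with base-frequency PWMs, IUPAC consensus, information
content, and TSS/TTS-anchored preferred positional ranges. EPMs can be
scanned against sequences with exact lattice p-values, tested for
enrichment in their expression class (log2 odds ratio), compared to
JASPAR-style reference databases by Pearson correlation, clustered across
models by consensus alignment, and traced across genotypes to classify
each motif as conserved or mutated and relate motif loss to predicted
expression shifts.

A synthetic-data module generates genomes with planted motifs, designed
expression classes, duplicated genes (homology) and genotype indels, so
the entire pipeline can be validated against known ground truth. It is
used by the test suite and the acceptance analysis.

Audience: computational biologists studying plant (or other compact)
genomes who want a self-contained, dependency-light reimplementation of
this modelling-plus-interpretation workflow in R.

## Worked example

End-to-end on a small synthetic genome (2 chromosomes x 400 genes, one
planted high-class motif `CACGTGAC` and one low-class motif `GATAAGGC`,
both inserted with probability 0.9 at TSS offsets 20-200 nt):

```r
library(epmotif)

scfg  <- synthetic_config(n_chroms = 2, genes_per_chrom = 400, seed = 7)
synth <- generate_genome(scfg)
tpm   <- generate_expression(synth)

labels <- label_expression(tpm)
table(labels$klass)
#>    low medium   high
#>    200    400    200

flanks    <- extract_all_flanks(synth$annotation, synth$genome, region_config())
sequences <- setNames(flanks$fused, flanks$gene_id)

folds <- make_folds(labels, synth$annotation,
                    load_homology(synth$homology), scheme = "SSR", seed = 1)
fit   <- train_folds(folds, sequences, labels, cnn_config(seed = 1))
fit[[1]]$model
#> Convolutional expression classifier (cre_cnn)
#>   input length : 3020 nt (one-hot, 4 channels)
#>   architecture : 3 conv blocks x 2 layers, filters [16,16,16], kernel 8, pool 4
#>   trained      : 76 epochs run, best epoch 66 (lowest val loss)
#>   validation   : accuracy 0.869, auROC 0.959, F1 0.871 (n = 183)
```

The validation accuracy is the fraction of held-out low/high genes called
correctly at the 0.5 probability threshold (probabilities at or below 0.5
are read as low expression); auROC is threshold-free. Interpreting the
fold model recovers the planted motif:

```r
f      <- folds[[1]]
tracks <- compute_contributions_batch(fit[[1]]$model, sequences[f$val_ids],
                                      k = 10, seed = 1)
epms   <- discover_epms(tracks, region_config(), seed = 1,
                        species_code = "Synt")
## the EPM best matching the planted high-class pattern
fwd  <- epms[vapply(epms, function(e) e$orientation == "fwd", NA)]
pccs <- vapply(fwd, function(e)
  compare_to_reference(list(e), list(ref = encode_seq("CACGTGAC")),
                       n_shuffles = 1, seed = 1)$pcc, 0)
hi <- fwd[[which.max(pccs)]]
round(max(pccs), 3)
#> [1] 0.998
hi
#> EPM epmSynt-S0-p0m04 [p0, fwd]: 39 seqlets, IC 14.4 bits, consensus CACGTGAC
#>   preferred range upstream (TSS-relative): [76.0, 159.0]
```

The `p0` metacluster marks motifs whose contributions push predictions
towards high expression; the trimmed consensus is exactly the planted
`CACGTGAC`, and the preferred range (the interquartile interval of seqlet
offsets downstream of the TSS) sits inside the planted 20-200 nt window.
Scanning and enrichment then quantify how strongly in-range occurrences
separate the classes:

```r
hi_set  <- list(hi, revcomp_epm(hi))
matches <- flag_preferred(
  scan_motifs(hi_set, sequences,
              scan_config(background = base_composition(sequences)),
              region_config()), hi_set)
epm_enrichment(hi, matches, labels)[, c("a", "A", "b", "B", "enrichment")]
#>    a   A b   B enrichment
#> 1 77 200 3 200   5.146111
```

i.e. in-range occurrences in 77 of 200 high genes versus 3 of 200 low
genes, a log2 odds ratio of about 5.1.

## Package layout

| area | functions |
|---|---|
| regions | `read_genome`, `read_annotation`, `region_config`, `extract_flanks`, `extract_all_flanks`, `encode_seq`, `decode_onehot` |
| labels | `aggregate_isoforms`, `log_max_tpm`, `expression_thresholds`, `assign_classes`, `label_expression` |
| folds | `load_homology`, `is_homologous`, `make_folds`, `shuffle_sequences` |
| model | `cnn_config`, `cre_cnn` (+ `predict`, `print`, `summary`, `plot`, `residuals`), `evaluate_classifier`, `train_folds` |
| attribution | `compute_contributions`, `compute_contributions_batch`, `sum_gene_score`, `average_saliency` |
| motifs | `extract_seqlets`, `split_metaclusters`, `cluster_and_aggregate`, `discover_epms`, `motif_properties`, `name_epm`, `parse_epm_name`, `revcomp_epm` |
| analysis | `scan_config`, `scan_motifs`, `pwm_score_distribution`, `flag_preferred`, `epm_enrichment`, `occurrence_chi2`, `compare_to_reference`, `cluster_epms` |
| genotypes | `analysis_config`, `classify_heterogeneity`, `epm_conservation`, `gene_conservation`, `bootstrap_percentages`, `fisher_intersection`, `cluster_genotype_profiles`, `category_comparison` |
| synthetic | `synthetic_config`, `generate_genome`, `generate_expression`, `generate_genotypes`, `write_synthetic` |
| pipeline | `run_experiment` |

The methods vignette (`vignettes/epmotif-methods.Rmd`) documents the
model, the attribution rule, all tunable parameters and the design
decisions in detail.
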