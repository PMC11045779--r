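---
title: "Predicting gene expression class from flanking DNA and mining expression-predictive motifs"
author: "epmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene expression class from flanking DNA and mining expression-predictive motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epmotif` treats the level of gene expression as a property that is partly
encoded in the proximal *cis*-regulatory sequence of a gene. Genes are
classified by their expression into three groups using the lower and upper
quartiles of the per-gene `logMaxTPM` distribution (`log10(max TPM across
samples + 1)`): genes strictly below the lower quartile are *low*, strictly
above the upper quartile *high*, everything else *medium*. A binary
classifier is then trained to separate low (label 0) from high (label 1)
genes; medium genes are held out entirely. Ties at a threshold fall into
*medium*, so the binary sets are defined by strict inequalities.

The input to the classifier is a fixed-width window around each gene,
anchored at the annotated gene start and end: 1000 nt of promoter plus
500 nt of 5'UTR upstream, and 500 nt of 3'UTR plus 1000 nt of terminator
downstream. Genes on the minus strand are reverse complemented so that all
inputs read 5'→3' along the gene. The two 1.5 kb halves are fused with a
20 nt spacer of `N`s into a 3020 nt sequence, one-hot encoded over the
channels A, C, G, T; `N` and the spacer give all-zero rows. Windows that
run over a chromosome end are padded with `N` rather than dropped, which
keeps the gene universe identical across cross-validation folds.

The classifier is a 1D convolutional network: three convolutional blocks,
each with two convolutional layers (rectified-linear activations) followed
by max pooling and dropout; then two fully connected layers interspaced
with dropout, and a single sigmoid output unit giving the probability of
the *high* class. Training minimises binary cross-entropy with the Adam
optimiser (learning rate 0.001), runs at most 100 epochs, stops early
after 10 epochs without validation-loss improvement, halves the learning
rate after 5 stagnant epochs (not below 1e-5), and restores the
parameters of the epoch with the lowest validation loss. All dropout
layers use rate 0.25. A predicted probability at or below 0.5 is read as
low expression.

### Free hyperparameters and their defaults

The block structure, dropout rate, optimiser, learning-rate schedule and
stopping rules above are fixed design constants of the method. The
remaining hyperparameters are free, and their defaults are sized for
training on a single CPU:

* `filters_per_block = c(16, 16, 16)`, `kernel_size = 8` — enough width to
  discover short motifs while keeping one fold's training in minutes.
* `pool_size = 4` per block — the fused input is reduced 3020 → 755 → 188
  → 47 positions, so the fully connected block still sees position-resolved
  features at ~64 nt granularity. Wide pooling (or global pooling) proved
  markedly harder to optimise at these data sizes: max-pooling over very
  long windows collapses a single localised motif into a statistic
  dominated by background maxima, and the network then tends toward the
  constant prediction. `pool_size` accepts a vector (one entry per block;
  `0` requests a global pool) for experimentation.
* `fc_sizes = c(64, 32)`, `batch_size = 2` — small batches maximise
  optimiser steps per epoch, which matters because the early-stopping
  patience counts epochs.

### Initialisation

Weights are He-uniform. Convolutions after the first start as a noisy
identity: the centre tap passes channel *c* to channel *c* (modulo the
output width) with weight 1, plus down-scaled He noise. At initialisation
the network therefore behaves like a single motif-scanning layer followed
by the pooling cascade, and the deeper layers depart from identity only as
the data pulls them. Thin, deep rectifier stacks initialised fully at
random are poorly conditioned at the data sizes this package targets: in
our experiments they frequently collapsed onto a constant prediction
(dropout accelerates this failure mode) before any motif feature was
found. The identity-preserving start keeps the input–output path
informative from the first epoch. Because early stopping counts epochs, a
run that has not escaped the chance-level plateau within the patience
window ends prematurely; when that happens (best validation loss still at
the chance level) training restarts from a re-seeded initialisation, up
to `n_restarts` attempts, and the first converged attempt is kept. When
no attempt converges the first one is returned: picking the luckiest
validation loss among non-converged runs would bias a no-signal control
(the shuffled-sequence scheme) away from chance.
Training is exactly reproducible given the configuration seed: weight
initialisation, restarts, minibatch order and dropout masks all derive
from it.

## Cross-validation and homology hygiene

Models are validated by leave-one-chromosome-out cross-validation (one
fold per chromosome; `MSR` folds hold out a whole species instead).
Validation genes with a homolog in the training chromosomes are dropped
under the `SSR` and `MSR` schemes; two genes count as homologous when a
protein-level hit links them with e-value < 0.001 and bit score > 50
(both strict). The `SSRU` scheme keeps homologous validation genes, and
`SSC` is the shuffled-sequence control: the same folds, but every input
sequence is replaced by a per-sequence mononucleotide permutation that
preserves composition (and leaves all `N` positions, including the fused
spacer, in place); a dinucleotide-preserving shuffle is available as an
option. Only training sets are class-balanced (majority class
down-sampled without replacement, seeded); validation sets stay
unbalanced, and accuracy, auROC and F1 are all reported so that imbalance
stays visible.

## Attribution

Per-nucleotide contribution scores are computed by backpropagating the
model output to the input with the rescale rule relative to a reference
input. For every elementwise nonlinearity the multiplier is the ratio of
the output difference to the input difference between the actual and the
reference forward pass; linear layers propagate multipliers through their
weights. Max-pooling windows are decomposed into chains of pairwise
maxima, `max(a, b) = a + relu(b - a)`, each propagated with the rescale
rule — with this decomposition the contributions satisfy
summation-to-delta exactly (up to float rounding): the per-position scores
sum to `f(input) - mean f(reference)`.

The default reference averages contributions over 10 per-sequence
mononucleotide shuffles (seeded; `N` positions stay in place, so the
spacer contributes nothing); an all-zeros reference is available. From the
input multipliers the package derives *hypothetical* scores
(`hyp[l, b] = mult[l, b] - sum_c mult[l, c] ref[l, c]`, the what-if
contribution of base *b* at position *l*) and *actual* scores, which are
the hypothetical scores masked by the observed one-hot input. Averaging
the per-position actual scores across sequences gives the saliency
profile used to locate the predictive regions of the input.

## Motif discovery

Seqlets are fixed-width windows (default 21 nt) whose absolute
contribution sum exceeds the `1 - fdr_level` quantile (default 0.05) of a
per-track null built from `null_reps = 20` positionwise permutations of
the track. Overlapping windows are resolved greedily by descending
absolute sum; windows never cross the spacer, and each seqlet is anchored
by its centre — TSS-relative in the upstream half (negative offsets lie
in the promoter), TTS-relative downstream. Seqlets split by the sign of
their score into metacluster `p0` (positive, high-expression-associated)
and `p1` (negative); zero scores are discarded.

Within a metacluster, seqlets are clustered greedily in order of
descending absolute score: a seqlet joins the first cluster whose seed it
matches with cosine cross-correlation ≥ 0.7, maximised over alignment
offsets (minimum 11 of 21 columns overlapping) and both orientations;
otherwise it founds a new cluster. At most 2000 seqlets per metacluster
are clustered (the strongest), and clusters below 10 members are
discarded. Aligned hypothetical-score patches average into the
contribution weight matrix (CWM); the aligned seqlet sequences give the
base-frequency PWM. Both matrices are then trimmed to the motif's
information-content core (the maximal run of columns with ≥ 0.25 bits, at
least 4 columns), since the flanks of the fixed seqlet window are
background-like and would dilute scanning and database comparison. Each motif gets an IUPAC consensus (per position, the
code covering all bases with frequency ≥ 0.25), an information content
(`sum over positions of 2 + sum_b p log2 p` bits), a preferred positional
range per half — the interquartile interval of its seqlet offsets,
reported only when more than a tenth of the motif's seqlets fall in that
half — and a nomenclature name of the form `epmArth-S019-p0m06` (species
code, model type S/M, condition digit, optional two-digit run index,
metacluster, motif number, `R` suffix for the reverse complement, which
is emitted alongside every motif).

## Scanning, enrichment and comparison

Sequences are scanned with the log2-odds score of the PWM (pseudocount
0.01) against a 0-order background (by default estimated from the scanned
sequences). P-values are exact: a dynamic programme over the discretised
score lattice (bin width 1e-4) yields the null distribution of scores
under the background model. The sensitivity threshold (default 1e-4)
applies to the exact per-window p-value; the e-value — p-value times the
total scanned search space (positions × strands, summed over sequences)
— is reported for every match. The threshold is deliberately per window:
over a genome-scale search space no short motif could ever reach a
space-wide e-value of 1e-4 (an exact 8-mer already has p ≈ 1.5e-5), so a
space-wide cut-off would silently discard every true occurrence. Matches
are reported on both strands; windows containing `N` are skipped. A match is *in range* when its anchor offset falls inside
the motif's preferred range for that half (closed interval).

Motif–class enrichment is the log2 fold change in the odds of an in-range
match being present in genes of the motif's own class (high for `p0`, low
for `p1`) versus the opposite class; a continuity correction of 0.5 is
added to the counts by default (`eps = 0` recovers the plain odds ratio,
which is exactly antisymmetric under swapping the classes). Occurrence
counts are additionally tested against an equal split between the classes
with a 1-df chi-square goodness-of-fit test. Comparison against reference
motif databases (JASPAR-style PFM text) reports the best Pearson
correlation over alignment offsets (≥ 4 overlapping columns) and both
orientations, with a column-shuffling null (1000 shuffles) for p-values
and e-values across the database; e < 0.05 flags a significant hit.
Motifs from different models or species are clustered by local alignment
of their consensus strings (IUPAC-aware match score: Jaccard index of the
base sets rescaled to [-1, 1]; the reverse complement is also searched)
followed by average-linkage hierarchical clustering cut at height 0.5.

## Genotype comparison

A trained model applied to the flanks of the same genes in multiple
genotypes yields a probability matrix; the population variance (divide by
*n*) across genotypes calls a gene *differential* when it exceeds 0.005,
*homogeneous* otherwise. Scanning each genotype's flanks classifies an
EPM for a gene as *conserved* (in-range match in every genotype) or
*mutated* (present in the reference genotype, absent from at least one
other); motifs absent from the reference are a third state, *absent*,
excluded from the two-way statistics. Group percentages are summarised by
bootstrap: 1000 seeded draws of pools of 100 genes with replacement. A
two-sided Fisher exact test measures the intersection of gene sets;
genotype expression profiles are clustered with Euclidean distance and
average linkage and exported as newick trees. The category-level
comparison between two species maps per-gene values in [0, 1] (observed
binary label, or predicted probability) through ortholog pairs and
reports the difference of category means — bounded in [-1, 1], with -1
meaning expression in species A only — together with a two-sided Wilcoxon
rank-sum test on the predicted values, Benjamini–Hochberg-corrected
across categories.

## What the synthetic data emulates

The generator builds multi-chromosome genomes (default 4 × 500 genes,
2 kb genes, 4 kb intergenic, GC 0.4 i.i.d. background) with an exact
25/50/25 low/medium/high class design. One 8-nt motif (`CACGTGAC`) is
inserted in high-class genes and one (`GATAAGGC`) in low-class genes,
each with probability 0.9 at a uniform TSS offset of 20–200 nt (inside
the 5'UTR); the truth tables record every instance. Five percent of genes
are duplicated — body and 1.5 kb flanks copied onto a slot of another
chromosome — and reported as homology hits (e-value 1e-30, bit score
200), giving the fold-hygiene machinery real work. Expression values are
drawn from separated per-class bands of logMaxTPM (low 0–0.3, medium
0.8–1.7, high 2.2–3.5) with three replicate samples under multiplicative
log-normal noise, so quartile labelling recovers the designed classes for
≳ 95% of genes. Fifteen genotypes are derived from the reference: a third
of the accessions share a 10-nt deletion that starts at the second base
of the planted high-class motif in half of the motif-carrying genes. The
edited upstream window is re-extracted with extra margin so the
gene-start anchor stays at input position 1000, exactly as re-extraction
from an edited genome would behave.

What passing on these fixtures does *not* show: real flanking sequence is
not i.i.d. (isochores, repeats, TEs), real regulatory grammar involves
many interacting motifs with softer penetrance, homology is a continuum
rather than exact duplication, and real TPM noise is not log-normal with
a designed gap. Synthetic results validate the machinery — extraction
arithmetic, fold hygiene, training, attribution completeness, motif
recovery, conservation calls — not biological performance.

## Numerical choices and degenerate inputs

* Quantiles everywhere are the linear-interpolation (type 7) definition.
* Score-lattice p-values are exact up to the 1e-4 discretisation; tests
  against exhaustive enumeration agree to 1e-9 for widths ≤ 6.
* Rescale multipliers fall back to the local derivative when the
  input–reference difference at a unit is below 1e-10.
* Max-pool ties take the first maximising position.
* Genes shorter than `utr5_len + utr3_len` have overlapping windows; they
  are extracted anyway and flagged `overlapping`.
* Chromosomes with no binary-labelled genes produce a skipped fold with a
  warning; a single-class training fold is skipped likewise.
* The equal-split chi-square test errors on zero total occurrences, and
  enrichment errors on an empty class.
* All randomness flows from explicit integer seeds; independent streams
  are derived per purpose (initialisation, batching, shuffles, nulls,
  bootstraps), so results are reproducible end to end.

## Problem sizes used in the shipped analyses

The shipped tests and the acceptance analysis train on the default
synthetic genome (4 chromosomes × 500 genes, ≈ 1000 binary-labelled
genes, ≈ 760 balanced training sequences per fold) with the default model
above; one fold trains in a few minutes on one CPU. Attribution uses 10
shuffled references per gene across the pooled validation sets; motif
discovery caps at 2000 seqlets per metacluster. These sizes were chosen
as the smallest at which every stage (fold hygiene, training, recovery of
both planted motifs, conservation analysis) exercises realistically.

## Known limitations

* The classifier is proximal-sequence-only: distal enhancers, chromatin
  state and tissue-specific regulation are invisible to it.
* Training on very small folds (tens of genes) is unstable; the defaults
  assume hundreds of training genes per fold.
* The seqlet aggregation is a greedy one-pass clustering, not an
  iterative refinement; motif boundaries are fixed at the window length.
* The exact-p-value scanner assumes a 0-order background.
* `MSR` homology filtering defaults to within-species hit tables; supply
  cross-species hits explicitly if leakage across species is a concern.
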