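#' Synthetic genome configuration
#'
#' Defines toy multi-chromosome genomes in which planted motifs causally
#' determine the expression class, providing ground truth for every
#' pipeline stage. Defaults: four chromosomes of 500 genes; one 8-nt
#' high-class motif inserted with probability 0.9 at TSS offsets 20-200 nt
#' (within the 5'UTR) and one low-class motif with the same geometry; 5%
#' of genes duplicated onto another chromosome (recorded as homology
#' hits); 15 genotypes of which a third carry a 10-nt indel deleting the
#' high-class motif instance in half of the motif-carrying genes.
#'
#' @param n_chroms,genes_per_chrom,gene_len,intergenic_len genome geometry
#'   (nt / counts).
#' @param motif_specs list of motif specifications: `pattern` (DNA string),
#'   `class_assoc` (`"high"`/`"low"`), `anchor` (`"TSS"`/`"TTS"`),
#'   `offset_range` (`c(lo, hi)` nt), `insertion_prob`.
#' @param background_gc GC content of the i.i.d. background.
#' @param duplicate_fraction fraction of genes copied (with their flanks)
#'   to another chromosome and listed as homologs.
#' @param n_genotypes number of genotypes (the first is the reference).
#' @param edit_spec list: `indel_len`, `target_motif` (index into
#'   `motif_specs`), `fraction_of_genotypes` carrying the edits,
#'   `gene_fraction` of motif-carrying genes edited.
#' @param seed single global seed; all sub-generators derive streams from
#'   it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 4L, genes_per_chrom = 500L,
                             gene_len = 2000L, intergenic_len = 4000L,
                             motif_specs = list(
                               list(pattern = "CACGTGAC", class_assoc = "high",
                                    anchor = "TSS", offset_range = c(20L, 200L),
                                    insertion_prob = 0.9),
                               list(pattern = "GATAAGGC", class_assoc = "low",
                                    anchor = "TSS", offset_range = c(20L, 200L),
                                    insertion_prob = 0.9)),
                             background_gc = 0.4,
                             duplicate_fraction = 0.05,
                             n_genotypes = 15L,
                             edit_spec = list(indel_len = 10L,
                                              target_motif = 1L,
                                              fraction_of_genotypes = 1 / 3,
                                              gene_fraction = 0.5),
                             seed = 7L) {
  for (m in motif_specs) {
    if (grepl("[^ACGT]", m$pattern)) stop("motif patterns must be over ACGT")
    if (m$insertion_prob < 0 || m$insertion_prob > 1)
      stop("insertion_prob must be in [0, 1]")
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 genes_per_chrom = as.integer(genes_per_chrom),
                 gene_len = as.integer(gene_len),
                 intergenic_len = as.integer(intergenic_len),
                 motif_specs = motif_specs, background_gc = background_gc,
                 duplicate_fraction = duplicate_fraction,
                 n_genotypes = as.integer(n_genotypes),
                 edit_spec = edit_spec, seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

## place `pattern` at oriented anchor offset within a gene; returns the
## genome coordinates [from, to] and the strand-adjusted pattern
.motif_coords <- function(start, end, strand, anchor, offset, len) {
  if (strand == "+") {
    from <- if (anchor == "TSS") start + offset else end + 1L + offset
    list(from = from, to = from + len - 1L)
  } else {
    to <- if (anchor == "TSS") end - offset else start - 1L - offset
    list(from = to - len + 1L, to = to)
  }
}

#' Generate a synthetic genome with planted motifs
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genome` (named character vector), `annotation`
#'   (data.frame as from [read_annotation()]), `classes` (gene_id,
#'   class, duplicate_of), `motifs` (truth table: gene_id, motif_id,
#'   pattern, anchor, offset, from, to), `homology` (12-column hit table
#'   for the duplicated genes) and `cfg`.
#' @export
generate_genome <- function(cfg = synthetic_config()) {
  with_seed(derive_seed(cfg$seed, "genome"), {
    slot <- cfg$gene_len + cfg$intergenic_len
    chrom_len <- cfg$intergenic_len + cfg$genes_per_chrom * slot
    genome <- character(cfg$n_chroms)
    names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
    ann <- list()
    for (c in seq_len(cfg$n_chroms)) {
      genome[c] <- .random_dna(chrom_len, cfg$background_gc)
      i <- seq_len(cfg$genes_per_chrom)
      start <- cfg$intergenic_len + (i - 1L) * slot + 1L
      ann[[c]] <- data.frame(
        gene_id = sprintf("gene_c%d_%04d", c, i),
        chrom = names(genome)[c],
        start = start, end = start + cfg$gene_len - 1L,
        strand = sample(c("+", "-"), cfg$genes_per_chrom, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    annotation <- do.call(rbind, ann)
    n <- nrow(annotation)

    ## designed classes: exact 25 / 50 / 25 split
    klass <- sample(rep(c("low", "medium", "medium", "high"),
                        length.out = n))
    classes <- data.frame(gene_id = annotation$gene_id, class = klass,
                          duplicate_of = NA_character_,
                          stringsAsFactors = FALSE)

    ## plant motifs
    motif_rows <- list()
    for (g in seq_len(n)) {
      a <- annotation[g, ]
      for (mi in seq_along(cfg$motif_specs)) {
        sp <- cfg$motif_specs[[mi]]
        if (sp$class_assoc != klass[g]) next
        if (runif(1) > sp$insertion_prob) next
        offset <- sample(sp$offset_range[1]:sp$offset_range[2], 1L)
        len <- nchar(sp$pattern)
        co <- .motif_coords(a$start, a$end, a$strand, sp$anchor, offset, len)
        pat <- if (a$strand == "+") sp$pattern else revcomp(sp$pattern)
        substr(genome[a$chrom], co$from, co$to) <- pat
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          gene_id = a$gene_id, motif_id = mi, pattern = sp$pattern,
          anchor = sp$anchor, offset = offset, from = co$from, to = co$to,
          stringsAsFactors = FALSE)
      }
    }
    motifs <- do.call(rbind, motif_rows)

    ## duplications: copy gene body plus 1.5 kb flanks onto a slot of a
    ## different chromosome; the target inherits class, strand and motifs
    n_dup <- round(cfg$duplicate_fraction * n)
    homology <- NULL
    if (n_dup > 0L) {
      margin <- 1500L
      src <- sample(n, n_dup)
      candidates <- setdiff(seq_len(n), src)
      tgt <- rep(NA_integer_, n_dup)
      for (j in seq_len(n_dup)) {
        ## the overwritten slot keeps the source's designed class so the
        ## 25/50/25 class design stays exact
        ok <- candidates[annotation$chrom[candidates] !=
                           annotation$chrom[src[j]] &
                           klass[candidates] == klass[src[j]]]
        tgt[j] <- sample(ok, 1L)
        candidates <- setdiff(candidates, tgt[j])
      }
      for (j in seq_len(n_dup)) {
        s <- annotation[src[j], ]; t <- annotation[tgt[j], ]
        block <- substr(genome[s$chrom], s$start - margin, s$end + margin)
        substr(genome[t$chrom], t$start - margin, t$end + margin) <- block
        annotation$strand[tgt[j]] <- s$strand
        classes$class[tgt[j]] <- classes$class[src[j]]
        classes$duplicate_of[tgt[j]] <- s$gene_id
        motifs <- motifs[motifs$gene_id != t$gene_id, , drop = FALSE]
        mrows <- motifs[motifs$gene_id == s$gene_id, , drop = FALSE]
        if (nrow(mrows)) {
          mrows$gene_id <- t$gene_id
          shift <- t$start - s$start
          mrows$from <- mrows$from + shift
          mrows$to <- mrows$to + shift
          motifs <- rbind(motifs, mrows)
        }
      }
      homology <- data.frame(
        V1 = annotation$gene_id[src], V2 = annotation$gene_id[tgt],
        V3 = 100.0, V4 = cfg$gene_len, V5 = 0L, V6 = 0L, V7 = 1L,
        V8 = cfg$gene_len, V9 = 1L, V10 = cfg$gene_len, V11 = 1e-30,
        V12 = 200.0, stringsAsFactors = FALSE)
    }
    rownames(motifs) <- NULL
    list(genome = genome, annotation = annotation, classes = classes,
         motifs = motifs, homology = homology, cfg = cfg)
  })
}

#' Generate a TPM table matching the designed classes
#'
#' Per-class logMaxTPM targets are drawn from separated uniform bands
#' (low 0-0.3, medium 0.8-1.7, high 2.2-3.5) and converted to TPM with
#' three replicate sample columns under multiplicative log-normal noise,
#' so that quartile labelling recovers the designed classes for virtually
#' all genes.
#'
#' @param synth output of [generate_genome()].
#' @param n_samples number of replicate sample columns (default 3).
#' @param noise_sd standard deviation of the log-normal sample noise.
#' @return numeric matrix (genes x samples) with gene ids as row names.
#' @export
generate_expression <- function(synth, n_samples = 3L, noise_sd = 0.2) {
  cfg <- synth$cfg
  with_seed(derive_seed(cfg$seed, "expression"), {
    kl <- synth$classes$class
    n <- length(kl)
    v <- numeric(n)
    v[kl == "low"] <- runif(sum(kl == "low"), 0, 0.3)
    v[kl == "medium"] <- runif(sum(kl == "medium"), 0.8, 1.7)
    v[kl == "high"] <- runif(sum(kl == "high"), 2.2, 3.5)
    base <- 10^v - 1
    tpm <- vapply(seq_len(n_samples), function(s)
      base * exp(rnorm(n, 0, noise_sd)), numeric(n))
    rownames(tpm) <- synth$classes$gene_id
    colnames(tpm) <- paste0("sample", seq_len(n_samples))
    tpm
  })
}

#' Generate per-genotype flanking sequences with motif-disrupting indels
#'
#' The reference genotype carries the unedited flanks. A seeded subset of
#' the other genotypes shares a set of edits: in a seeded subset of the
#' genes carrying the target motif, an `indel_len`-nt deletion starting at
#' the second base of the planted instance removes the motif. The edited
#' upstream window is re-extracted with extra margin so the gene-start
#' anchor stays at its input position, exactly as re-extraction from an
#' edited genome would behave.
#'
#' @param synth output of [generate_genome()].
#' @param region a [region_config()].
#' @param gene_ids genes to include (default: all).
#' @return list with `flanks` (named list genotype -> named character
#'   vector of fused flanks), `ledger` (data.frame: genotype, gene_id,
#'   flank_pos (0-based deletion start in the fused input), tss_offset,
#'   indel_len), `edited_genotypes`, `edited_genes`, `reference`
#'   (genotype name).
#' @export
generate_genotypes <- function(synth, region = region_config(),
                               gene_ids = NULL) {
  cfg <- synth$cfg
  es <- cfg$edit_spec
  ann <- synth$annotation
  if (!is.null(gene_ids)) ann <- ann[ann$gene_id %in% gene_ids, ]
  ref_flanks <- extract_all_flanks(ann, synth$genome, region)
  fused_ref <- setNames(ref_flanks$fused, ref_flanks$gene_id)
  genotype_names <- c("ref", sprintf("acc%02d", seq_len(cfg$n_genotypes - 1L) + 1L))

  with_seed(derive_seed(cfg$seed, "genotypes"), {
    n_edit_gt <- round(es$fraction_of_genotypes * (cfg$n_genotypes - 1L))
    edited_gt <- sort(sample(genotype_names[-1L], n_edit_gt))
    carriers <- synth$motifs$gene_id[synth$motifs$motif_id == es$target_motif]
    carriers <- intersect(carriers, ann$gene_id)
    edited_genes <- sort(sample(carriers,
                                round(es$gene_fraction * length(carriers))))

    ## edited upstream windows, re-extracted with margin
    edited_up <- character(0)
    ledger <- list()
    target_rows <- synth$motifs[synth$motifs$motif_id == es$target_motif, ]
    tss_off <- setNames(target_rows$offset, target_rows$gene_id)
    for (g in edited_genes) {
      a <- ann[ann$gene_id == g, ]
      off <- tss_off[[g]]
      chrom <- synth$genome[[a$chrom]]
      ext <- es$indel_len
      up_ext <- if (a$strand == "+") {
        .window(chrom, a$start - region$promoter_len,
                a$start + region$utr5_len + ext - 1L)
      } else {
        revcomp(.window(chrom, a$end - region$utr5_len - ext + 1L,
                        a$end + region$promoter_len))
      }
      ## delete indel_len nt starting at the second motif base
      del_start <- region$promoter_len + off + 2L   # 1-based in up_ext
      up_edit <- paste0(substr(up_ext, 1L, del_start - 1L),
                        substr(up_ext, del_start + es$indel_len,
                               nchar(up_ext)))
      up_edit <- substr(up_edit, 1L, region$upstream_len)
      dn <- ref_flanks$downstream[ref_flanks$gene_id == g]
      edited_up[g] <- paste0(up_edit, strrep("N", region$spacer_len), dn)
      ledger[[length(ledger) + 1L]] <- data.frame(
        gene_id = g, flank_pos = del_start - 1L, tss_offset = off + 1L,
        indel_len = es$indel_len, stringsAsFactors = FALSE)
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(gene_id = character(), flank_pos = integer(),
                 tss_offset = integer(), indel_len = integer())

    flanks <- lapply(genotype_names, function(gt) {
      f <- fused_ref
      if (gt %in% edited_gt && length(edited_genes))
        f[edited_genes] <- edited_up[edited_genes]
      f
    })
    names(flanks) <- genotype_names
    full_ledger <- do.call(rbind, lapply(edited_gt, function(gt)
      cbind(genotype = gt, ledger, stringsAsFactors = FALSE)))
    list(flanks = flanks, ledger = full_ledger,
         edited_genotypes = edited_gt, edited_genes = edited_genes,
         reference = "ref")
  })
}

#' Write a synthetic genome to FASTA + GFF3 + TSV files
#'
#' @param synth output of [generate_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  dss <- Biostrings::DNAStringSet(synth$genome)
  Biostrings::writeXStringSet(dss, fa)
  gff <- file.path(dir, "genes.gff3")
  a <- synth$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = a$chrom,
    ranges = IRanges::IRanges(start = a$start, end = a$end),
    strand = a$strand, type = "gene", ID = a$gene_id)
  rtracklayer::export(gr, gff, format = "gff3")
  hom <- file.path(dir, "homology.tsv")
  if (!is.null(synth$homology))
    write.table(synth$homology, hom, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  truth <- file.path(dir, "truth_motifs.tsv")
  write.table(synth$motifs, truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cls <- file.path(dir, "truth_classes.tsv")
  write.table(synth$classes, cls, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(fasta = fa, gff3 = gff, homology = hom, motifs = truth, classes = cls)
}
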