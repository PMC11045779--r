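#' Region extraction configuration
#'
#' Lengths (in nucleotides) of the four flanking segments extracted around
#' each gene, plus the neutral spacer inserted between the upstream and
#' downstream halves. The defaults give the canonical 1 kb promoter + 500 nt
#' 5'UTR upstream block and 500 nt 3'UTR + 1 kb terminator downstream block,
#' fused with a 20 nt run of `N`s into a 3020 nt model input.
#'
#' @param promoter_len,utr5_len,utr3_len,terminator_len,spacer_len segment
#'   lengths in nt, all `>= 0`.
#' @return an object of class `region_config`.
#' @export
region_config <- function(promoter_len = 1000L, utr5_len = 500L,
                          utr3_len = 500L, terminator_len = 1000L,
                          spacer_len = 20L) {
  lens <- c(promoter_len, utr5_len, utr3_len, terminator_len, spacer_len)
  if (any(lens < 0)) stop("all region lengths must be >= 0")
  cfg <- list(promoter_len = as.integer(promoter_len),
              utr5_len = as.integer(utr5_len),
              utr3_len = as.integer(utr3_len),
              terminator_len = as.integer(terminator_len),
              spacer_len = as.integer(spacer_len))
  cfg$upstream_len <- cfg$promoter_len + cfg$utr5_len
  cfg$downstream_len <- cfg$utr3_len + cfg$terminator_len
  cfg$total_input_len <- cfg$upstream_len + cfg$spacer_len + cfg$downstream_len
  ## 0-based positions of the two anchors within the fused input:
  ## tss_pos is the first transcribed base, tts_pos the first terminator base
  cfg$tss_pos <- cfg$promoter_len
  cfg$tts_pos <- cfg$upstream_len + cfg$spacer_len + cfg$utr3_len
  class(cfg) <- "region_config"
  cfg
}

#' Read a genome FASTA file
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than `N` are mapped
#' to `N` with a warning.
#'
#' @param fasta_path path to a (multi-)FASTA file.
#' @return named character vector, one uppercase DNA string per chromosome.
#' @export
read_genome <- function(fasta_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) == 0L) stop("empty FASTA file: ", fasta_path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in ", fasta_path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- nm
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    warning("ambiguity codes in ", sum(amb),
            " sequence(s) mapped to N")
    seqs[amb] <- gsub("[^ACGTN]", "N", seqs[amb])
  }
  seqs
}

#' Read gene annotations from a GFF3 file
#'
#' Only rows of type `gene` are used as extraction anchors; transcripts,
#' exons and other features are ignored. Coordinates stay 1-based inclusive.
#'
#' @param gff3_path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_annotation <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0L) stop("no gene records in ", gff3_path)
  ids <- df$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("gene record without ID attribute in ", gff3_path)
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-")))
    stop("gene with missing strand ('.' or '*'); strand is required")
  data.frame(gene_id = as.character(ids),
             chrom = as.character(df$seqnames),
             start = df$start,
             end = df$end,
             strand = strand,
             stringsAsFactors = FALSE)
}

## slice [from, to] (1-based, may exceed bounds) out of a chromosome,
## padding out-of-range positions with N
.window <- function(chrom_seq, from, to) {
  n <- nchar(chrom_seq)
  lo <- max(1L, from)
  hi <- min(n, to)
  core <- if (lo > hi) "" else substr(chrom_seq, lo, hi)
  paste0(strrep("N", max(0L, lo - from)), core, strrep("N", max(0L, to - hi)))
}

#' Extract oriented flanking sequence for one gene
#'
#' Anchored at the annotated gene start and end. For `-` strand genes the
#' mirrored windows are taken and reverse complemented, so the result is
#' always in gene 5'->3' orientation. Windows running past chromosome ends
#' are padded with `N`.
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `start`, `end`,
#'   `strand`.
#' @param chrom_seq chromosome sequence containing the gene.
#' @param cfg a [region_config()].
#' @return list with `gene_id`, `upstream`, `downstream`, `fused` and
#'   `overlapping` (TRUE when the gene is shorter than `utr5_len + utr3_len`
#'   so the two windows overlap).
#' @export
extract_flanks <- function(gene, chrom_seq, cfg = region_config()) {
  s <- as.integer(gene$start); e <- as.integer(gene$end)
  if (gene$strand == "+") {
    up <- .window(chrom_seq, s - cfg$promoter_len, s + cfg$utr5_len - 1L)
    dn <- .window(chrom_seq, e - cfg$utr3_len + 1L, e + cfg$terminator_len)
  } else {
    up <- revcomp(.window(chrom_seq, e - cfg$utr5_len + 1L, e + cfg$promoter_len))
    dn <- revcomp(.window(chrom_seq, s - cfg$terminator_len, s + cfg$utr3_len - 1L))
  }
  list(gene_id = gene$gene_id,
       upstream = up,
       downstream = dn,
       fused = paste0(up, strrep("N", cfg$spacer_len), dn),
       overlapping = (e - s + 1L) < (cfg$utr5_len + cfg$utr3_len))
}

#' Extract flanking sequences for all genes of a genome
#'
#' @param annotation data.frame from [read_annotation()].
#' @param genome named character vector from [read_genome()].
#' @param cfg a [region_config()].
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `upstream`, `downstream`, `fused`, `overlapping`.
#' @export
extract_all_flanks <- function(annotation, genome, cfg = region_config()) {
  miss <- setdiff(unique(annotation$chrom), names(genome))
  if (length(miss)) stop("chromosomes missing from genome: ",
                         paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    extract_flanks(g, genome[[g$chrom]], cfg)
  })
  data.frame(gene_id = vapply(res, `[[`, "", "gene_id"),
             chrom = annotation$chrom,
             strand = annotation$strand,
             upstream = vapply(res, `[[`, "", "upstream"),
             downstream = vapply(res, `[[`, "", "downstream"),
             fused = vapply(res, `[[`, "", "fused"),
             overlapping = vapply(res, `[[`, NA, "overlapping"),
             stringsAsFactors = FALSE)
}

#' One-hot encode a DNA sequence
#'
#' Channel order A, C, G, T. `N` (including the fused spacer) yields an
#' all-zero row, so every row sums to 0 or 1 and decoding recovers the
#' sequence with `N` at zero rows.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return numeric matrix of dimension `nchar(seq) x 4`.
#' @export
encode_seq <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(ch), c(BASES, "N"))
  if (length(bad)) stop("unexpected character(s) in sequence: ",
                        paste(bad, collapse = ","))
  m <- matrix(0, nrow = length(ch), ncol = 4L,
              dimnames = list(NULL, BASES))
  hit <- match(ch, BASES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' @param mat `L x 4` one-hot matrix as produced by [encode_seq()].
#' @return DNA string with `N` at all-zero rows.
#' @export
decode_onehot <- function(mat) {
  idx <- onehot_to_index(mat)
  out <- BASES[idx]
  out[is.na(idx)] <- "N"
  paste(out, collapse = "")
}

#' Write extracted flanks to a FASTA file
#'
#' One record per gene; the description carries the segment boundaries.
#'
#' @param flanks data.frame from [extract_all_flanks()].
#' @param path output file path.
#' @param cfg the [region_config()] used for extraction.
#' @export
write_flanks_fasta <- function(flanks, path, cfg = region_config()) {
  dss <- Biostrings::DNAStringSet(flanks$fused)
  names(dss) <- sprintf("%s promoter=%d utr5=%d spacer=%d utr3=%d terminator=%d",
                        flanks$gene_id, cfg$promoter_len, cfg$utr5_len,
                        cfg$spacer_len, cfg$utr3_len, cfg$terminator_len)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Map a 0-based fused-input position to its anchor-relative offset
#'
#' Positions in the upstream half are reported relative to the TSS (negative
#' values lie in the promoter); positions in the downstream half relative to
#' the TTS (negative values lie in the 3'UTR). Spacer positions return `NA`.
#'
#' @param pos integer vector of 0-based positions in the fused input.
#' @param cfg a [region_config()].
#' @return data.frame with columns `half` (`"upstream"`/`"downstream"`/`NA`)
#'   and `offset`.
#' @export
anchor_offset <- function(pos, cfg = region_config()) {
  half <- ifelse(pos < cfg$upstream_len, "upstream",
                 ifelse(pos >= cfg$upstream_len + cfg$spacer_len,
                        "downstream", NA))
  offset <- ifelse(half == "upstream", pos - cfg$tss_pos,
                   ifelse(half == "downstream", pos - cfg$tts_pos, NA))
  data.frame(half = half, offset = offset, stringsAsFactors = FALSE)
}
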