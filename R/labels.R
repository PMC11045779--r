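#' Aggregate transcript-isoform TPM to gene-level TPM
#'
#' Gene TPM is the sum of its isoform TPMs in every sample.
#'
#' @param tx_tpm numeric matrix (transcripts x samples) with transcript ids
#'   as row names.
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`.
#' @return numeric matrix (genes x samples).
#' @export
aggregate_isoforms <- function(tx_tpm, tx2gene) {
  tx_tpm <- as.matrix(tx_tpm)
  g <- tx2gene$gene_id[match(rownames(tx_tpm), tx2gene$transcript_id)]
  if (anyNA(g)) stop("transcript(s) without gene mapping: ",
                     paste(head(rownames(tx_tpm)[is.na(g)]), collapse = ","))
  rowsum(tx_tpm, group = g)
}

#' logMaxTPM of a gene
#'
#' `log10(max(TPM across samples) + 1)`. The maximum over the samples of the
#' tissue under analysis is used, with a pseudocount of 1 before the log.
#'
#' @param tpm numeric matrix (genes x samples) or a single numeric vector of
#'   per-sample TPM values for one gene.
#' @param base log base (default 10).
#' @param pseudocount added before taking the log (default 1).
#' @return numeric vector of logMaxTPM values, one per gene.
#' @export
log_max_tpm <- function(tpm, base = 10, pseudocount = 1) {
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = 1L)
  if (ncol(tpm) < 1L) stop("at least one sample is required")
  if (any(tpm < 0)) stop("negative TPM values")
  log(apply(tpm, 1L, max) + pseudocount, base = base)
}

#' Lower/upper quartile thresholds of a logMaxTPM distribution
#'
#' Empirical 25th and 75th percentiles (linear-interpolation quantile
#' definition, `stats::quantile` type 7).
#'
#' @param values numeric vector of logMaxTPM values (>= 4 genes).
#' @return list with elements `q_low`, `q_high`.
#' @export
expression_thresholds <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("need at least 4 genes to place quartiles")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  list(q_low = q[1], q_high = q[2])
}

#' Assign three-way expression classes and the binary training label
#'
#' Genes strictly below `q_low` are `low` (binary 0), strictly above
#' `q_high` are `high` (binary 1); everything else, including ties at the
#' thresholds, is `medium` and carries no binary label.
#'
#' @param values named numeric vector of logMaxTPM values (names = gene ids).
#' @param thresholds list from [expression_thresholds()].
#' @return data.frame with columns `gene_id`, `log_max_tpm`, `klass`
#'   (factor low/medium/high) and `binary` (0, 1, or NA for medium).
#' @export
assign_classes <- function(values, thresholds) {
  kl <- ifelse(values < thresholds$q_low, "low",
               ifelse(values > thresholds$q_high, "high", "medium"))
  data.frame(gene_id = if (is.null(names(values)))
               as.character(seq_along(values)) else names(values),
             log_max_tpm = unname(values),
             klass = factor(kl, levels = c("low", "medium", "high")),
             binary = unname(ifelse(kl == "low", 0L,
                                    ifelse(kl == "high", 1L, NA_integer_))),
             stringsAsFactors = FALSE)
}

#' Label genes from a TPM table
#'
#' Convenience wrapper: logMaxTPM, quartile thresholds and classes in one
#' step.
#'
#' @param tpm numeric matrix (genes x samples) with gene ids as row names.
#' @return data.frame as in [assign_classes()], plus the thresholds as
#'   attribute `"thresholds"`.
#' @export
label_expression <- function(tpm) {
  v <- log_max_tpm(tpm)
  names(v) <- rownames(tpm)
  thr <- expression_thresholds(v)
  out <- assign_classes(v, thr)
  attr(out, "thresholds") <- thr
  out
}

#' Read a TSV TPM table
#'
#' Genes/transcripts in rows (first column = id), samples in columns.
#'
#' @param path path to a tab-separated table with a header row.
#' @return numeric matrix with ids as row names.
#' @export
read_tpm_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}
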