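#' Per-nucleotide contribution scores for one input
#'
#' Backpropagates the model output to the input with the rescale rule
#' relative to a reference input, yielding, per position, a hypothetical
#' score for each of the four bases (the what-if contribution of placing
#' that base there) and an actual score that is the hypothetical score
#' masked by the observed one-hot input. Contributions satisfy
#' summation-to-delta: the actual scores sum to
#' `f(input) - mean f(reference)`.
#'
#' The default reference averages contributions over `k` per-sequence
#' mononucleotide shuffles (seeded; `N` positions, including the fused
#' spacer, stay in place). `reference = "zeros"` uses the all-zero input.
#'
#' @param model a fitted [cre_cnn()].
#' @param x one input: a DNA string or an `L x 4` one-hot matrix.
#' @param reference `"shuffled"` (default) or `"zeros"`.
#' @param k number of shuffled references to average over.
#' @param seed seed for the shuffled references.
#' @param gene_id optional identifier stored in the track.
#' @return object of class `importance_track`: list with `gene_id`,
#'   `actual` (L x 4), `hypothetical` (L x 4), `per_position` (length L,
#'   row sums of `actual`), `delta` (= f(x) - mean f(ref)) and `f_x`.
#' @export
compute_contributions <- function(model, x, reference = c("shuffled", "zeros"),
                                  k = 10L, seed = 1L, gene_id = NULL) {
  reference <- match.arg(reference)
  if (is.character(x)) {
    if (is.null(gene_id) && !is.null(names(x))) gene_id <- names(x)[1]
    seq <- toupper(x[[1]])
    X <- encode_seq(seq)
  } else {
    X <- x
    seq <- decode_onehot(X)
  }
  if (nrow(X) != model$input_len)
    stop("input length does not match the trained model")
  refs <- if (reference == "zeros") {
    list(matrix(0, nrow(X), 4L))
  } else {
    shuf <- shuffle_sequences(rep(seq, k), seed = seed)
    lapply(shuf, encode_seq)
  }
  hyp <- matrix(0, nrow(X), 4L)
  f_ref <- 0
  f_x <- NA_real_
  for (R in refs) {
    dl <- cpp_deeplift(X, R, model$arch, model$params)
    mult <- dl$mult
    ## hypothetical: contribution if base b were observed at position l,
    ## relative to the reference distribution at that position
    hyp <- hyp + (mult - rowSums(mult * R))
    f_ref <- f_ref + dl$f_ref
    f_x <- dl$f_x
  }
  hyp <- hyp / length(refs)
  f_ref <- f_ref / length(refs)
  actual <- hyp * X
  colnames(actual) <- colnames(hyp) <- BASES
  structure(list(gene_id = gene_id, actual = actual, hypothetical = hyp,
                 per_position = rowSums(actual),
                 delta = f_x - f_ref, f_x = f_x, seq = seq),
            class = "importance_track")
}

#' Contribution tracks for a batch of sequences
#'
#' @param model a fitted [cre_cnn()].
#' @param sequences named character vector of fused sequences.
#' @inheritParams compute_contributions
#' @return named list of `importance_track` objects.
#' @export
compute_contributions_batch <- function(model, sequences,
                                        reference = "shuffled", k = 10L,
                                        seed = 1L) {
  out <- lapply(seq_along(sequences), function(i)
    compute_contributions(model, sequences[i], reference = reference, k = k,
                          seed = derive_seed(seed, names(sequences)[i] %||% i),
                          gene_id = names(sequences)[i]))
  names(out) <- names(sequences)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.importance_track <- function(x, ...) {
  cat("Importance track", if (!is.null(x$gene_id)) paste0("for ", x$gene_id),
      "\n")
  cat(sprintf("  length %d nt; sum of scores %.4f; f(x) = %.4f; delta %.4f\n",
              length(x$per_position), sum(x$per_position), x$f_x, x$delta))
  invisible(x)
}

#' Summed importance score of one gene
#'
#' The sum over the flanking region of per-position contribution scores;
#' positive sums accompany predicted high expression, negative sums
#' predicted low expression.
#'
#' @param track an `importance_track`.
#' @return numeric scalar.
#' @export
sum_gene_score <- function(track) sum(track$per_position)

#' Average saliency profile over a set of tracks
#'
#' Position-wise arithmetic mean of the per-position contribution scores,
#' highlighting the most predictive regions of the input (typically the
#' sequence proximal to the TSS and TTS).
#'
#' @param tracks list of `importance_track` objects of equal length.
#' @return object of class `saliency_profile`: list with
#'   `mean_per_position` and `n_sequences`.
#' @export
average_saliency <- function(tracks) {
  lens <- vapply(tracks, function(t) length(t$per_position), 0L)
  if (length(unique(lens)) != 1L) stop("tracks differ in length")
  m <- rowMeans(vapply(tracks, `[[`, numeric(lens[1]), "per_position"))
  structure(list(mean_per_position = m, n_sequences = length(tracks)),
            class = "saliency_profile")
}

#' @export
print.saliency_profile <- function(x, ...) {
  cat(sprintf("Saliency profile over %d sequences (length %d); peak %.4g at position %d\n",
              x$n_sequences, length(x$mean_per_position),
              max(x$mean_per_position), which.max(x$mean_per_position)))
  invisible(x)
}

#' Plot a saliency profile
#'
#' @param x a `saliency_profile`.
#' @param cfg optional [region_config()]; when given, TSS/TTS anchors are
#'   marked.
#' @param ... passed to [graphics::plot()].
#' @export
plot.saliency_profile <- function(x, cfg = NULL, ...) {
  graphics::plot(seq_along(x$mean_per_position) - 1L, x$mean_per_position,
                 type = "l", xlab = "position in fused input (0-based)",
                 ylab = "mean contribution", ...)
  if (!is.null(cfg)) {
    graphics::abline(v = c(cfg$tss_pos, cfg$tts_pos), lty = 3, col = "grey50")
    graphics::mtext(c("TSS", "TTS"), at = c(cfg$tss_pos, cfg$tts_pos), side = 3,
                    cex = 0.8)
  }
  invisible(x)
}

#' Export a saliency profile as TSV
#'
#' @param profile a `saliency_profile`.
#' @param path output file.
#' @export
write_saliency_tsv <- function(profile, path) {
  write.table(data.frame(position = seq_along(profile$mean_per_position) - 1L,
                         mean_score = profile$mean_per_position),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
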