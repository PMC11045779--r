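#' Extract seqlets from importance tracks
#'
#' Slides a window over the per-position contribution scores of every track
#' and keeps windows whose absolute score sum exceeds the `1 - fdr_level`
#' quantile of a per-track null built from position-permuted tracks.
#' Overlapping calls within a track are resolved greedily by descending
#' absolute sum. The fused spacer is excluded: windows are confined to the
#' upstream and downstream halves and are anchored at the TSS (upstream,
#' negative offsets = promoter) or the TTS (downstream, negative offsets =
#' 3'UTR) via their window centre.
#'
#' @param tracks list of `importance_track` objects
#'   ([compute_contributions_batch()]).
#' @param cfg the [region_config()] the inputs were built with.
#' @param window_len seqlet window length in nt (default 21).
#' @param null_reps number of positionwise permutations per track.
#' @param fdr_level null quantile level (default 0.05).
#' @param seed seed for the permutation null.
#' @return object of class `seqlet_set`: list with `df` (gene_id, start,
#'   end, total_score, half, offset), `patches` (list of `window_len x 4`
#'   hypothetical-score matrices), `seqs` (window sequences), `window_len`,
#'   `cfg`.
#' @export
extract_seqlets <- function(tracks, cfg = region_config(), window_len = 21L,
                            null_reps = 20L, fdr_level = 0.05, seed = 1L) {
  L <- length(tracks[[1]]$per_position)
  if (window_len > L) stop("window_len exceeds track length")
  pp <- vapply(tracks, `[[`, numeric(L), "per_position")
  thr <- cpp_null_threshold(pp, window_len, as.integer(null_reps), fdr_level,
                            derive_seed(seed, "seqlet-null"))
  ## valid 0-based window starts per half (never crossing the spacer)
  up_starts <- 0:(cfg$upstream_len - window_len)
  dn_starts <- (cfg$upstream_len + cfg$spacer_len):(L - window_len)
  starts <- c(up_starts, dn_starts)

  rows <- list(); patches <- list(); seqs <- character()
  for (t in seq_along(tracks)) {
    x <- pp[, t]
    cs <- cumsum(c(0, x))
    wsum <- cs[starts + window_len + 1L] - cs[starts + 1L]
    cand <- which(abs(wsum) > thr[t])
    if (!length(cand)) next
    cand <- cand[order(-abs(wsum[cand]))]
    taken <- integer(0)
    for (ci in cand) {
      s0 <- starts[ci]
      if (any(abs(taken - s0) < window_len)) next
      taken <- c(taken, s0)
      centre <- s0 + window_len %/% 2L
      an <- anchor_offset(centre, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tracks[[t]]$gene_id %||% as.character(t),
        start = s0, end = s0 + window_len,
        total_score = wsum[ci], half = an$half, offset = an$offset,
        stringsAsFactors = FALSE)
      patches[[length(patches) + 1L]] <-
        tracks[[t]]$hypothetical[(s0 + 1L):(s0 + window_len), , drop = FALSE]
      seqs[length(seqs) + 1L] <-
        substr(tracks[[t]]$seq, s0 + 1L, s0 + window_len)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               total_score = numeric(), half = character(),
               offset = numeric(), stringsAsFactors = FALSE)
  structure(list(df = df, patches = patches, seqs = seqs,
                 window_len = as.integer(window_len), cfg = cfg),
            class = "seqlet_set")
}

#' @export
print.seqlet_set <- function(x, ...) {
  cat(sprintf("Seqlet set: %d seqlets (window %d nt) from %d gene(s)\n",
              nrow(x$df), x$window_len, length(unique(x$df$gene_id))))
  if (nrow(x$df))
    cat(sprintf("  score range %.3g .. %.3g; %d upstream / %d downstream\n",
                min(x$df$total_score), max(x$df$total_score),
                sum(x$df$half == "upstream"), sum(x$df$half == "downstream")))
  invisible(x)
}

.subset_seqlets <- function(x, idx) {
  structure(list(df = x$df[idx, , drop = FALSE], patches = x$patches[idx],
                 seqs = x$seqs[idx], window_len = x$window_len, cfg = x$cfg),
            class = "seqlet_set")
}

#' Split seqlets into sign metaclusters
#'
#' Positive total scores form metacluster `p0` (associated with predicted
#' high expression), negative scores `p1` (low); zero-score seqlets are
#' discarded.
#'
#' @param seqlets a `seqlet_set`.
#' @return list with elements `p0` and `p1`, each a `seqlet_set`.
#' @export
split_metaclusters <- function(seqlets) {
  list(p0 = .subset_seqlets(seqlets, which(seqlets$df$total_score > 0)),
       p1 = .subset_seqlets(seqlets, which(seqlets$df$total_score < 0)))
}

## reverse complement of a patch / matrix in A,C,G,T channel order:
## reverse positions, swap A<->T and C<->G
rc_matrix <- function(m) {
  m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
}
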