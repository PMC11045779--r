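#' Motif scan configuration
#'
#' @param sensitivity report windows whose exact match p-value is strictly
#'   below this threshold (default 1e-4). The threshold acts per scanned
#'   window; the e-value over the whole scanned search space is still
#'   computed and reported for every match.
#' @param background base composition used for the log-odds score and the
#'   null score distribution; `NULL` (default) estimates the 0-order
#'   composition from the scanned sequences.
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @param pseudocount added to PWM entries before the log-odds transform.
#' @param bin_width score-lattice discretisation for the exact p-value
#'   dynamic programme.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(sensitivity = 1e-4, background = NULL,
                        both_strands = TRUE, pseudocount = 0.01,
                        bin_width = 1e-4) {
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  if (!is.null(background)) {
    if (length(background) != 4L || any(background < 0))
      stop("background must be 4 nonnegative frequencies")
    background <- background / sum(background)
  }
  structure(list(sensitivity = sensitivity,
                 background = background, both_strands = both_strands,
                 pseudocount = pseudocount, bin_width = bin_width),
            class = "scan_config")
}

#' Base composition of a set of sequences
#'
#' 0-order A/C/G/T frequencies over all non-`N` positions; useful as a
#' fixed scan background when several sequence sets (e.g. genotypes) must
#' be scanned under identical settings.
#'
#' @param sequences character vector of DNA strings.
#' @return numeric vector of 4 frequencies summing to 1.
#' @export
base_composition <- function(sequences) {
  ch <- strsplit(paste(sequences, collapse = ""), "")[[1]]
  tab <- table(factor(ch, levels = BASES))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- BASES
  out
}

#' Log2-odds score matrix of a PWM against a background
#'
#' @param pwm positions x 4 base-frequency matrix.
#' @param background 4 background frequencies summing to 1.
#' @param pseudocount added to the PWM entries before the log-odds
#'   transform (a zero pseudocount yields `-Inf` scores for zero entries).
#' @return positions x 4 matrix of log2-odds scores.
#' @export
pwm_score_matrix <- function(pwm, background, pseudocount = 0.01) {
  p <- (pwm + pseudocount) / (1 + 4 * pseudocount)
  log2(sweep(p, 2L, background, "/"))
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programme over the discretised score lattice under an i.i.d.
#' background model: returns a function mapping a score to the exact
#' probability that a random background word scores at least that high.
#'
#' @param score_mat W x 4 log-odds score matrix (log-odds matrix of the PWM against the background).
#' @param background background base frequencies (length 4, sums to 1).
#' @param bin_width lattice bin width (default 1e-4).
#' @return list with `pvalue(score)` (vectorised), and `score_at(p)` giving
#'   the smallest score whose p-value is <= `p`.
#' @export
pwm_score_distribution <- function(score_mat, background, bin_width = 1e-4) {
  si <- round(score_mat / bin_width)
  W <- nrow(si)
  ## -Inf entries (zero probability under the motif with no pseudocount)
  ## can never contribute to a finite total; their probability mass simply
  ## drops out of the distribution
  finite <- is.finite(si)
  if (any(!apply(finite, 1L, any)))
    stop("PWM column with no finite score")
  ## lattice must span every partial sum, not only the final support
  part_min <- cumsum(vapply(seq_len(W), function(j)
    min(si[j, finite[j, ]]), 0))
  part_max <- cumsum(vapply(seq_len(W), function(j)
    max(si[j, finite[j, ]]), 0))
  lo <- min(0, part_min)
  hi <- max(0, part_max)
  n <- as.integer(hi - lo + 1L)
  ## distribution over integer scores; index i holds score i - 1 + lo
  vec <- numeric(n)
  vec[0 - lo + 1L] <- 1
  for (j in seq_len(W)) {
    nxt <- numeric(n)
    for (b in which(finite[j, ])) {
      s <- si[j, b]
      src <- which(vec != 0)
      nxt[src + s] <- nxt[src + s] + vec[src] * background[b]
    }
    vec <- nxt
  }
  surv <- rev(cumsum(rev(vec)))  # P(total int score >= k + lo - 1)
  pvalue <- function(score) {
    k <- round(score / bin_width) - lo + 1L
    k <- pmax(1L, pmin(n + 1L, k))
    ifelse(k > n, 0, surv[pmin(k, n)])
  }
  score_at <- function(p) {
    k <- which(surv <= p)
    if (!length(k)) return(Inf)
    (min(k) + lo - 1L) * bin_width
  }
  list(pvalue = pvalue, score_at = score_at, bin_width = bin_width)
}

#' Scan sequences for EPM occurrences
#'
#' Log-odds scan of every EPM PWM against the supplied sequences, on both
#' strands, with exact p-values from the score-lattice dynamic programme
#' and e-values relative to the total scanned search space. Windows whose
#' p-value falls below the sensitivity threshold are reported. Match
#' offsets are
#' anchored like seqlets (window centre, TSS-relative upstream /
#' TTS-relative downstream) when `cfg` is given.
#'
#' @param epms an `epm_set` or list of `epm` objects (forward orientations
#'   are scanned; the reverse strand covers their complements).
#' @param sequences named character vector of sequences to scan.
#' @param scan_cfg a [scan_config()].
#' @param cfg optional [region_config()] for anchor-relative offsets.
#' @return data.frame of class `motif_matches`: `epm_name`, `gene_id`,
#'   `pos` (0-based window start), `half`, `offset`, `strand`, `score`,
#'   `p_value`, `e_value`.
#' @export
scan_motifs <- function(epms, sequences, scan_cfg = scan_config(),
                        cfg = NULL) {
  epms <- epms[vapply(epms, function(e) e$orientation == "fwd", NA)]
  codes <- lapply(sequences, seq_to_code)
  bg <- scan_cfg$background
  if (is.null(bg)) {
    tab <- table(factor(unlist(lapply(codes, function(x) x[x < 4L])),
                        levels = 0:3))
    bg <- as.numeric(tab) / sum(tab)
    bg[bg == 0] <- 1e-6
    bg <- bg / sum(bg)
  }
  out <- list()
  for (e in epms) {
    W <- nrow(e$pwm)
    sm <- pwm_score_matrix(e$pwm, bg, scan_cfg$pseudocount)
    dist <- pwm_score_distribution(sm, bg, scan_cfg$bin_width)
    n_strands <- if (scan_cfg$both_strands) 2L else 1L
    space <- sum(pmax(nchar(sequences) - W + 1L, 0L)) * n_strands
    min_score <- dist$score_at(scan_cfg$sensitivity)
    strands <- if (scan_cfg$both_strands) c("+", "-") else "+"
    for (st in strands) {
      smat <- if (st == "+") sm else rc_matrix(sm)
      hits <- cpp_scan_pwm(codes, smat, min_score - dist$bin_width / 2)
      if (!length(hits$seq)) next
      p <- dist$pvalue(hits$score)
      ev <- p * space
      keep <- p < scan_cfg$sensitivity
      if (!any(keep)) next
      pos <- hits$pos[keep]
      centre <- pos + W %/% 2L
      an <- if (is.null(cfg))
        data.frame(half = NA_character_, offset = NA_real_)[rep(1, sum(keep)), ]
      else anchor_offset(centre, cfg)
      out[[length(out) + 1L]] <- data.frame(
        epm_name = e$name %||% "(unnamed)",
        gene_id = names(sequences)[hits$seq[keep]] %||%
          as.character(hits$seq[keep]),
        pos = pos, half = an$half, offset = an$offset, strand = st,
        score = hits$score[keep], p_value = p[keep], e_value = ev[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(epm_name = character(), gene_id = character(),
               pos = integer(), half = character(), offset = numeric(),
               strand = character(), score = numeric(), p_value = numeric(),
               e_value = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("motif_matches", "data.frame")
  res
}

#' Flag matches lying in their EPM's preferred range
#'
#' A match is in range when its half has a preferred range for the EPM and
#' the anchor offset falls inside the closed interval `[Q1, Q3]`. EPMs
#' without a range for a half contribute no in-range matches there.
#'
#' @param matches `motif_matches` from [scan_motifs()].
#' @param epms the `epm_set` the matches came from.
#' @return `matches` with a logical `within_preferred` column.
#' @export
flag_preferred <- function(matches, epms) {
  ranges <- lapply(epms, `[[`, "preferred_ranges")
  names(ranges) <- vapply(epms, function(e) e$name %||% "", "")
  matches$within_preferred <- vapply(seq_len(nrow(matches)), function(i) {
    ## the reverse-complement name maps to the same motif's ranges
    nm <- matches$epm_name[i]
    r <- ranges[[nm]] %||% ranges[[sub("R$", "", nm)]]
    if (is.null(r)) return(FALSE)
    h <- matches$half[i]
    if (is.na(h) || is.null(r[[h]])) return(FALSE)
    matches$offset[i] >= r[[h]][1] && matches$offset[i] <= r[[h]][2]
  }, NA)
  matches
}
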