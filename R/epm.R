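#' Cluster seqlets of one metacluster and aggregate them into EPMs
#'
#' Greedy agglomerative clustering: seqlets are visited by descending
#' absolute score; each is assigned to the first existing cluster whose seed
#' patch it matches with normalised cross-correlation at or above
#' `similarity_threshold` (maximised over alignment offsets and both
#' orientations), otherwise it founds a new cluster. Each cluster is aligned
#' to its seed seqlet; the contribution weight matrix (CWM) is the mean
#' aligned hypothetical-score patch and the position weight matrix (PWM) the
#' base-frequency matrix of the aligned seqlet sequences. Clusters with
#' fewer than `min_seqlets` members are discarded.
#'
#' @param seqlets a `seqlet_set` from one metacluster
#'   ([split_metaclusters()]).
#' @param metacluster `"p0"` or `"p1"`.
#' @param max_per_metacluster cap on the number of seqlets clustered (the
#'   strongest are kept).
#' @param similarity_threshold cosine cross-correlation needed to join a
#'   cluster.
#' @param min_seqlets minimum cluster size retained as an EPM.
#' @param min_overlap minimum aligned overlap (columns) when scoring a
#'   shifted match.
#' @param trim_ic after aggregation the motif is trimmed to its maximal
#'   contiguous run of columns with at least this information content
#'   (bits); background-like flanks of the seqlet window would otherwise
#'   dilute the motif. Set to 0 to keep the full window.
#' @return list of `epm` objects (without names; see [name_epm()]).
#' @export
cluster_and_aggregate <- function(seqlets, metacluster = c("p0", "p1"),
                                  max_per_metacluster = 2000L,
                                  similarity_threshold = 0.7,
                                  min_seqlets = 10L, min_overlap = 11L,
                                  trim_ic = 0.25) {
  metacluster <- match.arg(metacluster)
  n <- nrow(seqlets$df)
  if (n == 0L) return(list())
  W <- seqlets$window_len
  ord <- order(-abs(seqlets$df$total_score))
  ord <- ord[seq_len(min(n, max_per_metacluster))]

  S <- W - min_overlap                 # max |shift|
  shifts <- -S:S
  ext <- W + 2L * S                    # padded frame length
  pad_vec <- function(patch, shift) {
    ## place patch columns into the padded frame at offset S + shift
    v <- numeric(4L * ext)
    idx0 <- S + shift
    rows <- (idx0 + 1L):(idx0 + W)
    m <- matrix(0, ext, 4L)
    m[rows, ] <- patch
    as.numeric(m)
  }
  ## per-shift norm of the overlapping part of a W-wide patch placed at the
  ## frame centre, against a patch placed at centre + shift
  overlap_norms <- function(patch) {
    cn <- sqrt(cumsum(rowSums(patch^2)))  # prefix norms
    vapply(shifts, function(sh) {
      a <- max(1L, 1L + sh); b <- min(W, W + sh)   # overlap in patch coords
      lo <- if (a > 1L) cn[a - 1L] else 0
      sqrt(max(cn[b]^2 - lo^2, 0))
    }, 0)
  }

  seeds_mat <- matrix(0, nrow = length(ord), ncol = 4L * ext)
  seed_norms <- matrix(0, nrow = length(ord), ncol = length(shifts))
  n_clusters <- 0L
  assign_cluster <- integer(length(ord))
  assign_shift <- integer(length(ord))
  assign_orient <- character(length(ord))

  for (ii in seq_along(ord)) {
    i <- ord[ii]
    patch <- seqlets$patches[[i]]
    best <- list(sim = -Inf)
    for (orient in c("fwd", "rev")) {
      p <- if (orient == "fwd") patch else rc_matrix(patch)
      if (n_clusters > 0L) {
        ## dot products of every seed frame with the patch at every shift
        pv <- vapply(shifts, function(sh) pad_vec(p, sh), numeric(4L * ext))
        dots <- seeds_mat[seq_len(n_clusters), , drop = FALSE] %*% pv
        ## at shift sh the patch overlaps with its columns
        ## [max(1, 1-sh), min(W, W-sh)] (the overlap_norms formula at -sh)
        ## and the seed with [max(1, 1+sh), min(W, W+sh)] (formula at +sh)
        pn <- overlap_norms(p)[rev(seq_along(shifts))]
        sn <- seed_norms[seq_len(n_clusters), , drop = FALSE]
        sims <- dots / (outer(rep(1, n_clusters), pn) * sn + 1e-12)
        bi <- arrayInd(which.max(sims), dim(sims))
        if (sims[bi] > best$sim)
          best <- list(sim = sims[bi], cluster = bi[1],
                       shift = shifts[bi[2]], orient = orient)
      }
    }
    if (is.finite(best$sim) && best$sim >= similarity_threshold) {
      assign_cluster[ii] <- best$cluster
      assign_shift[ii] <- best$shift
      assign_orient[ii] <- best$orient
    } else {
      n_clusters <- n_clusters + 1L
      seeds_mat[n_clusters, ] <- pad_vec(patch, 0L)
      seed_norms[n_clusters, ] <- overlap_norms(patch)
      assign_cluster[ii] <- n_clusters
      assign_shift[ii] <- 0L
      assign_orient[ii] <- "fwd"
    }
  }

  ## aggregate clusters
  out <- list()
  for (cl in seq_len(n_clusters)) {
    mem <- which(assign_cluster == cl)
    if (length(mem) < min_seqlets) next
    idx <- ord[mem]
    cwm_sum <- matrix(0, W, 4L)
    base_cnt <- matrix(0, W, 4L)
    cov <- numeric(W)
    for (j in seq_along(mem)) {
      sh <- assign_shift[mem[j]]
      p <- seqlets$patches[[idx[j]]]
      sq <- seqlets$seqs[idx[j]]
      if (assign_orient[mem[j]] == "rev") {
        p <- rc_matrix(p)
        sq <- revcomp(sq)
      }
      ## patch column c lands on seed column c + sh
      a <- max(1L, 1L + sh); b <- min(W, W + sh)
      tgt <- (a:b)          # seed columns covered
      src <- tgt - sh
      cwm_sum[tgt, ] <- cwm_sum[tgt, ] + p[src, , drop = FALSE]
      cov[tgt] <- cov[tgt] + 1
      ch <- strsplit(sq, "")[[1]][src]
      hit <- match(ch, BASES)
      okb <- !is.na(hit)
      if (any(okb))
        base_cnt[cbind(tgt[okb], hit[okb])] <-
          base_cnt[cbind(tgt[okb], hit[okb])] + 1
    }
    keep <- cov > 0
    cwm <- cwm_sum
    cwm[keep, ] <- cwm[keep, ] / cov[keep]
    pwm <- base_cnt
    rs <- rowSums(pwm)
    pwm[rs > 0, ] <- pwm[rs > 0, ] / rs[rs > 0]
    pwm[rs == 0, ] <- 0.25
    ## trim to the information-content core: background-like flank columns
    ## dilute the motif and add noise to downstream scanning
    core <- .ic_core(pwm, min_ic = trim_ic, min_width = 4L)
    cwm <- cwm[core, , drop = FALSE]
    pwm <- pwm[core, , drop = FALSE]
    colnames(cwm) <- colnames(pwm) <- BASES
    props <- motif_properties(pwm)
    offs <- seqlets$df$offset[idx]
    halves <- seqlets$df$half[idx]
    pr <- positional_preference_ranges(offs, halves)
    out[[length(out) + 1L]] <- structure(
      list(name = NULL, metacluster = metacluster, cwm = cwm, pwm = pwm,
           n_seqlets = length(mem), info_content = props$info_content,
           consensus = props$consensus, preferred_ranges = pr,
           seqlet_offsets = split(offs, halves),
           seqlet_gene_ids = seqlets$df$gene_id[idx],
           orientation = "fwd", sum_score = sum(cwm)),
      class = "epm")
  }
  ## order by size, largest first
  out[order(-vapply(out, `[[`, 0L, "n_seqlets"))]
}

## maximal contiguous run of columns whose information content reaches
## min_ic; falls back to the full width when the run is shorter than
## min_width
.ic_core <- function(pwm, min_ic = 0.25, min_width = 4L) {
  if (min_ic <= 0) return(seq_len(nrow(pwm)))
  plogp <- pwm * log2(pwm)
  plogp[pwm == 0] <- 0
  ic <- 2 + rowSums(plogp)
  ok <- ic >= min_ic
  if (!any(ok)) return(seq_len(nrow(pwm)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  if (r$lengths[best] < min_width) return(seq_len(nrow(pwm)))
  starts[best]:ends[best]
}

## preferred ranges: [Q1, Q3] of anchor offsets per half, present only when
## more than one tenth of the motif's seqlets fall in that half
positional_preference_ranges <- function(offsets, halves, min_fraction = 0.1) {
  n <- length(offsets)
  out <- list(upstream = NULL, downstream = NULL)
  for (h in c("upstream", "downstream")) {
    o <- offsets[halves == h]
    if (length(o) > min_fraction * n)
      out[[h]] <- unname(quantile(o, c(0.25, 0.75), type = 7))
  }
  out
}

#' Positional preferred ranges of an EPM
#'
#' The interquartile interval of the motif's seqlet anchor offsets, per
#' half (upstream offsets are TSS-relative, downstream TTS-relative). A
#' half is reported only when more than one tenth of the motif's seqlets
#' fall in it.
#'
#' @param epm an `epm` object.
#' @return list with `upstream` and `downstream`, each `c(lo, hi)` or
#'   `NULL`.
#' @export
positional_preference <- function(epm) epm$preferred_ranges

#' Information content and IUPAC consensus of a PWM
#'
#' Information content is `sum over positions of (2 + sum_b p_b log2 p_b)`
#' bits (`0 log 0 = 0`); the consensus assigns each position the IUPAC code
#' covering all bases with frequency >= 0.25.
#'
#' @param pwm positions x 4 base-frequency matrix, rows summing to 1.
#' @return list with `info_content` (bits) and `consensus` (IUPAC string).
#' @export
motif_properties <- function(pwm) {
  if (any(abs(rowSums(pwm) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  plogp <- pwm * log2(pwm)
  plogp[pwm == 0] <- 0
  ic <- sum(2 + rowSums(plogp))
  cons <- paste(apply(pwm, 1L, function(p) iupac_code(BASES[p >= 0.25])),
                collapse = "")
  list(info_content = ic, consensus = cons)
}

#' Reverse-complement version of an EPM
#'
#' @param epm an `epm` object.
#' @return the linked `epm` with reversed-complemented matrices and the `R`
#'   name suffix.
#' @export
revcomp_epm <- function(epm) {
  out <- epm
  out$cwm <- rc_matrix(epm$cwm)
  out$pwm <- rc_matrix(epm$pwm)
  out$consensus <- revcomp(epm$consensus)
  out$orientation <- if (epm$orientation == "fwd") "rev" else "fwd"
  if (!is.null(epm$name))
    out$name <- if (grepl("R$", epm$name)) sub("R$", "", epm$name)
                else paste0(epm$name, "R")
  out
}

#' Compose an EPM name
#'
#' Nomenclature: `epm{Species}-{S|M}{condition}{run}-p{0|1}m{index}` with an
#' `R` suffix for the reverse-complement orientation. The species code is
#' four letters (two of the genus, two of the epithet); `S`/`M` mark
#' single- and multi-species reference models; the condition digit (0 =
#' standard) may be followed by a two-digit cross-validation run index.
#'
#' @param species_code 4-letter species abbreviation, e.g. `"Arth"`.
#' @param model_type `"S"` or `"M"`.
#' @param condition single digit (default 0).
#' @param run_idx optional run index (0-99); omitted in the short dialect.
#' @param metacluster `"p0"` or `"p1"`.
#' @param motif_idx motif number within the metacluster.
#' @param revcomp TRUE for the reverse-complement orientation.
#' @return name string, e.g. `"epmArth-S019-p0m06"`.
#' @export
name_epm <- function(species_code, model_type = c("S", "M"), condition = 0L,
                     run_idx = NULL, metacluster = c("p0", "p1"),
                     motif_idx = 1L, revcomp = FALSE) {
  model_type <- match.arg(model_type)
  metacluster <- match.arg(metacluster)
  if (nchar(species_code) != 4L) stop("species_code must be 4 letters")
  if (condition < 0 || condition > 9) stop("condition must be a single digit")
  run <- if (is.null(run_idx)) "" else sprintf("%02d", as.integer(run_idx))
  sprintf("epm%s-%s%d%s-%sm%02d%s", species_code, model_type,
          as.integer(condition), run, metacluster, as.integer(motif_idx),
          if (revcomp) "R" else "")
}

#' Parse an EPM name
#'
#' Inverts [name_epm()]; both dialects (with and without the run index) are
#' accepted.
#'
#' @param name EPM name string.
#' @return list with `species_code`, `model_type`, `condition`, `run_idx`
#'   (or `NULL`), `metacluster`, `motif_idx`, `revcomp`.
#' @export
parse_epm_name <- function(name) {
  m <- regmatches(name, regexec(
    "^epm([A-Za-z]{4})-([SM])([0-9])([0-9]{2})?-(p[01])m([0-9]+)(R?)$", name))[[1]]
  if (length(m) == 0L) stop("malformed EPM name: ", name)
  list(species_code = m[2], model_type = m[3],
       condition = as.integer(m[4]),
       run_idx = if (m[5] == "") NULL else as.integer(m[5]),
       metacluster = m[6], motif_idx = as.integer(m[7]),
       revcomp = m[8] == "R")
}

#' @export
print.epm <- function(x, ...) {
  cat(sprintf("EPM %s [%s, %s]: %d seqlets, IC %.1f bits, consensus %s\n",
              x$name %||% "(unnamed)", x$metacluster, x$orientation,
              x$n_seqlets, x$info_content, x$consensus))
  for (h in c("upstream", "downstream")) {
    r <- x$preferred_ranges[[h]]
    if (!is.null(r))
      cat(sprintf("  preferred range %s (%s): [%.1f, %.1f]\n", h,
                  if (h == "upstream") "TSS-relative" else "TTS-relative",
                  r[1], r[2]))
  }
  invisible(x)
}

#' Discover expression-predictive motifs from importance tracks
#'
#' Full discovery pipeline: seqlet extraction, sign metacluster split,
#' similarity clustering and aggregation, nomenclature assignment, and
#' emission of the linked reverse-complement motif for every EPM.
#'
#' @inheritParams extract_seqlets
#' @inheritParams cluster_and_aggregate
#' @param species_code,model_type,condition,run_idx naming fields
#'   ([name_epm()]).
#' @param include_revcomp also emit the reverse-complement version of each
#'   EPM (default TRUE).
#' @return object of class `epm_set`: list of `epm` objects.
#' @export
discover_epms <- function(tracks, cfg = region_config(), window_len = 21L,
                          null_reps = 20L, fdr_level = 0.05, seed = 1L,
                          max_per_metacluster = 2000L,
                          similarity_threshold = 0.7, min_seqlets = 10L,
                          trim_ic = 0.25,
                          species_code = "Synt", model_type = "S",
                          condition = 0L, run_idx = NULL,
                          include_revcomp = TRUE) {
  seqlets <- extract_seqlets(tracks, cfg, window_len, null_reps, fdr_level,
                             seed)
  mc <- split_metaclusters(seqlets)
  epms <- list()
  for (m in c("p0", "p1")) {
    cl <- cluster_and_aggregate(mc[[m]], metacluster = m,
                                max_per_metacluster = max_per_metacluster,
                                similarity_threshold = similarity_threshold,
                                min_seqlets = min_seqlets, trim_ic = trim_ic)
    for (k in seq_along(cl)) {
      cl[[k]]$name <- name_epm(species_code, model_type, condition, run_idx,
                               m, k)
      epms[[length(epms) + 1L]] <- cl[[k]]
      if (include_revcomp)
        epms[[length(epms) + 1L]] <- revcomp_epm(cl[[k]])
    }
  }
  names(epms) <- vapply(epms, `[[`, "", "name")
  structure(epms, class = "epm_set", seqlets = seqlets)
}

#' @export
print.epm_set <- function(x, ...) {
  cat(sprintf("EPM set: %d motif(s) (including reverse complements)\n",
              length(x)))
  for (e in x) print(e)
  invisible(x)
}

#' Plot an EPM as a contribution-score logo
#'
#' Simple base-graphics logo: per position, letters are stacked with
#' heights proportional to the CWM scores (negative scores plot downwards).
#'
#' @param x an `epm` object.
#' @param which `"cwm"` (default) or `"pwm"`.
#' @param ... unused.
#' @export
plot.epm <- function(x, which = c("cwm", "pwm"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  W <- nrow(m)
  ylim <- range(0, rowSums(pmax(m, 0)), rowSums(pmin(m, 0)))
  graphics::plot(NULL, xlim = c(0.5, W + 0.5), ylim = ylim,
                 xlab = "position", ylab = which, main = x$name %||% "")
  cols <- c(A = "forestgreen", C = "dodgerblue3", G = "goldenrod2",
            T = "firebrick")
  for (i in seq_len(W)) {
    up <- 0; dn <- 0
    for (b in order(-abs(m[i, ]))) {
      v <- m[i, b]
      if (v >= 0) {
        graphics::rect(i - 0.45, up, i + 0.45, up + v, col = cols[b],
                       border = NA)
        graphics::text(i, up + v / 2, BASES[b], cex = 0.6)
        up <- up + v
      } else {
        graphics::rect(i - 0.45, dn + v, i + 0.45, dn, col = cols[b],
                       border = NA)
        dn <- dn + v
      }
    }
  }
  graphics::abline(h = 0)
  invisible(x)
}
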