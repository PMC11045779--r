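#' Class enrichment of an EPM
#'
#' Log2 fold change in the odds of the EPM (an in-range match) being
#' present in genes of its own expression class versus genes of the
#' opposite class. The own class is `high` for `p0` motifs and `low` for
#' `p1` motifs. With the continuity correction `eps` (default 0.5) the
#' fractions are `(a + eps)/(A + 2*eps)`; `eps = 0` gives the uncorrected
#' odds ratio (antisymmetric under swapping the classes).
#'
#' @param epm an `epm` object (or its name, when `matches` carries names).
#' @param matches `motif_matches` with the `within_preferred` flag
#'   ([flag_preferred()]); only in-range matches count.
#' @param labels data.frame from [assign_classes()].
#' @param eps continuity correction.
#' @return data.frame of class `enrichment_result` with counts `a`, `A`,
#'   `b`, `B`, the two fractions, `enrichment` (log2 odds ratio), `chi2`,
#'   `p`.
#' @export
epm_enrichment <- function(epm, matches, labels, eps = 0.5) {
  own <- if (epm$metacluster == "p0") "high" else "low"
  opp <- if (own == "high") "low" else "high"
  nm <- epm$name
  hit_genes <- unique(matches$gene_id[matches$within_preferred &
                                        (matches$epm_name == nm |
                                           matches$epm_name == paste0(nm, "R"))])
  own_genes <- labels$gene_id[labels$klass == own]
  opp_genes <- labels$gene_id[labels$klass == opp]
  a <- sum(own_genes %in% hit_genes); A <- length(own_genes)
  b <- sum(opp_genes %in% hit_genes); B <- length(opp_genes)
  if (A == 0L || B == 0L) stop("empty expression class")
  f_own <- (a + eps) / (A + 2 * eps)
  f_opp <- (b + eps) / (B + 2 * eps)
  enr <- log2((f_own / (1 - f_own)) / (f_opp / (1 - f_opp)))
  chi <- occurrence_chi2(a, A, b, B)
  structure(data.frame(epm_name = nm, own_class = own, a = a, A = A, b = b,
                       B = B, fraction_own = f_own, fraction_opp = f_opp,
                       enrichment = enr, chi2 = chi$chi2, p = chi$p,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Chi-square test of equal occurrence between the two classes
#'
#' Goodness-of-fit of the occurrence counts `(a, b)` against the equal
#' split expectation `((a+b)/2, (a+b)/2)`, 1 degree of freedom.
#'
#' @param a,b occurrence counts in the two classes.
#' @param A,B class sizes (retained for the interface; the equal-split test
#'   uses only `a` and `b`).
#' @return list with `chi2` and `p`.
#' @export
occurrence_chi2 <- function(a, A = NULL, b, B = NULL) {
  if (a + b == 0) stop("no occurrences to test")
  ct <- chisq.test(c(a, b), p = c(0.5, 0.5))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Compare EPMs to a reference motif database
#'
#' Best Pearson correlation between the EPM PWM and each reference PFM over
#' all alignment offsets with at least `min_overlap` aligned columns, in
#' both orientations. The p-value is the fraction of `n_shuffles`
#' column-shuffled versions of the reference scoring at least as high; the
#' e-value multiplies by the number of references. Hits with e-value below
#' 0.05 are flagged significant.
#'
#' @param epms `epm_set` or list of `epm` objects.
#' @param references named list of reference PFMs (positions x 4,
#'   column-normalised rows), e.g. from [read_jaspar_pfm()].
#' @param n_shuffles column shuffles per reference (default 1000).
#' @param seed RNG seed for the shuffles.
#' @param min_overlap minimum aligned columns (default 4).
#' @return data.frame: `epm_name`, `reference_id`, `offset`, `orientation`,
#'   `pcc`, `p_value`, `e_value`, `significant`.
#' @export
compare_to_reference <- function(epms, references, n_shuffles = 1000L,
                                 seed = 1L, min_overlap = 4L) {
  if (inherits(epms, "epm")) epms <- list(epms)
  epms <- epms[vapply(epms, function(e) e$orientation == "fwd", NA)]
  for (r in references) if (nrow(r) < min_overlap)
    stop("reference narrower than the minimum overlap")
  best_pcc <- function(q, r) {
    Wq <- nrow(q); Wr <- nrow(r)
    best <- list(pcc = -Inf, offset = 0L, orientation = "fwd")
    for (orient in c("fwd", "rev")) {
      rr <- if (orient == "fwd") r else rc_matrix(r)
      for (off in (-(Wr - min_overlap)):(Wq - min_overlap)) {
        qa <- max(1L, off + 1L); qb <- min(Wq, off + Wr)
        ra <- qa - off; rb <- qb - off
        if (qb - qa + 1L < min_overlap) next
        x <- as.numeric(q[qa:qb, ]); y <- as.numeric(rr[ra:rb, ])
        if (sd(x) == 0 || sd(y) == 0) next
        pcc <- cor(x, y)
        if (pcc > best$pcc) best <- list(pcc = pcc, offset = off,
                                         orientation = orient)
      }
    }
    best
  }
  out <- list()
  for (e in epms) {
    for (ri in seq_along(references)) {
      r <- references[[ri]]
      obs <- best_pcc(e$pwm, r)
      null <- with_seed(derive_seed(seed, paste0(e$name, "-", ri)), {
        vapply(seq_len(n_shuffles), function(k) {
          best_pcc(e$pwm, r[sample(nrow(r)), , drop = FALSE])$pcc
        }, 0)
      })
      p <- mean(null >= obs$pcc)
      ev <- p * length(references)
      out[[length(out) + 1L]] <- data.frame(
        epm_name = e$name %||% "(unnamed)",
        reference_id = names(references)[ri] %||% as.character(ri),
        offset = obs$offset, orientation = obs$orientation, pcc = obs$pcc,
        p_value = p, e_value = ev, significant = ev < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## Smith-Waterman local alignment of IUPAC consensus strings with an
## IUPAC-aware substitution score: 2 * jaccard(base sets) - 1
sw_score <- function(a, b, gap = 0.8) {
  sa <- IUPAC_SETS[strsplit(a, "")[[1]]]
  sb <- IUPAC_SETS[strsplit(b, "")[[1]]]
  n <- length(sa); m <- length(sb)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      jac <- length(intersect(sa[[i]], sb[[j]])) /
        length(union(sa[[i]], sb[[j]]))
      s <- 2 * jac - 1
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] - gap,
                               H[i + 1L, j] - gap)
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

#' Hierarchical clustering of EPMs by consensus similarity
#'
#' Pairwise distance is `1 - (local-alignment score / min length)` of the
#' IUPAC consensus strings, with an IUPAC-aware match score (Jaccard index
#' of the base sets, rescaled to `[-1, 1]`); the reverse-complement
#' orientation is also searched, so a motif and its reverse complement are
#' at distance 0. Average-linkage hierarchical clustering, cut at
#' `cut_height`. Singletons are allowed.
#'
#' @param epms `epm_set` or list of `epm` objects.
#' @param cut_height tree cut height (default 0.5).
#' @param gap gap penalty of the local alignment.
#' @return list with `clusters` (named membership vector), `hclust`, and
#'   `dist`.
#' @export
cluster_epms <- function(epms, cut_height = 0.5, gap = 0.8) {
  cons <- vapply(epms, `[[`, "", "consensus")
  nms <- vapply(seq_along(epms),
                function(i) epms[[i]]$name %||% as.character(i), "")
  if (any(!nzchar(cons))) stop("EPM with empty consensus")
  k <- length(cons)
  if (k < 2L) stop("need at least two EPMs to cluster")
  D <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- max(sw_score(cons[i], cons[j], gap),
               sw_score(cons[i], revcomp(cons[j]), gap))
      D[i, j] <- D[j, i] <- 1 - s / min(nchar(cons[i]), nchar(cons[j]))
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  cl <- cutree(hc, h = cut_height)
  list(clusters = cl, hclust = hc, dist = as.dist(D))
}
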