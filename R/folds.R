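#' Load pairwise protein homology hits
#'
#' Consumes 12-column tabular hit files (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score). Self hits are dropped and the pair list is
#' symmetrised: every non-self pair is stored in both directions.
#'
#' @param hits either a file path or a data.frame with at least columns
#'   1 (query), 2 (subject), 11 (e-value), 12 (bit score).
#' @return data.frame with columns `query_gene`, `subject_gene`, `e_value`,
#'   `bit_score`, symmetrised.
#' @export
load_homology <- function(hits) {
  if (is.character(hits)) {
    hits <- read.delim(hits, header = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(hits) < 12L) stop("expected a 12-column hit table")
  df <- data.frame(query_gene = as.character(hits[[1]]),
                   subject_gene = as.character(hits[[2]]),
                   e_value = as.numeric(hits[[11]]),
                   bit_score = as.numeric(hits[[12]]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$e_value) || anyNA(df$bit_score)) stop("malformed hit rows")
  df <- df[df$query_gene != df$subject_gene, , drop = FALSE]
  sym <- rbind(df, data.frame(query_gene = df$subject_gene,
                              subject_gene = df$query_gene,
                              e_value = df$e_value,
                              bit_score = df$bit_score,
                              stringsAsFactors = FALSE))
  unique(sym)
}

#' Homology test on a single hit
#'
#' Two sequences count as homologous when the hit has an e-value below 0.001
#' and a bit score above 50 (both strict).
#'
#' @param e_value,bit_score hit statistics (vectorised).
#' @return logical vector.
#' @export
is_homologous <- function(e_value, bit_score) {
  e_value < 0.001 & bit_score > 50
}

## gene -> character vector of qualifying homologs
.homolog_map <- function(homology) {
  if (is.null(homology) || nrow(homology) == 0L) return(list())
  q <- homology[is_homologous(homology$e_value, homology$bit_score), ,
                drop = FALSE]
  split(q$subject_gene, q$query_gene)
}

#' Build leave-one-chromosome-out cross-validation folds
#'
#' One fold per chromosome (schemes `SSR`, `SSRU`, `SSC`) or per held-out
#' species (`MSR`; training uses all chromosomes of the other species). Under
#' `SSR`, `SSC` and `MSR`, validation genes with a qualifying homolog
#' (e-value < 0.001, bit score > 50) in the training set are dropped; `SSRU`
#' keeps them. The training majority class is down-sampled without
#' replacement to the minority count; validation sets are left unbalanced.
#'
#' @param labels data.frame from [assign_classes()]; only genes with a
#'   binary label (low/high) are used.
#' @param annotation data.frame with `gene_id`, `chrom` and, for `MSR`, a
#'   `species` column.
#' @param homology symmetrised pair table from [load_homology()], or `NULL`.
#' @param scheme one of `"SSR"`, `"SSRU"`, `"MSR"`, `"SSC"`.
#' @param seed integer seed controlling the down-sampling.
#' @return object of class `cre_folds`: a list of folds, each with
#'   `fold_id`, `validation_unit`, `train_ids`, `val_ids`, `scheme`, `seed`.
#' @export
make_folds <- function(labels, annotation, homology = NULL,
                       scheme = c("SSR", "SSRU", "MSR", "SSC"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  lab <- labels[!is.na(labels$binary), c("gene_id", "binary")]
  ann_cols <- c("gene_id", "chrom", if (scheme == "MSR") "species")
  if (scheme == "MSR" && is.null(annotation$species))
    stop("MSR folds require a 'species' column in the annotation")
  lab <- merge(lab, annotation[, ann_cols], by = "gene_id")
  lab <- lab[order(lab$gene_id), ]
  unit <- if (scheme == "MSR") lab$species else lab$chrom
  hmap <- .homolog_map(homology)
  drop_homologs <- scheme != "SSRU"

  folds <- list()
  for (u in sort(unique(unit))) {
    val <- lab$gene_id[unit == u]
    train <- lab$gene_id[unit != u]
    if (length(val) == 0L || length(train) == 0L) {
      warning("fold ", u, " skipped: no binary-labelled genes on one side")
      next
    }
    if (drop_homologs && length(hmap)) {
      train_set <- train
      has_h <- vapply(val, function(g) {
        h <- hmap[[g]]
        !is.null(h) && any(h %in% train_set)
      }, NA)
      val <- val[!has_h]
    }
    ## balance the training set by down-sampling the majority class
    ytr <- lab$binary[match(train, lab$gene_id)]
    n0 <- sum(ytr == 0L); n1 <- sum(ytr == 1L)
    if (n0 == 0L || n1 == 0L) {
      warning("fold ", u, " skipped: single-class training set")
      next
    }
    k <- min(n0, n1)
    train <- with_seed(derive_seed(seed, paste0("fold-", u)), {
      keep0 <- sample(train[ytr == 0L], k)
      keep1 <- sample(train[ytr == 1L], k)
      sort(c(keep0, keep1))
    })
    folds[[length(folds) + 1L]] <- list(
      fold_id = paste0(scheme, "-", u),
      validation_unit = u,
      train_ids = train,
      val_ids = sort(val),
      scheme = scheme,
      seed = seed)
  }
  if (length(folds) == 0L) stop("no usable folds")
  structure(folds, class = "cre_folds", labels = lab)
}

#' @export
print.cre_folds <- function(x, ...) {
  cat("Cross-validation folds (", x[[1]]$scheme, " scheme): ",
      length(x), " fold(s)\n", sep = "")
  for (f in x) {
    cat(sprintf("  %-12s train %5d (balanced)  val %5d\n",
                f$fold_id, length(f$train_ids), length(f$val_ids)))
  }
  invisible(x)
}

#' Mononucleotide (or dinucleotide) sequence shuffling control
#'
#' Per-sequence permutation that retains the nucleotide composition. All `N`
#' positions (including the fused spacer block) are preserved in place.
#' `mode = "dinuc"` preserves the dinucleotide composition of every run of
#' non-`N` bases using an Eulerian-walk shuffle.
#'
#' @param seqs character vector of DNA strings.
#' @param seed integer seed; identical seeds reproduce identical output.
#' @param mode `"mono"` (default) or `"dinuc"`.
#' @return character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs, seed = 1L, mode = c("mono", "dinuc")) {
  mode <- match.arg(mode)
  with_seed(derive_seed(seed, "shuffle"), {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      keep <- ch == "N"
      if (mode == "mono") {
        ch[!keep] <- sample(ch[!keep])
      } else {
        ## shuffle each maximal non-N run preserving dinucleotides
        r <- rle(keep)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (i in which(!r$values)) {
          seg <- ch[starts[i]:ends[i]]
          ch[starts[i]:ends[i]] <- .dinuc_shuffle(seg)
        }
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = !is.null(names(seqs)))
  })
}

## Altschul-Erickson style doublet-preserving shuffle of a character vector
.dinuc_shuffle <- function(seg) {
  n <- length(seg)
  if (n < 3L) return(seg)
  ## edge lists per source base
  edges <- split(seg[-1L], seg[-n])
  edges <- lapply(edges, function(e) if (length(e) > 1L) sample(e) else e)
  ## force last vertex: an Eulerian path must end at seg[n]; retry shuffles
  ## until a walk consuming all edges exists (guaranteed eventually since
  ## the original order is one such walk)
  for (attempt in 1:200) {
    take <- lapply(edges, identity)
    out <- character(n); out[1L] <- seg[1L]
    ok <- TRUE
    for (i in 2:n) {
      v <- out[i - 1L]
      e <- take[[v]]
      if (length(e) == 0L) { ok <- FALSE; break }
      out[i] <- e[1L]
      take[[v]] <- e[-1L]
    }
    if (ok) return(out)
    edges <- lapply(edges, function(e) if (length(e) > 1L) sample(e) else e)
  }
  seg  # degenerate composition; return unchanged
}
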