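#' Read a JASPAR-style PFM text file
#'
#' Supports the JASPAR format: a `>ID name` header followed by four rows
#' (`A`, `C`, `G`, `T`) of counts, with or without the bracketed row style
#' (`A [ 1 2 3 ]`). Matrices are column-normalised to row-stochastic
#' positions x 4 PFMs.
#'
#' @param path path to the PFM text file.
#' @return named list of positions x 4 frequency matrices.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("motif block with fewer than 4 rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) stop("ragged PFM rows")
    m <- t(do.call(rbind, rows))
    colnames(m) <- BASES
    m <- m / rowSums(m)
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    out[[id]] <- m
  }
  out
}

#' Write EPMs in MEME motif format
#'
#' @param epms `epm_set` or list of `epm` objects.
#' @param path output file.
#' @param background background frequencies recorded in the header.
#' @export
write_meme <- function(epms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (e in epms) {
    writeLines(sprintf("MOTIF %s", e$name %||% "unnamed"), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(e$pwm), e$n_seqlets), con)
    for (i in seq_len(nrow(e$pwm)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", e$pwm[i, 1], e$pwm[i, 2],
                         e$pwm[i, 3], e$pwm[i, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write EPM side data (CWM, scores, ranges) as TSV
#'
#' @param epms `epm_set`.
#' @param path output file.
#' @export
write_epm_tsv <- function(epms, path) {
  df <- do.call(rbind, lapply(epms, function(e) {
    data.frame(name = e$name %||% "", metacluster = e$metacluster,
               orientation = e$orientation, n_seqlets = e$n_seqlets,
               info_content = e$info_content, consensus = e$consensus,
               sum_score = e$sum_score,
               up_lo = e$preferred_ranges$upstream[1] %||% NA,
               up_hi = e$preferred_ranges$upstream[2] %||% NA,
               dn_lo = e$preferred_ranges$downstream[1] %||% NA,
               dn_hi = e$preferred_ranges$downstream[2] %||% NA,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fold manifest as JSON
#'
#' @param folds a `cre_folds` object.
#' @param path output file.
#' @export
write_fold_manifest <- function(folds, path) {
  manifest <- lapply(folds, function(f)
    list(fold_id = f$fold_id, validation_unit = f$validation_unit,
         scheme = f$scheme, seed = f$seed,
         n_train = length(f$train_ids), n_val = length(f$val_ids),
         train_ids = f$train_ids, val_ids = f$val_ids))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write motif matches as BED-like TSV
#'
#' @param matches `motif_matches` data.frame.
#' @param path output file.
#' @export
write_matches_tsv <- function(matches, path) {
  write.table(as.data.frame(matches), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
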