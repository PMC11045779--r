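#' Run an end-to-end experiment
#'
#' Orchestrates the full pipeline on one configuration: data loading (or
#' synthetic generation), flank extraction, expression labelling, fold
#' construction, per-fold training and evaluation, and optionally
#' attribution and motif discovery on the pooled validation sets. All
#' artifacts are written under `output_dir` and listed in a JSON manifest.
#'
#' @param config a list with elements:
#'   * `synthetic`: a [synthetic_config()], or `NULL` to read files,
#'   * `fasta`, `gff`, `tpm`, `homology`: input paths (when `synthetic` is
#'     `NULL`; `homology` may be `NULL`),
#'   * `region`: a [region_config()] (default used when missing),
#'   * `model`: a [cnn_config()],
#'   * `scan`: a [scan_config()],
#'   * `scheme`: `"SSR"`, `"SSRU"`, `"MSR"` or `"SSC"`,
#'   * `output_dir`: output directory,
#'   * `seed`: experiment seed,
#'   * `discover_motifs`: logical (default `FALSE`),
#'   * `attribution_k`: shuffled references per gene (default 10),
#'   * `species_code`: 4-letter code used in EPM names (default `"Synt"`).
#' @return invisible list with `manifest`, `folds`, `fold_results`,
#'   `labels`, and, when requested, `epms`, `matches`, `enrichment`.
#' @export
run_experiment <- function(config) {
  cfg <- modifyList(list(region = region_config(), model = cnn_config(),
                         scan = scan_config(), scheme = "SSR", seed = 1L,
                         discover_motifs = FALSE, attribution_k = 10L,
                         species_code = "Synt", homology = NULL),
                    config)
  if (is.null(cfg$output_dir)) stop("config$output_dir is required")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  files <- character(0)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    res
  }

  inputs <- stage("load", {
    if (!is.null(cfg$synthetic)) {
      synth <- generate_genome(cfg$synthetic)
      tpm <- generate_expression(synth)
      list(genome = synth$genome, annotation = synth$annotation,
           tpm = tpm, homology = synth$homology, synth = synth)
    } else {
      for (p in c(cfg$fasta, cfg$gff, cfg$tpm))
        if (!file.exists(p)) stop("input file not found: ", p)
      list(genome = read_genome(cfg$fasta),
           annotation = read_annotation(cfg$gff),
           tpm = read_tpm_table(cfg$tpm),
           homology = if (!is.null(cfg$homology))
             read.delim(cfg$homology, header = FALSE) else NULL)
    }
  })

  flanks <- stage("extract", {
    fl <- extract_all_flanks(inputs$annotation, inputs$genome, cfg$region)
    write_flanks_fasta(fl, out("flanks.fasta"), cfg$region)
    files <- c(files, "flanks.fasta")
    fl
  })
  sequences <- setNames(flanks$fused, flanks$gene_id)

  labels <- stage("label", {
    lab <- label_expression(inputs$tpm)
    write.table(lab, out("labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, "labels.tsv")
    lab
  })

  folds <- stage("folds", {
    hom <- if (!is.null(inputs$homology)) load_homology(inputs$homology)
    f <- make_folds(labels, inputs$annotation, hom, scheme = cfg$scheme,
                    seed = cfg$seed)
    write_fold_manifest(f, out("folds.json"))
    files <- c(files, "folds.json")
    f
  })

  fold_results <- stage("train", {
    model_cfg <- cfg$model
    model_cfg$seed <- derive_seed(cfg$seed, "model")
    res <- train_folds(folds, sequences, labels, model_cfg, verbose = TRUE)
    metrics <- do.call(rbind, lapply(res, function(r)
      data.frame(fold_id = r$fold_id, accuracy = r$metrics$accuracy,
                 auroc = r$metrics$auroc, f1 = r$metrics$f1,
                 n_val = r$metrics$n)))
    write.table(metrics, out("metrics.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, "metrics.tsv")
    res
  })

  result <- list(folds = folds, fold_results = fold_results,
                 labels = labels)

  if (isTRUE(cfg$discover_motifs)) {
    epms <- stage("discover", {
      tracks <- list()
      for (r in fold_results) {
        f <- folds[[match(r$fold_id, vapply(folds, `[[`, "", "fold_id"))]]
        tracks <- c(tracks, compute_contributions_batch(
          r$model, sequences[f$val_ids], k = cfg$attribution_k,
          seed = derive_seed(cfg$seed, paste0("attr-", r$fold_id))))
      }
      profile <- average_saliency(tracks)
      write_saliency_tsv(profile, out("saliency.tsv"))
      e <- discover_epms(tracks, cfg$region,
                         seed = derive_seed(cfg$seed, "discover"),
                         species_code = cfg$species_code,
                         model_type = if (cfg$scheme == "MSR") "M" else "S")
      write_meme(e, out("epms.meme"))
      write_epm_tsv(e, out("epms.tsv"))
      files <- c(files, "saliency.tsv", "epms.meme", "epms.tsv")
      e
    })
    result$epms <- epms
    if (length(epms)) {
      result$matches <- stage("scan", {
        m <- scan_motifs(epms, sequences, cfg$scan, cfg$region)
        m <- flag_preferred(m, epms)
        write_matches_tsv(m, out("matches.tsv"))
        files <- c(files, "matches.tsv")
        m
      })
      result$enrichment <- stage("enrich", {
        fw <- epms[vapply(epms, function(e) e$orientation == "fwd", NA)]
        enr <- do.call(rbind, lapply(fw, function(e)
          epm_enrichment(e, result$matches, labels)))
        write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, "enrichment.tsv")
        enr
      })
    }
  }

  manifest <- list(
    scheme = cfg$scheme, seed = cfg$seed,
    n_genes = nrow(inputs$annotation),
    n_folds = length(folds),
    metrics = lapply(fold_results, function(r)
      c(list(fold_id = r$fold_id), r$metrics)),
    files = as.list(setdiff(list.files(cfg$output_dir), "manifest.json")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
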