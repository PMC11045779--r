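#' Genotype analysis configuration
#'
#' @param variance_threshold probability variance above which a gene is
#'   called differentially expressed across genotypes (default 0.005).
#' @param prob_low_cutoff probabilities at or below this value classify a
#'   genotype as low-expressing (default 0.5).
#' @param bootstrap_pool pool size per bootstrap draw (default 100).
#' @param bootstrap_reps number of bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(variance_threshold = 0.005,
                            prob_low_cutoff = 0.5, bootstrap_pool = 100L,
                            bootstrap_reps = 1000L, seed = 1L) {
  stopifnot(prob_low_cutoff > 0, prob_low_cutoff < 1, bootstrap_pool > 0,
            bootstrap_reps > 0)
  structure(list(variance_threshold = variance_threshold,
                 prob_low_cutoff = prob_low_cutoff,
                 bootstrap_pool = as.integer(bootstrap_pool),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Classify cross-genotype expression heterogeneity
#'
#' Per gene, the population variance (divide by n) of the predicted
#' high-expression probabilities across genotypes; genes whose variance
#' exceeds the threshold are called `differential`, the rest `homogeneous`.
#' Per genotype, probabilities at or below the cutoff indicate low
#' expression.
#'
#' @param probs either a named numeric vector (one gene, one probability
#'   per genotype) or a genes x genotypes matrix.
#' @param cfg an [analysis_config()].
#' @return data.frame with `gene_id`, `variance`, `heterogeneity`
#'   (`homogeneous`/`differential`) and one `class_<genotype>` column per
#'   genotype (`low`/`high`).
#' @export
classify_heterogeneity <- function(probs, cfg = analysis_config()) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L,
                                           dimnames = list("gene1",
                                                           names(probs)))
  v <- apply(probs, 1L, function(x) mean((x - mean(x))^2))
  het <- ifelse(v > cfg$variance_threshold, "differential", "homogeneous")
  cls <- ifelse(probs <= cfg$prob_low_cutoff, "low", "high")
  out <- data.frame(gene_id = rownames(probs) %||% as.character(seq_len(nrow(probs))),
                    variance = unname(v), heterogeneity = unname(het),
                    stringsAsFactors = FALSE)
  cls_df <- as.data.frame(cls, stringsAsFactors = FALSE)
  names(cls_df) <- paste0("class_", colnames(probs) %||%
                            seq_len(ncol(probs)))
  cbind(out, cls_df)
}

#' Conservation status of EPMs across genotypes
#'
#' Per gene and EPM: `conserved` when the EPM has at least one in-range
#' match in every genotype; `mutated` when it is present in the reference
#' genotype but absent from at least one other; `absent` when the
#' reference genotype itself has no in-range match (excluded from the
#' two-way statistics).
#'
#' @param matches_by_genotype named list (one element per genotype) of
#'   `motif_matches` with the `within_preferred` flag; gene ids must be
#'   comparable across genotypes.
#' @param reference_genotype name of the reference genotype in the list.
#' @param gene_ids genes to assess (default: all genes with any match).
#' @param epm_names EPMs to assess (default: all EPMs seen in the
#'   reference; reverse-complement matches count towards their forward
#'   motif).
#' @return data.frame with `gene_id`, `epm_name`, `status`.
#' @export
epm_conservation <- function(matches_by_genotype, reference_genotype,
                             gene_ids = NULL, epm_names = NULL) {
  if (!reference_genotype %in% names(matches_by_genotype))
    stop("reference genotype not found")
  norm_name <- function(x) sub("R$", "", x)
  presence <- lapply(matches_by_genotype, function(m) {
    m <- m[m$within_preferred, , drop = FALSE]
    unique(data.frame(gene_id = m$gene_id,
                      epm_name = norm_name(m$epm_name),
                      stringsAsFactors = FALSE))
  })
  ref <- presence[[reference_genotype]]
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(lapply(presence, `[[`, "gene_id"))))
  if (is.null(epm_names))
    epm_names <- sort(unique(ref$epm_name))
  grid <- expand.grid(gene_id = gene_ids, epm_name = epm_names,
                      stringsAsFactors = FALSE)
  key <- function(df) paste(df$gene_id, df$epm_name)
  pres_keys <- lapply(presence, key)
  gk <- key(grid)
  in_ref <- gk %in% pres_keys[[reference_genotype]]
  n_present <- Reduce(`+`, lapply(pres_keys, function(k) gk %in% k))
  status <- ifelse(n_present == length(presence), "conserved",
                   ifelse(in_ref, "mutated", "absent"))
  data.frame(grid, status = status, stringsAsFactors = FALSE)
}

#' Per-gene conservation call
#'
#' A gene is `mutated` when any of its EPMs is mutated, `conserved` when it
#' has at least one assessed EPM and none is mutated, `absent` otherwise.
#'
#' @param conservation data.frame from [epm_conservation()].
#' @return data.frame with `gene_id`, `gene_status`.
#' @export
gene_conservation <- function(conservation) {
  st <- split(conservation$status, conservation$gene_id)
  gs <- vapply(st, function(s) {
    if (any(s == "mutated")) "mutated"
    else if (any(s == "conserved")) "conserved"
    else "absent"
  }, "")
  data.frame(gene_id = names(gs), gene_status = unname(gs),
             stringsAsFactors = FALSE)
}

#' Bootstrap percentages of conserved / mutated genes per heterogeneity group
#'
#' Draws `bootstrap_reps` pools of `bootstrap_pool` genes with replacement
#' from each heterogeneity group and records the percentage of conserved
#' and mutated genes per pool.
#'
#' @param gene_status data.frame with `gene_id`, `gene_status`
#'   ([gene_conservation()]).
#' @param heterogeneity data.frame with `gene_id`, `heterogeneity`
#'   ([classify_heterogeneity()]).
#' @param cfg an [analysis_config()].
#' @return data.frame with one row per (group, replicate): `group`,
#'   `rep`, `pct_conserved`, `pct_mutated`.
#' @export
bootstrap_percentages <- function(gene_status, heterogeneity,
                                  cfg = analysis_config()) {
  df <- merge(gene_status, heterogeneity[, c("gene_id", "heterogeneity")],
              by = "gene_id")
  out <- list()
  for (g in unique(df$heterogeneity)) {
    st <- df$gene_status[df$heterogeneity == g]
    if (!length(st)) next
    draws <- with_seed(derive_seed(cfg$seed, paste0("boot-", g)), {
      vapply(seq_len(cfg$bootstrap_reps), function(r) {
        pool <- sample(st, cfg$bootstrap_pool, replace = TRUE)
        c(mean(pool == "conserved"), mean(pool == "mutated")) * 100
      }, numeric(2))
    })
    out[[length(out) + 1L]] <- data.frame(
      group = g, rep = seq_len(cfg$bootstrap_reps),
      pct_conserved = draws[1, ], pct_mutated = draws[2, ],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fisher exact test of set intersection
#'
#' Two-sided Fisher exact test on the 2x2 membership table of two gene
#' sets within a universe.
#'
#' @param setA,setB character vectors (subsets of `universe`).
#' @param universe character vector of all genes.
#' @return list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
fisher_intersection <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  tab <- table(factor(inA, c(TRUE, FALSE)), factor(inB, c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Hierarchical clustering of genotypes by predicted expression profiles
#'
#' Euclidean distance between genotype probability profiles, average
#' linkage. Genes with missing values are dropped.
#'
#' @param prob_matrix genes x genotypes matrix of predicted probabilities.
#' @return an [ape::as.phylo()] tree (`phylo`), with the `hclust` object as
#'   attribute `"hclust"`.
#' @export
cluster_genotype_profiles <- function(prob_matrix) {
  if (ncol(prob_matrix) < 2L) stop("need at least two genotypes")
  prob_matrix <- prob_matrix[complete.cases(prob_matrix), , drop = FALSE]
  hc <- hclust(dist(t(prob_matrix), method = "euclidean"),
               method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Write a genotype tree as newick
#'
#' @param tree a `phylo` object ([cluster_genotype_profiles()]).
#' @param path output file.
#' @export
write_genotype_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Category-level observed-vs-predicted expression comparison
#'
#' Per functional category, the difference of mean per-gene values between
#' species B and species A, where the per-gene value lies in `[0, 1]`
#' (observed: the binary label; predicted: the probability). The scaled
#' difference is therefore in `[-1, 1]`: -1 marks expression in species A
#' only, 0 equal expression, +1 expression in species B only. Differential
#' categories are tested with a two-sided Wilcoxon rank-sum test on the
#' predicted per-gene values and corrected with Benjamini-Hochberg across
#' categories.
#'
#' @param categories data.frame with `gene_id` (species A ids) and
#'   `category`.
#' @param obs_a,obs_b named numeric vectors of observed binary labels
#'   (0/1) for species A and B genes.
#' @param pred_a,pred_b named numeric vectors of predicted probabilities.
#' @param orthologs data.frame with `gene_a`, `gene_b` mapping species A
#'   genes to their species B orthologs.
#' @param min_n minimum genes per category (default 5).
#' @return data.frame: `category_id`, `n`, `scaled_obs_diff`,
#'   `scaled_pred_diff`, `wilcoxon_p`, `fdr`; the Spearman correlation
#'   between the observed and predicted scaled differences across
#'   categories is attached as attribute `"spearman"`.
#' @export
category_comparison <- function(categories, obs_a, obs_b, pred_a, pred_b,
                                orthologs, min_n = 5L) {
  rows <- list()
  for (cat in unique(categories$category)) {
    ga <- categories$gene_id[categories$category == cat]
    gb <- orthologs$gene_b[match(ga, orthologs$gene_a)]
    keep <- !is.na(gb) & ga %in% names(pred_a) & gb %in% names(pred_b) &
      ga %in% names(obs_a) & gb %in% names(obs_b)
    ga <- ga[keep]; gb <- gb[keep]
    if (length(ga) < min_n) next
    pa <- pred_a[ga]; pb <- pred_b[gb]
    wp <- suppressWarnings(wilcox.test(pa, pb, alternative = "two.sided",
                                       exact = FALSE)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      category_id = cat, n = length(ga),
      scaled_obs_diff = mean(obs_b[gb]) - mean(obs_a[ga]),
      scaled_pred_diff = mean(pb) - mean(pa),
      wilcoxon_p = wp, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no category reached the minimum size")
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$wilcoxon_p, method = "BH")
  attr(out, "spearman") <- suppressWarnings(
    cor(out$scaled_obs_diff, out$scaled_pred_diff, method = "spearman"))
  out
}
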