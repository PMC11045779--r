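test_that("heterogeneity calls use population variance against the threshold", {
  cfg <- analysis_config()
  r <- classify_heterogeneity(c(gA = 0.6, gB = 0.6, gC = 0.6), cfg)
  expect_equal(r$variance, 0)
  expect_equal(r$heterogeneity, "homogeneous")
  ## {0.2, 0.9}: population variance 0.1225 > 0.005
  r2 <- classify_heterogeneity(c(a = 0.2, b = 0.9), cfg)
  expect_equal(r2$variance, 0.1225)
  expect_equal(r2$heterogeneity, "differential")
  ## boundary: p = 0.5 classifies the genotype as low
  r3 <- classify_heterogeneity(c(a = 0.5, b = 0.9), cfg)
  expect_equal(r3$class_a, "low")
  expect_equal(r3$class_b, "high")
  ## invariance to genotype ordering
  m <- matrix(runif(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  r4 <- classify_heterogeneity(m, cfg)
  r5 <- classify_heterogeneity(m[, 5:1], cfg)
  expect_equal(r4$variance, r5$variance)
  expect_equal(r4$heterogeneity, r5$heterogeneity)
})

fake_matches <- function(genes) {
  data.frame(epm_name = "epmSynt-S0-p0m01", gene_id = genes, pos = 0,
             half = "upstream", offset = 10, strand = "+", score = 1,
             p_value = 0, e_value = 0, within_preferred = TRUE,
             stringsAsFactors = FALSE)
}

test_that("conservation status distinguishes conserved, mutated and absent", {
  mbg <- c(list(ref = fake_matches(c("g1", "g2"))),
           setNames(lapply(1:14, function(i)
             fake_matches(if (i == 1) "g1" else c("g1", "g2"))),
             paste0("acc", 1:14)))
  cons <- epm_conservation(mbg, "ref")
  expect_equal(cons$status[cons$gene_id == "g1"], "conserved")   # 15/15
  expect_equal(cons$status[cons$gene_id == "g2"], "mutated")     # 14/15, in ref
  ## a gene absent from the reference is 'absent', not mutated
  mbg2 <- mbg; mbg2$ref <- fake_matches("g1")
  cons2 <- epm_conservation(mbg2, "ref", gene_ids = c("g1", "g2"))
  expect_equal(cons2$status[cons2$gene_id == "g2"], "absent")
  ## statuses are mutually exclusive per (gene, EPM)
  expect_equal(anyDuplicated(cons[, c("gene_id", "epm_name")]), 0L)
})

test_that("bootstrap percentages are seeded and match binomial theory", {
  gs <- data.frame(gene_id = paste0("g", 1:200),
                   gene_status = c(rep("conserved", 140), rep("mutated", 60)))
  het <- data.frame(gene_id = gs$gene_id, heterogeneity = "homogeneous")
  cfg <- analysis_config(seed = 3)
  b1 <- bootstrap_percentages(gs, het, cfg)
  b2 <- bootstrap_percentages(gs, het, cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 1000L)
  ## mean within 3 binomial SE of the true fraction (pool size 100)
  se <- sqrt(0.7 * 0.3 / 100) * 100
  expect_lt(abs(mean(b1$pct_conserved) - 70), 3 * se)
  ## all-conserved group: every percentage is 100
  gs2 <- data.frame(gene_id = paste0("g", 1:50), gene_status = "conserved")
  het2 <- data.frame(gene_id = gs2$gene_id, heterogeneity = "homogeneous")
  b3 <- bootstrap_percentages(gs2, het2, cfg)
  expect_true(all(b3$pct_conserved == 100))
})

test_that("Fisher intersection test matches hypergeometric summation", {
  universe <- paste0("g", 1:100)
  ## direct hypergeometric oracle for the two-sided test
  hyper_p <- function(k, K, n, N) {
    ## K = |A|, n = |B|, N = |U|, k = |A and B|
    probs <- dhyper(0:min(K, n), K, N - K, n)
    sum(probs[probs <= dhyper(k, K, N - K, n) * (1 + 1e-7)])
  }
  set.seed(80)
  for (i in 1:10) {
    A <- sample(universe, 10); B <- sample(universe, 10)
    got <- fisher_intersection(A, B, universe)
    k <- length(intersect(A, B))
    expect_equal(got$p, hyper_p(k, 10, 10, 100), tolerance = 1e-9)
  }
  ## strong overlap is highly significant
  half <- universe[1:50]
  expect_lt(fisher_intersection(half, half, universe)$p, 1e-10)
  ## degenerate tiny sets do not crash
  r <- fisher_intersection("g1", "g2", c("g1", "g2"))
  expect_true(is.finite(r$p))
  expect_error(fisher_intersection("a", "b", character(0)), "universe")
})

test_that("genotype profile clustering joins identical columns first", {
  set.seed(81)
  m <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  m <- cbind(m, x2 = m[, "x"])      # identical twin of x
  tree <- cluster_genotype_profiles(m)
  expect_s3_class(tree, "phylo")
  hc <- attr(tree, "hclust")
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("x", "x2"))
  expect_equal(hc$height[1], 0)
  ## newick output parses back with the same tips
  nwk <- tempfile(fileext = ".nwk")
  write_genotype_tree(tree, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, colnames(m))
  expect_error(cluster_genotype_profiles(m[, 1, drop = FALSE]), "two genotypes")
})

test_that("category comparison hits the scaling endpoints and matches a rank-sum oracle", {
  genes_a <- paste0("a", 1:40)
  genes_b <- paste0("b", 1:40)
  orth <- data.frame(gene_a = genes_a, gene_b = genes_b)
  cats <- data.frame(gene_id = genes_a,
                     category = rep(c("only_a", "equal", "mixed", "only_b"),
                                    each = 10))
  obs_a <- setNames(rep(c(1, 1, 0, 0), each = 10), genes_a)
  obs_b <- setNames(rep(c(0, 1, 0, 1), each = 10), genes_b)
  set.seed(82)
  pred_a <- setNames(plogis(rnorm(40, obs_a * 2 - 1)), genes_a)
  pred_b <- setNames(plogis(rnorm(40, obs_b * 2 - 1)), genes_b)
  cc <- category_comparison(cats, obs_a, obs_b, pred_a, pred_b, orth)
  expect_equal(cc$scaled_obs_diff[cc$category_id == "only_a"], -1)
  expect_equal(cc$scaled_obs_diff[cc$category_id == "only_b"], 1)
  expect_equal(cc$scaled_obs_diff[cc$category_id == "equal"], 0)
  expect_true(all(cc$fdr >= cc$wilcoxon_p))
  ## independent oracle: normal-approximation rank-sum p and BH correction
  for (i in seq_len(nrow(cc))) {
    ga <- cats$gene_id[cats$category == cc$category_id[i]]
    gb <- orth$gene_b[match(ga, orth$gene_a)]
    w <- suppressWarnings(wilcox.test(pred_a[ga], pred_b[gb], exact = FALSE))
    expect_equal(cc$wilcoxon_p[i], w$p.value, tolerance = 1e-9)
  }
  expect_equal(cc$fdr, p.adjust(cc$wilcoxon_p, "BH"), tolerance = 1e-12)
  ## identical distributions: scaled difference 0, p near 1
  same <- category_comparison(
    data.frame(gene_id = genes_a[1:10], category = "s"),
    obs_a, obs_a, pred_a, pred_a,
    data.frame(gene_a = genes_a[1:10], gene_b = genes_a[1:10]))
  expect_equal(same$scaled_pred_diff, 0)
  expect_gt(same$wilcoxon_p, 0.9)
})
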