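onehot_pwm <- function(seq) {
  m <- encode_seq(seq)
  m[rowSums(m) == 0, ] <- 0.25
  m
}

fake_epm <- function(pwm, name = "epmSynt-S0-p0m01", metacluster = "p0",
                     ranges = list(upstream = NULL, downstream = NULL)) {
  structure(list(name = name, metacluster = metacluster, cwm = pwm,
                 pwm = pwm, n_seqlets = 10L,
                 info_content = motif_properties(pwm)$info_content,
                 consensus = motif_properties(pwm)$consensus,
                 preferred_ranges = ranges, orientation = "fwd",
                 sum_score = sum(pwm)),
            class = "epm")
}

test_that("scan p-values equal exhaustive enumeration for short motifs", {
  set.seed(30)
  for (W in c(3L, 5L, 6L)) {
    pwm <- matrix(runif(W * 4), W, 4)
    pwm <- pwm / rowSums(pwm)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    sm <- pwm_score_matrix(pwm, bg, pseudocount = 0.01)
    dist <- pwm_score_distribution(sm, bg, bin_width = 1e-4)
    ## enumerate all 4^W words on the same score lattice the DP uses
    sm_lat <- round(sm / 1e-4) * 1e-4
    words <- as.matrix(expand.grid(rep(list(1:4), W)))
    scores <- vapply(seq_len(nrow(words)), function(i)
      sum(sm_lat[cbind(seq_len(W), words[i, ])]), 0)
    probs <- vapply(seq_len(nrow(words)), function(i)
      prod(bg[words[i, ]]), 0)
    qs <- sort(scores)[ceiling(c(0.001, 0.25, 0.5, 0.9, 1) * length(scores))]
    for (q in qs) {
      exact <- sum(probs[scores >= q - 1e-9])
      expect_equal(dist$pvalue(q), exact, tolerance = 1e-9)
    }
  }
  ## uniform background, one-hot motif: best-score p-value is (1/4)^W
  pwm <- onehot_pwm("ACGT")
  sm <- pwm_score_matrix(pwm, rep(0.25, 4), pseudocount = 0)
  dist <- pwm_score_distribution(sm, rep(0.25, 4))
  expect_equal(dist$pvalue(sum(sm[pwm == 1])), (1 / 4)^4,
               tolerance = 1e-9)
})

test_that("scanning finds planted words with correct strand and threshold semantics", {
  set.seed(31)
  body <- random_dna(400)
  target <- "ACGTACGTACGT"
  s <- paste0(substr(body, 1, 100), target, substr(body, 101, 300))
  epm <- fake_epm(onehot_pwm(target))
  cfg <- scan_config(sensitivity = 1e-3, background = rep(0.25, 4))
  m <- scan_motifs(list(epm), c(gene1 = s), cfg)
  fwd <- m[m$strand == "+", ]
  expect_true(any(fwd$pos == 100))
  ## strand closure: the reverse-complemented sequence yields the mirror hit
  m2 <- scan_motifs(list(epm), c(gene1 = revcomp(s)), cfg)
  rev_hit <- m2[m2$strand == "-", ]
  expect_true(any(rev_hit$pos == nchar(s) - 100 - nchar(target)))
  ## the sensitivity threshold acts on the exact window p-value; e-values
  ## over the scanned space are reported alongside
  cfg_strict <- scan_config(sensitivity = 1e-6, background = rep(0.25, 4))
  m3 <- scan_motifs(list(epm), c(gene1 = s), cfg_strict)
  expect_true(all(m3$p_value < 1e-6))
  expect_equal(m3$e_value, m3$p_value * (nchar(s) - nrow(epm$pwm) + 1) * 2,
               tolerance = 1e-12)
  ## windows containing N are skipped
  sN <- paste0(substr(s, 1, 100), "N", substr(s, 102, nchar(s)))
  mN <- scan_motifs(list(epm), c(gene1 = sN), cfg)
  expect_false(any(mN$pos == 100 & mN$strand == "+"))
})

test_that("preferred-range flag uses closed intervals and absent ranges", {
  epm <- fake_epm(onehot_pwm("ACGTACGT"),
                  ranges = list(upstream = c(17.5, 32.5), downstream = NULL))
  matches <- data.frame(epm_name = epm$name, gene_id = "g",
                        pos = 0, half = c("upstream", "upstream", "upstream",
                                          "downstream"),
                        offset = c(25, 17.5, 33, 25), strand = "+",
                        score = 1, p_value = 1e-6, e_value = 1e-6)
  fl <- flag_preferred(matches, list(epm))
  expect_equal(fl$within_preferred, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("enrichment reproduces direct odds arithmetic and its sign convention", {
  ## counts 80/100 vs 20/100 with eps = 0 give exactly 4
  epm <- fake_epm(onehot_pwm("ACGTACGT"), metacluster = "p0")
  labels <- data.frame(gene_id = paste0("g", 1:200),
                       klass = rep(c("high", "low"), each = 100))
  hit <- c(paste0("g", 1:80), paste0("g", 101:120))
  matches <- data.frame(epm_name = epm$name, gene_id = hit, pos = 0,
                        half = "upstream", offset = 10, strand = "+",
                        score = 1, p_value = 0, e_value = 0,
                        within_preferred = TRUE)
  r <- epm_enrichment(epm, matches, labels, eps = 0)
  expect_equal(r$enrichment, 4)
  expect_equal(r$a, 80); expect_equal(r$b, 20)
  ## equal fractions give zero
  matches2 <- matches; matches2$gene_id <- c(paste0("g", 1:50), paste0("g", 101:150))
  expect_equal(epm_enrichment(epm, matches2, labels, eps = 0)$enrichment, 0)
  ## lower own-class fraction gives a negative value (p1 sign anchor)
  epm_p1 <- fake_epm(onehot_pwm("ACGTACGT"), name = "epmSynt-S0-p1m01",
                     metacluster = "p1")
  matches3 <- matches; matches3$epm_name <- epm_p1$name
  ## p1 own class is low; hits are mostly in high genes here
  r3 <- epm_enrichment(epm_p1, matches3, labels, eps = 0)
  expect_lt(r3$enrichment, 0)
  ## antisymmetry under swapping class roles (eps = 0)
  expect_equal(r3$enrichment, -r$enrichment)
})

test_that("occurrence chi-square matches the closed-form equal-split statistic", {
  r <- occurrence_chi2(90, 100, 10, 100)
  expect_equal(r$chi2, (90 - 50)^2 / 50 + (10 - 50)^2 / 50)  # = 64
  expect_equal(r$chi2, 64)
  expect_equal(occurrence_chi2(25, 50, 25, 50)$chi2, 0)
  expect_equal(occurrence_chi2(25, 50, 25, 50)$p, 1)
  ## p equals the 1-df chi-square survival function
  set.seed(32)
  for (i in 1:20) {
    a <- rpois(1, 40); b <- rpois(1, 20)
    if (a + b == 0) next
    r <- occurrence_chi2(a, NULL, b, NULL)
    expect_equal(r$p, pchisq(r$chi2, df = 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("reference comparison scores identity and reverse complement at PCC 1", {
  set.seed(33)
  pwm <- matrix(runif(32), 8, 4); pwm <- pwm / rowSums(pwm)
  epm <- fake_epm(pwm)
  refs <- list(self = pwm, rc = epm_otif_rc <- pwm[8:1, 4:1],
               other = matrix(0.25, 8, 4))
  hits <- compare_to_reference(list(epm), refs, n_shuffles = 50, seed = 1)
  expect_equal(hits$pcc[hits$reference_id == "self"], 1, tolerance = 1e-12)
  expect_equal(hits$orientation[hits$reference_id == "rc"], "rev")
  expect_equal(hits$pcc[hits$reference_id == "rc"], 1, tolerance = 1e-12)
  ## significance rule: e-value below 0.05 flags the hit
  expect_true(all(hits$significant == (hits$e_value < 0.05)))
})

test_that("EPM clustering groups a motif with its reverse complement", {
  mk <- function(cons, name) fake_epm(onehot_pwm(cons), name = name)
  epms <- list(mk("CTCTCTCT", "a"), mk("AGAGAGAG", "b"),
               mk("CATCATCA", "c"), mk("GCCGCCGC", "d"),
               mk("TGATGATG", "e"))
  cl <- cluster_epms(epms, cut_height = 0.5)
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])  # RC pair together
  expect_equal(cl$clusters[["c"]], cl$clusters[["e"]])  # RC pair together
  ## three disjoint planted families give exactly three clusters
  expect_equal(length(unique(cl$clusters)), 3L)
})
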