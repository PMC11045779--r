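## build an importance track directly (no model needed): per-position scores
## plus matching hypothetical patch and sequence
fake_track <- function(seq, scores, gene_id = "g1") {
  X <- encode_seq(seq)
  hyp <- matrix(scores, nrow = length(scores), ncol = 4) * 0.25
  actual <- X * scores
  structure(list(gene_id = gene_id, actual = actual, hypothetical = hyp,
                 per_position = scores, seq = seq, delta = sum(scores),
                 f_x = 0.9),
            class = "importance_track")
}

small_cfg <- region_config(promoter_len = 60, utr5_len = 40, utr3_len = 40,
                           terminator_len = 60, spacer_len = 10)

test_that("all-zero tracks yield no seqlets and a spike yields exactly one", {
  L <- small_cfg$total_input_len
  zero <- fake_track(random_dna(L, seed = 70), rep(0, L))
  s <- extract_seqlets(list(zero), small_cfg, window_len = 11)
  expect_equal(nrow(s$df), 0L)

  scores <- rep(0, L); scores[70:77] <- 2        # spike at TSS+9..TSS+16
  spike <- fake_track(random_dna(L, seed = 71), scores)
  s <- extract_seqlets(list(spike), small_cfg, window_len = 11, seed = 2)
  expect_equal(nrow(s$df), 1L)
  ## brute-force scan oracle: the kept window must be the max-|sum| window
  win_sums <- vapply(0:(L - 11), function(p) sum(scores[(p + 1):(p + 11)]), 0)
  expect_equal(s$df$start, which.max(abs(win_sums)) - 1L)
  expect_equal(s$df$total_score, max(win_sums))
  expect_equal(s$df$half, "upstream")
})

test_that("overlapping candidate windows resolve greedily by absolute sum", {
  L <- small_cfg$total_input_len
  scores <- rep(0, L)
  scores[30:40] <- 0.5      # |sum| 5.5
  scores[36:46] <- 0.3      # overlapping, weaker once the first is taken
  scores[30:40] <- 0.5; scores[41:46] <- 0.3
  tr <- fake_track(random_dna(L, seed = 72), scores)
  s <- extract_seqlets(list(tr), small_cfg, window_len = 11, seed = 3)
  ## no two retained windows overlap
  if (nrow(s$df) > 1) {
    st <- sort(s$df$start)
    expect_true(all(diff(st) >= 11))
  }
  ## the strongest window is always retained
  win_sums <- vapply(0:(L - 11), function(p) sum(scores[(p + 1):(p + 11)]), 0)
  expect_true((which.max(abs(win_sums)) - 1L) %in% s$df$start)
})

test_that("metacluster split is by sign with zeros discarded", {
  L <- small_cfg$total_input_len
  pos <- rep(0, L); pos[20:30] <- 1
  neg <- rep(0, L); neg[120:130] <- -1
  trks <- list(fake_track(random_dna(L, seed = 73), pos, "gpos"),
               fake_track(random_dna(L, seed = 74), neg, "gneg"))
  s <- extract_seqlets(trks, small_cfg, window_len = 11, seed = 4)
  mc <- split_metaclusters(s)
  expect_true(all(mc$p0$df$total_score > 0))
  expect_true(all(mc$p1$df$total_score < 0))
  expect_true(all(mc$p0$df$gene_id == "gpos"))
  expect_equal(nrow(mc$p0$df) + nrow(mc$p1$df), nrow(s$df))
})

test_that("identical seqlets collapse to one cluster with a 0/1 PWM", {
  W <- 11L
  patch <- matrix(0, W, 4); patch[cbind(1:W, rep(1:4, length.out = W))] <- 0.5
  seq <- paste(c("A", "C", "G", "T")[rep(1:4, length.out = W)], collapse = "")
  sl <- structure(list(
    df = data.frame(gene_id = paste0("g", 1:12), start = 0L, end = W,
                    total_score = 5, half = "upstream", offset = 10,
                    stringsAsFactors = FALSE),
    patches = rep(list(patch), 12), seqs = rep(seq, 12),
    window_len = W, cfg = small_cfg), class = "seqlet_set")
  epms <- cluster_and_aggregate(sl, "p0", min_seqlets = 10)
  expect_equal(length(epms), 1L)
  expect_equal(epms[[1]]$n_seqlets, 12L)
  expect_equal(epms[[1]]$cwm, patch, ignore_attr = TRUE)
  expect_true(all(epms[[1]]$pwm %in% c(0, 1)))
  expect_equal(motif_properties(epms[[1]]$pwm)$consensus, seq)
})

test_that("a seqlet and its reverse complement join one cluster", {
  W <- 11L
  set.seed(75)
  patch <- matrix(rnorm(W * 4, 0.3, 0.05), W, 4)
  seq <- random_dna(W)
  rc_patch <- patch[W:1, 4:1]
  sl <- structure(list(
    df = data.frame(gene_id = paste0("g", 1:20), start = 0L, end = W,
                    total_score = 5, half = "upstream", offset = 10,
                    stringsAsFactors = FALSE),
    patches = c(rep(list(patch), 10), rep(list(rc_patch), 10)),
    seqs = c(rep(seq, 10), rep(revcomp(seq), 10)),
    window_len = W, cfg = small_cfg), class = "seqlet_set")
  epms <- cluster_and_aggregate(sl, "p0", min_seqlets = 10)
  expect_equal(length(epms), 1L)
  expect_equal(epms[[1]]$n_seqlets, 20L)
})

test_that("two disjoint planted patterns give two clusters matching the patterns", {
  W <- 12L
  mk_sl <- function(seq, score, n, ids) {
    patch <- encode_seq(seq) * score
    list(df = data.frame(gene_id = ids, start = 0L, end = W,
                         total_score = score * W, half = "upstream",
                         offset = 10, stringsAsFactors = FALSE),
         patches = rep(list(patch), n), seqs = rep(seq, n))
  }
  a <- mk_sl("CTCTCTCTCTCT", 0.5, 15, paste0("a", 1:15))
  b <- mk_sl("CATCATCATCAT", 0.4, 15, paste0("b", 1:15))
  sl <- structure(list(df = rbind(a$df, b$df),
                       patches = c(a$patches, b$patches),
                       seqs = c(a$seqs, b$seqs), window_len = W,
                       cfg = small_cfg), class = "seqlet_set")
  epms <- cluster_and_aggregate(sl, "p0", min_seqlets = 10)
  expect_equal(length(epms), 2L)
  pwm_cor <- function(epm, seq) cor(as.numeric(epm$pwm), as.numeric(encode_seq(seq)))
  best_a <- max(vapply(epms, pwm_cor, 0, seq = "CTCTCTCTCTCT"))
  best_b <- max(vapply(epms, pwm_cor, 0, seq = "CATCATCATCAT"))
  expect_gte(best_a, 0.95)
  expect_gte(best_b, 0.95)
})

test_that("positional preference follows the quartile-and-tenth rule", {
  expect_equal(epmotif:::positional_preference_ranges(
    c(10, 20, 30, 40), rep("upstream", 4))$upstream, c(17.5, 32.5))
  ## 5 of 100 seqlets upstream: upstream range absent
  halves <- c(rep("upstream", 5), rep("downstream", 95))
  offs <- c(1:5, 101:195)
  pr <- epmotif:::positional_preference_ranges(offs, halves)
  expect_null(pr$upstream)
  expect_false(is.null(pr$downstream))
  ## degenerate: all offsets equal
  expect_equal(epmotif:::positional_preference_ranges(
    rep(7, 20), rep("downstream", 20))$downstream, c(7, 7))
})

test_that("information content and consensus behave at the extremes", {
  one_hot <- encode_seq("ACGT")
  p <- motif_properties(one_hot)
  expect_equal(p$info_content, 8)            # 2 bits x 4 positions
  expect_equal(p$consensus, "ACGT")
  unif <- matrix(0.25, 3, 4)
  p2 <- motif_properties(unif)
  expect_equal(p2$info_content, 0)
  expect_equal(p2$consensus, "NNN")
  r <- matrix(c(0.5, 0, 0.5, 0), 1, 4)
  expect_equal(motif_properties(r)$consensus, "R")
  expect_error(motif_properties(matrix(c(0.5, 0.2, 0.1, 0.1), 1, 4)), "sum")
})

test_that("EPM names round-trip through both dialects", {
  nm <- name_epm("Arth", "S", 0, 19, "p0", 6)
  expect_equal(nm, "epmArth-S019-p0m06")
  p <- parse_epm_name(nm)
  expect_equal(p$species_code, "Arth")
  expect_equal(p$run_idx, 19L)
  expect_equal(p$motif_idx, 6L)
  expect_false(p$revcomp)
  ## short dialect without a run index
  nm2 <- name_epm("Soly", "M", 0, NULL, "p0", 2)
  expect_equal(nm2, "epmSoly-M0-p0m02")
  p2 <- parse_epm_name(nm2)
  expect_null(p2$run_idx)
  ## reverse-complement suffix
  nm3 <- name_epm("Zema", "S", 1, 3, "p1", 12, revcomp = TRUE)
  expect_true(parse_epm_name(nm3)$revcomp)
  ## full round trip over random fields
  set.seed(76)
  for (i in 1:20) {
    args <- list(species_code = paste(sample(LETTERS, 4, TRUE), collapse = ""),
                 model_type = sample(c("S", "M"), 1),
                 condition = sample(0:9, 1),
                 run_idx = if (runif(1) < 0.5) sample(0:99, 1) else NULL,
                 metacluster = sample(c("p0", "p1"), 1),
                 motif_idx = sample(1:99, 1),
                 revcomp = runif(1) < 0.5)
    p <- parse_epm_name(do.call(name_epm, args))
    expect_equal(p[names(args)], args)
  }
  expect_error(parse_epm_name("epmArth_S019"), "malformed")
})

test_that("reverse-complement EPMs mirror matrices and link names", {
  set.seed(77)
  pwm <- matrix(runif(32), 8, 4); pwm <- pwm / rowSums(pwm)
  e <- structure(list(name = "epmSynt-S0-p0m01", metacluster = "p0",
                      cwm = pwm * 0.1, pwm = pwm, n_seqlets = 12L,
                      info_content = 1, consensus = motif_properties(pwm)$consensus,
                      preferred_ranges = list(upstream = c(1, 2),
                                              downstream = NULL),
                      orientation = "fwd", sum_score = sum(pwm) * 0.1),
                 class = "epm")
  r <- revcomp_epm(e)
  expect_equal(r$name, "epmSynt-S0-p0m01R")
  expect_equal(r$pwm, e$pwm[8:1, 4:1], ignore_attr = TRUE)
  expect_equal(r$consensus, revcomp(e$consensus))
  expect_equal(revcomp_epm(r)$pwm, e$pwm, ignore_attr = TRUE)
  expect_equal(revcomp_epm(r)$name, e$name)
})
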