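make_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(V1 = r[[1]], V2 = r[[2]], V3 = 99.0, V4 = 100L, V5 = 0L,
               V6 = 0L, V7 = 1L, V8 = 100L, V9 = 1L, V10 = 100L,
               V11 = as.numeric(r[[3]]), V12 = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
  df
}

test_that("homology loading symmetrises pairs and drops self hits", {
  h <- load_homology(make_hits(list("g1", "g2", 1e-5, 60),
                               list("g3", "g3", 1e-9, 200)))
  expect_equal(nrow(h), 2L)          # self hit dropped, pair stored both ways
  expect_setequal(paste(h$query_gene, h$subject_gene),
                  c("g1 g2", "g2 g1"))
  ## k distinct non-self pairs give 2k directed entries
  set.seed(20)
  pairs <- t(combn(paste0("g", 1:8), 2))[sample(28, 12), ]
  hits <- do.call(make_hits, lapply(seq_len(12), function(i)
    list(pairs[i, 1], pairs[i, 2], 1e-6, 80)))
  expect_equal(nrow(load_homology(hits)), 24L)
})

test_that("homology criterion is e-value < 0.001 AND bit score > 50, strict", {
  expect_true(is_homologous(1e-5, 60))
  expect_false(is_homologous(0.1, 200))
  expect_false(is_homologous(1e-9, 50))
  expect_false(is_homologous(0.001, 60))
})

## a small labelled two-chromosome toy set with one homologous pair crossing
## the fold boundary
toy_fold_data <- function() {
  ann <- data.frame(gene_id = paste0("g", 1:20),
                    chrom = rep(c("chr1", "chr2"), each = 10),
                    stringsAsFactors = FALSE)
  labels <- data.frame(gene_id = ann$gene_id,
                       binary = rep(c(0L, 1L), 10),
                       stringsAsFactors = FALSE)
  labels$klass <- ifelse(labels$binary == 1L, "high", "low")
  list(ann = ann, labels = labels)
}

test_that("fold construction drops homologous validation genes under SSR, keeps them under SSRU", {
  d <- toy_fold_data()
  hom <- load_homology(make_hits(list("g1", "g11", 1e-5, 60),   # qualifying
                                 list("g2", "g12", 0.5, 60)))   # not qualifying
  ssr <- make_folds(d$labels, d$ann, hom, "SSR", seed = 1)
  ssru <- make_folds(d$labels, d$ann, hom, "SSRU", seed = 1)
  f1 <- ssr[[match("SSR-chr1", vapply(ssr, `[[`, "", "fold_id"))]]
  expect_false("g1" %in% f1$val_ids)     # has qualifying homolog g11 in train
  expect_true("g2" %in% f1$val_ids)      # hit below threshold is kept
  f1u <- ssru[[1]]
  expect_true("g1" %in% f1u$val_ids)
  ## invariant: no SSR validation gene has a qualifying homolog in training
  qual <- hom[is_homologous(hom$e_value, hom$bit_score), ]
  for (f in ssr) {
    crossing <- qual$query_gene %in% f$val_ids &
      qual$subject_gene %in% f$train_ids
    expect_false(any(crossing))
  }
})

test_that("training sets are exactly class-balanced and seed-reproducible", {
  d <- toy_fold_data()
  ## unbalance the labels: 14 high, 6 low
  d$labels$binary <- c(rep(1L, 14), rep(0L, 6))[order(order(d$labels$gene_id))]
  d$labels$binary <- c(rep(1L, 14), rep(0L, 6))
  folds <- make_folds(d$labels, d$ann, NULL, "SSR", seed = 5)
  for (f in folds) {
    y <- d$labels$binary[match(f$train_ids, d$labels$gene_id)]
    expect_equal(sum(y == 0L), sum(y == 1L))
  }
  again <- make_folds(d$labels, d$ann, NULL, "SSR", seed = 5)
  expect_identical(lapply(folds, `[[`, "train_ids"),
                   lapply(again, `[[`, "train_ids"))
  other <- make_folds(d$labels, d$ann, NULL, "SSR", seed = 6)
  expect_false(identical(lapply(folds, `[[`, "train_ids"),
                         lapply(other, `[[`, "train_ids")))
})

test_that("validation sets partition the binary genes across folds", {
  d <- toy_fold_data()
  folds <- make_folds(d$labels, d$ann, NULL, "SSR", seed = 1)
  vals <- lapply(folds, `[[`, "val_ids")
  expect_equal(sort(unlist(vals)), sort(d$labels$gene_id))
  expect_equal(length(unlist(vals)), length(unique(unlist(vals))))
})

test_that("MSR folds hold out one species at a time", {
  d <- toy_fold_data()
  d$ann$species <- rep(c("spA", "spB"), each = 10)
  folds <- make_folds(d$labels, d$ann, NULL, "MSR", seed = 1)
  expect_equal(length(folds), 2L)
  f <- folds[[1]]
  expect_true(all(d$ann$species[match(f$val_ids, d$ann$gene_id)] == "spA"))
  expect_true(all(d$ann$species[match(f$train_ids, d$ann$gene_id)] == "spB"))
  expect_error(make_folds(d$labels, d$ann[, 1:2], NULL, "MSR"), "species")
})

test_that("sequence shuffling preserves composition and N positions, reproducibly", {
  set.seed(21)
  seqs <- c(a = paste0(random_dna(40), strrep("N", 10), random_dna(40)),
            b = random_dna(90))
  s1 <- shuffle_sequences(seqs, seed = 3)
  s2 <- shuffle_sequences(seqs, seed = 3)
  s3 <- shuffle_sequences(seqs, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  for (i in seq_along(seqs)) {
    expect_identical(sort(strsplit(s1[i], "")[[1]]),
                     sort(strsplit(seqs[i], "")[[1]]))
  }
  expect_identical(unname(substr(s1["a"], 41, 50)), strrep("N", 10))
  ## long random sequences essentially never map to themselves
  long <- vapply(1:20, function(i) random_dna(3020), "")
  sh <- shuffle_sequences(long, seed = 9)
  expect_true(all(sh != long))
  ## dinucleotide mode preserves doublet counts
  x <- random_dna(200)
  dn <- unname(shuffle_sequences(c(x), seed = 1, mode = "dinuc"))
  count2 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_equal(count2(dn), count2(x))
})
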