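## Shared in-code fixtures; everything is generated at test time.

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

## tiny local stand-in for withr::with_seed (withr not a test dependency)
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  code
}

## small trained model on a planted-motif toy problem, cached per session
toy_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(401)
    L <- 120
    mk <- function(has) {
      s <- random_dna(L)
      if (has) substr(s, 40, 47) <- "CACGTGAC"
      s
    }
    y <- rep(0:1, 200)
    xs <- vapply(y == 1, mk, "")
    yv <- rep(0:1, 40)
    xv <- vapply(yv == 1, mk, "")
    cfg <- cnn_config(filters_per_block = c(8L, 8L, 8L),
                      pool_size = c(4L, 4L, 0L), fc_sizes = c(8L, 4L),
                      batch_size = 4L, max_epochs = 60L, seed = 11L)
    cache <<- cre_cnn(xs, y, xv, yv, cfg)
    cache
  }
})

## one-row gene annotation helper
gene_row <- function(id = "g1", chrom = "chr1", start, end, strand = "+") {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}
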