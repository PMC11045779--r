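test_that("FASTA reading uppercases and maps ambiguity codes to N", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "acgt", ">chr2 some description", "ACGRYN"), fa)
  expect_warning(g <- read_genome(fa), "ambiguity")
  expect_identical(g[["chr1"]], "ACGT")
  expect_identical(g[["chr2"]], "ACGNNN")
  expect_identical(names(g), c("chr1", "chr2"))

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), dup)
  expect_error(read_genome(dup), "duplicate")
})

test_that("GFF3 reading keeps gene rows only and demands strand", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=t1",
               "chr2\tsrc\tgene\t51\t80\t.\t-\t.\tID=g2"), gff)
  ann <- read_annotation(gff)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$start[ann$gene_id == "g1"], 101L)
  expect_equal(ann$end[ann$gene_id == "g1"], 200L)
  expect_equal(ann$strand[ann$gene_id == "g2"], "-")

  nostrand <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t.\t.\tID=g1"), nostrand)
  expect_error(read_annotation(nostrand), "strand")
})

test_that("default extraction yields two 1.5 kb regions fused over a 20 nt N spacer", {
  cfg <- region_config()
  expect_equal(cfg$total_input_len, 3020L)
  chrom <- random_dna(10000, seed = 1)
  fl <- extract_flanks(gene_row(start = 4000, end = 6000), chrom, cfg)
  expect_equal(nchar(fl$upstream), 1500L)
  expect_equal(nchar(fl$downstream), 1500L)
  expect_equal(nchar(fl$fused), 3020L)
  expect_identical(substr(fl$fused, 1501, 1520), strrep("N", 20))
  ## anchored at the gene start/end coordinates
  expect_identical(fl$upstream, substr(chrom, 3000, 4499))
  expect_identical(fl$downstream, substr(chrom, 5501, 7000))
  expect_false(fl$overlapping)
})

test_that("chromosome-edge genes are N-padded, not dropped", {
  cfg <- region_config()
  chrom <- random_dna(4000, seed = 2)
  fl <- extract_flanks(gene_row(start = 1, end = 2000), chrom, cfg)
  expect_equal(nchar(fl$upstream), 1500L)
  expect_identical(substr(fl$upstream, 1, 1000), strrep("N", 1000))
  expect_identical(substr(fl$upstream, 1001, 1500), substr(chrom, 1, 500))
})

test_that("minus-strand extraction equals the reverse complement of the mirrored windows", {
  cfg <- region_config(promoter_len = 30, utr5_len = 10, utr3_len = 10,
                       terminator_len = 30, spacer_len = 5)
  chrom <- random_dna(500, seed = 3)
  g <- gene_row(start = 200, end = 320, strand = "-")
  fl <- extract_flanks(g, chrom, cfg)
  ## independent oracle: raw windows + an independent reverse complement
  rc_oracle <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  expect_identical(fl$upstream, rc_oracle(substr(chrom, 320 - 10 + 1, 320 + 30)))
  expect_identical(fl$downstream, rc_oracle(substr(chrom, 200 - 30, 200 + 10 - 1)))
})

test_that("strand symmetry: extraction commutes with reverse-complementing the genome", {
  cfg <- region_config(promoter_len = 20, utr5_len = 8, utr3_len = 8,
                       terminator_len = 20, spacer_len = 4)
  for (seed in 1:5) {
    n <- 300
    chrom <- random_dna(n, seed = seed)
    s <- 100 + seed; e <- 180 + seed
    plus <- extract_flanks(gene_row(start = s, end = e, strand = "+"), chrom, cfg)
    ## the same gene on the reverse-complemented chromosome, coordinates mirrored
    rc_chrom <- revcomp(chrom)
    minus <- extract_flanks(gene_row(start = n - e + 1, end = n - s + 1,
                                     strand = "-"), rc_chrom, cfg)
    expect_identical(minus$fused, plus$fused)
  }
})

test_that("one-hot encoding round-trips and zeroes the spacer block", {
  expect_equal(encode_seq("ACGT"),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1),
                      4, 4, byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(unname(encode_seq("N")[1, ]), rep(0, 4))
  expect_error(encode_seq("ACGU"), "unexpected")

  cfg <- region_config()
  chrom <- random_dna(10000, seed = 4)
  fl <- extract_flanks(gene_row(start = 4000, end = 6000), chrom, cfg)
  m <- encode_seq(fl$fused)
  zero_rows <- which(rowSums(m) == 0)
  expect_identical(zero_rows, 1501:1520)         # exactly the spacer
  expect_true(all(rowSums(m) %in% c(0, 1)))
  expect_identical(decode_onehot(m), fl$fused)   # full round trip

  ## length conservation across genes
  starts <- c(2000, 4000, 7000)
  lens <- vapply(starts, function(s)
    nchar(extract_flanks(gene_row(start = s, end = s + 500), chrom, cfg)$fused), 0)
  expect_true(all(lens == cfg$total_input_len))
})

test_that("anchor offsets are TSS/TTS-relative and NA in the spacer", {
  cfg <- region_config()
  an <- anchor_offset(c(0, 999, 1000, 1510, 1520, 2019, 2020, 3019), cfg)
  expect_equal(an$offset, c(-1000, -1, 0, NA, -500, -1, 0, 999))
  expect_equal(an$half[4], NA_character_)
  expect_equal(an$half[1], "upstream")
  expect_equal(an$half[8], "downstream")
})
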