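#' @keywords internal
"_PACKAGE"

#' @useDynLib epmotif, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile var sd runif rnorm rbinom median predict
#'   chisq.test fisher.test wilcox.test p.adjust pchisq hclust cutree dist
#'   as.dist cor complete.cases setNames
#' @importFrom utils head tail read.delim write.table modifyList
NULL

BASES <- c("A", "C", "G", "T")

## IUPAC nucleotide codes mapped to the base sets they stand for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## inverse lookup: sorted base set -> code
.iupac_code_of <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

iupac_code <- function(bases) {
  code <- .iupac_code_of[[paste(sort(unique(bases)), collapse = "")]]
  if (is.null(code)) stop("no IUPAC code for base set: ", paste(bases, collapse = ","))
  code
}

#' Reverse complement of a DNA string
#'
#' Accepts IUPAC ambiguity codes; `N` maps to `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

## evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a stable sub-seed from an experiment seed
#'
#' Hashes a purpose tag together with the experiment seed so that every
#' stage (initialisation, folds, shuffles, nulls, bootstraps) gets its own
#' reproducible stream. The result is always below 2^31.
#'
#' @param seed integer experiment seed.
#' @param tag character tag naming the purpose.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

## one-hot matrix (L x 4) -> integer index vector (1..4, NA for all-zero rows)
onehot_to_index <- function(mat) {
  idx <- max.col(mat, ties.method = "first")
  idx[rowSums(mat) == 0] <- NA_integer_
  idx
}

## DNA string -> integer codes 0..3 (A,C,G,T), 4 for N — compact model input
seq_to_code <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], BASES)
  m[is.na(m)] <- 5L
  as.integer(m - 1L)
}

code_to_seq <- function(code) {
  paste(c(BASES, "N")[code + 1L], collapse = "")
}
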