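#' @importFrom stats median rpois rbinom runif rlnorm rnorm setNames
#' @importFrom utils head tail
#' @importFrom data.table := .N .I
NULL

## data.table non-standard evaluation inside this package
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

## width of the intersection of two 0-based half-open intervals
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## gap between two non-overlapping 0-based half-open intervals (0 = abutting)
interval_gap <- function(s1, e1, s2, e2) {
  ifelse(overlap_width(s1, e1, s2, e2) > 0, 0L, pmax(s2 - e1, s1 - e2))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## random DNA of a given length and GC content, as one character string
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

utils::globalVariables(c(
  ".", ".N", ".I", "read_id", "replicon_id", "start0", "strand", "nm",
  "best", "n_best", "u", "kmer", "pos0", "weight", "w", "pos", "J"
))
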