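#' @importFrom methods is
#' @importFrom stats rmultinom runif sd setNames t.test chisq.test cor rlnorm
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
# All stochastic steps in the package funnel through this so that one seed
# reproduces a whole run byte-for-byte.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of DNA sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' All sequences in the package live in the DNA alphabet; RNA input (U) is
#' converted to T at I/O boundaries.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# DNA/RNA alphabet normalization: U -> T, uppercase.
dna_upper <- function(x) chartr("uU", "TT", toupper(x))

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# vectorized: can DNA bases a and b form a pair? Watson-Crick always;
# G.T (the DNA image of the G.U wobble) optionally.
bases_pair <- function(a, b, allow_gu = FALSE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (!allow_gu) return(wc)
  wc | (a == "G" & b == "T") | (a == "T" & b == "G")
}

# random DNA string(s); relies on the caller-managed RNG state
random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# sample one index per row from ragged candidate counts: for read i with
# n[i] equally good placements, pick one uniformly ("mapped randomly").
sample_per_element <- function(n) {
  stopifnot(all(n >= 1L))
  pmin(1L + as.integer(floor(runif(length(n)) * n)), as.integer(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
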