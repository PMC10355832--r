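# Internal end-to-end read matcher.
#
# The pipeline needs every placement of a 18-29 nt read on a reference set,
# full read length, substitutions only.  Exact matching batches reads of
# equal width through Biostrings::PDict/matchPDict (fast path used for the
# hierarchical classifier); mismatch-tolerant matching ("80% similarity")
# scans each unique sequence with vmatchPattern.  Not a general aligner:
# no indels, no clipping, desk-scale references.

#' Find all end-to-end placements of reads on a reference
#'
#' Reports every placement of each full-length read on the reference
#' sequences with identity at or above `min_similarity` (fraction of
#' matching bases over the read length; substitutions only, no indels).
#' Both strands are searched unless `strand_mode` restricts the scan.
#'
#' @param reads character vector of read sequences (DNA alphabet).
#' @param reference named [Biostrings::DNAStringSet] of reference sequences.
#' @param min_similarity minimum identity fraction in (0, 1]; `1` requests
#'   exact matching.
#' @param strand_mode `"both"`, `"forward"` or `"reverse"`.
#' @return data.frame with columns `read` (index into `reads`), `ref`
#'   (reference name), `start`, `end` (1-based closed, on the forward
#'   strand of the reference), `strand`, `identity`.
#' @export
match_reads <- function(reads, reference, min_similarity = 1,
                        strand_mode = c("both", "forward", "reverse")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(min_similarity > 0, min_similarity <= 1)
  if (length(reference) == 0L) stop("empty reference")
  if (is.null(names(reference))) names(reference) <- seq_along(reference)
  reads <- dna_upper(reads)
  strands <- switch(strand_mode, both = c("+", "-"), forward = "+", reverse = "-")
  if (min_similarity == 1) {
    hits <- exact_hits(reads, reference, strands)
    hits$identity <- rep(1, nrow(hits))
    return(hits)
  }
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- reads[i]
    len <- nchar(r)
    max_mm <- floor(len * (1 - min_similarity) + 1e-9)
    rows <- list()
    for (s in strands) {
      pat <- if (s == "+") r else revcomp(r)
      m <- Biostrings::vmatchPattern(pat, reference, max.mismatch = max_mm,
                                     with.indels = FALSE, fixed = TRUE)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      ir <- unlist(m, use.names = FALSE)
      st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
      refn <- rep(names(reference), cnt)
      keep <- st >= 1L & en <= rep(Biostrings::width(reference), cnt)
      if (!any(keep)) next
      st <- st[keep]; en <- en[keep]; refn <- refn[keep]
      ident <- vapply(seq_along(st), function(j) {
        sub <- as.character(Biostrings::subseq(reference[[refn[j]]], st[j], en[j]))
        mean(strsplit(sub, "")[[1]] == strsplit(pat, "")[[1]])
      }, numeric(1))
      ok <- ident >= min_similarity - 1e-9
      if (!any(ok)) next
      rows[[s]] <- data.frame(read = i, ref = refn[ok], start = st[ok],
                              end = en[ok], strand = s, identity = ident[ok],
                              stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read = integer(0), ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$read, -res$identity, res$ref, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exact placements via a single variable-width PDict (trusted band over the
# shared prefix); returns the same data.frame layout as match_reads
# (without identity)
exact_hits <- function(reads, reference, strands = c("+", "-")) {
  widths <- nchar(reads)
  ref_w <- Biostrings::width(reference)
  minw <- min(widths)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads),
                          tb.start = 1L, tb.end = minw)
  acc <- list(); k <- 0L
  for (j in seq_along(reference)) {
    if (ref_w[j] < minw) next
    for (s in strands) {
      subj <- if (s == "+") reference[[j]]
        else Biostrings::reverseComplement(reference[[j]])
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      ir <- unlist(m, use.names = FALSE)
      st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
      idx <- rep(seq_along(reads), cnt)
      # trusted-band matching can report placements running off the subject
      ok <- st >= 1L & en <= ref_w[j]
      st <- st[ok]; en <- en[ok]; idx <- idx[ok]
      if (!length(st)) next
      if (s == "-") {
        L <- ref_w[j]
        tmp <- st
        st <- L - en + 1L
        en <- L - tmp + 1L
      }
      k <- k + 1L
      acc[[k]] <- data.frame(read = idx,
                             ref = names(reference)[j],
                             start = st, end = en, strand = s,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, acc)
  if (is.null(res))
    res <- data.frame(read = integer(0), ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  res <- res[order(res$read, res$ref, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
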