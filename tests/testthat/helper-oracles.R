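# Independent brute-force oracles kept deliberately naive; they never share
# code with the implementation paths they check.

# all end-to-end placements of `read` on `refs` by sliding-window character
# comparison (substitutions only)
oracle_match <- function(read, refs, min_similarity = 1,
                         strands = c("+", "-")) {
  out <- list()
  rchars <- strsplit(read, "")[[1]]
  L <- length(rchars)
  for (rn in names(refs)) {
    refstr <- as.character(refs[[rn]])
    n <- nchar(refstr)
    if (n < L) next
    for (s in strands) {
      pat <- if (s == "+") rchars else
        rev(chartr("ACGT", "TGCA", rchars))
      for (st in seq_len(n - L + 1L)) {
        win <- strsplit(substr(refstr, st, st + L - 1L), "")[[1]]
        ident <- mean(win == pat)
        if (ident >= min_similarity - 1e-9)
          out[[length(out) + 1L]] <- data.frame(
            ref = rn, start = st, end = st + L - 1L, strand = s,
            identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(ref = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0))
}

# single-base complementarity with optional G.U wobble
oracle_pair_ok <- function(a, b, allow_gu) {
  wc <- list(A = "T", C = "G", G = "C", T = "A")
  if (identical(b, wc[[a]])) return(TRUE)
  allow_gu && ((a == "G" && b == "T") || (a == "T" && b == "G"))
}

# brute-force all-pairs 10-nt 5'-to-5' overlap comparator over read groups
oracle_overlap_pairs <- function(triggers, responders,
                                 min_responder_reads = 10, allow_gu = FALSE) {
  hits <- list()
  tps <- strsplit(substr(triggers$sequence, 1, 10), "")
  rps <- strsplit(substr(responders$sequence, 1, 10), "")
  for (i in seq_len(nrow(triggers))) {
    tp <- tps[[i]]
    for (j in seq_len(nrow(responders))) {
      rp <- rps[[j]]
      ok <- TRUE
      for (k in 1:10) {
        if (!oracle_pair_ok(tp[k], rp[11 - k], allow_gu)) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1L]] <-
          data.frame(trigger_seq = triggers$sequence[i],
                     responder_seq = responders$sequence[j],
                     responder_count = responders$count[j],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(trigger_seq = character(0),
                      responder_seq = character(0)))
  df <- do.call(rbind, hits)
  per_trigger <- tapply(df$responder_count, df$trigger_seq, sum)
  df <- df[per_trigger[df$trigger_seq] > min_responder_reads, , drop = FALSE]
  df[order(df$trigger_seq, df$responder_seq), c("trigger_seq", "responder_seq")]
}

# brute-force nearest-neighbor / all-pairs head-to-tail distances
oracle_phasing <- function(start5, end3, range = -20:50,
                           mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  ds <- integer(0)
  for (i in seq_along(start5)) {
    downstream <- which(start5 > start5[i])
    if (!length(downstream)) next
    if (mode == "nearest") {
      j <- downstream[which.min(start5[downstream])]
      ds <- c(ds, start5[j] - end3[i])
    } else {
      ds <- c(ds, start5[downstream] - end3[i])
    }
  }
  ds <- ds[ds >= min(range) & ds <= max(range)]
  tab <- table(factor(ds, levels = range))
  stats::setNames(as.integer(tab), range)
}

# pooled-variance two-sample two-tailed t-test from the textbook formula
oracle_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

random_groups <- function(n, len_range = c(20, 28), count_range = c(1, 40),
                          set = "x") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  seqs <- unique(seqs)
  data.frame(sequence = seqs,
             count = sample(seq(count_range[1], count_range[2]),
                            length(seqs), replace = TRUE),
             set = set, stringsAsFactors = FALSE)
}
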