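#' Group identical reads
#'
#' Collapses a read set to one group per distinct sequence with its read
#' count; the unit of overlap pairing.
#'
#' @param reads character vector of read sequences (repeats allowed), or a
#'   data.frame already holding `sequence` and `count`.
#' @param set label recorded on the groups.
#' @return data.frame with `sequence`, `count`, `set`.
#' @export
group_reads <- function(reads, set = "reads") {
  if (is.data.frame(reads)) {
    stopifnot(all(c("sequence", "count") %in% names(reads)),
              !anyDuplicated(reads$sequence))
    out <- data.frame(sequence = dna_upper(reads$sequence),
                      count = as.integer(reads$count),
                      set = set, stringsAsFactors = FALSE)
    return(out)
  }
  if (length(reads) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      set = character(0), stringsAsFactors = FALSE))
  tab <- table(dna_upper(reads))
  data.frame(sequence = names(tab), count = as.integer(tab), set = set,
             stringsAsFactors = FALSE, row.names = NULL)
}

# do trigger/responder prefixes form a full 10-nt antiparallel duplex?
# trigger nt i pairs responder nt 11-i.  Vectorized over pairs of sequences.
overlap10_ok <- function(trig, resp, allow_gu = FALSE) {
  ok <- rep(TRUE, length(trig))
  wobble_free <- rep(TRUE, length(trig))
  for (i in 1:10) {
    a <- substr(trig, i, i)
    b <- substr(resp, 11L - i, 11L - i)
    wc <- bases_pair(a, b, allow_gu = FALSE)
    ok <- ok & bases_pair(a, b, allow_gu = allow_gu)
    wobble_free <- wobble_free & wc
  }
  list(ok = ok, wobble_free = wobble_free)
}

#' Find 5'-to-5' 10-nt complementary overlap pairs
#'
#' Reports trigger/responder group pairs whose first ten nucleotides form a
#' perfect antiparallel duplex — `responder[1:10] == revcomp(trigger[1:10])`
#' — the signature left by ping-pong-style cleavage, in which target slicing
#' opposite trigger nt 10/11 makes trigger and responder 5' ends overlap by
#' exactly 10 nt. G·U wobble pairs are disallowed unless `allow_gu`. A
#' trigger is reported only when the summed read count of its paired
#' responder groups strictly exceeds `min_responder_reads`.
#'
#' Wobble-free search is indexed by 10-mer prefix; the wobble-tolerant mode
#' checks all trigger-responder prefix combinations base by base.
#'
#' @param triggers,responders [group_reads()] data.frames; sequences must be
#'   at least 10 nt (shorter groups are skipped with a warning).
#' @param min_responder_reads strict threshold on the per-trigger sum of
#'   paired responder reads.
#' @param allow_gu accept G·U (DNA G·T) pairs.
#' @return data.frame of `OverlapPair` rows: `trigger_seq`, `responder_seq`,
#'   `trigger_count`, `responder_count`, `overlap_len` (10), `wobble_free`,
#'   `trigger_responder_reads` (the per-trigger sum used for the filter).
#' @export
find_overlap_pairs <- function(triggers, responders, min_responder_reads = 10,
                               allow_gu = FALSE) {
  short_t <- nchar(triggers$sequence) < 10L
  short_r <- nchar(responders$sequence) < 10L
  if (any(short_t) || any(short_r))
    warning(sum(short_t) + sum(short_r), " group(s) shorter than 10 nt skipped")
  triggers <- triggers[!short_t, , drop = FALSE]
  responders <- responders[!short_r, , drop = FALSE]
  empty <- data.frame(trigger_seq = character(0), responder_seq = character(0),
                      trigger_count = integer(0), responder_count = integer(0),
                      overlap_len = integer(0), wobble_free = logical(0),
                      trigger_responder_reads = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(triggers) == 0L || nrow(responders) == 0L) return(empty)
  tp <- substr(triggers$sequence, 1L, 10L)
  rp <- substr(responders$sequence, 1L, 10L)
  if (!allow_gu) {
    want <- revcomp(tp)
    idx <- split(seq_along(rp), rp)
    pair_list <- lapply(seq_along(want), function(i) {
      hits <- idx[[want[i]]]
      if (is.null(hits)) return(NULL)
      data.frame(t = i, r = hits)
    })
    pairs <- do.call(rbind, pair_list)
    if (is.null(pairs)) return(empty)
    wobble_free <- rep(TRUE, nrow(pairs))
  } else {
    grid <- expand.grid(t = seq_len(nrow(triggers)),
                        r = seq_len(nrow(responders)))
    chk <- overlap10_ok(tp[grid$t], rp[grid$r], allow_gu = TRUE)
    pairs <- grid[chk$ok, , drop = FALSE]
    if (nrow(pairs) == 0L) return(empty)
    wobble_free <- chk$wobble_free[chk$ok]
  }
  out <- data.frame(
    trigger_seq = triggers$sequence[pairs$t],
    responder_seq = responders$sequence[pairs$r],
    trigger_count = triggers$count[pairs$t],
    responder_count = responders$count[pairs$r],
    overlap_len = 10L, wobble_free = wobble_free,
    stringsAsFactors = FALSE)
  tot <- tapply(out$responder_count, out$trigger_seq, sum)
  out$trigger_responder_reads <- as.integer(tot[out$trigger_seq])
  out <- out[out$trigger_responder_reads > min_responder_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find cleavage-competent overlap pairs anchored on transcripts
#'
#' As [find_overlap_pairs()], with fragments located on transcripts (exact
#' match anchored at the fragment 5' end) and, when `require_g11`, the
#' additional requirement that guide nt 11 is Watson-Crick complementary to
#' the transcript base immediately 5' of the fragment 5' end — the base the
#' guide must pair for slicing between target positions t10/t11.
#'
#' @param guides,fragments [group_reads()] data.frames.
#' @param transcripts named character vector of transcript sequences.
#' @param require_g11 request 11th-nucleotide pairing.
#' @param min_group_reads strict threshold on the per-guide sum of paired
#'   fragment reads.
#' @param allow_gu accept G·U pairs in the 10-nt duplex.
#' @return data.frame of pairs with `gene_id`, `fragment_tx_pos` and
#'   `g11_paired` columns added; fragments not locatable on any transcript
#'   are skipped and counted in `attr(,"n_unanchored")`.
#' @export
cleavage_pairs <- function(guides, fragments, transcripts,
                           require_g11 = TRUE, min_group_reads = 10,
                           allow_gu = FALSE) {
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
  transcripts <- dna_upper(transcripts)
  frag_seq <- dna_upper(fragments$sequence)
  # anchor each fragment group: first exact occurrence on a transcript
  anchors <- lapply(frag_seq, function(s) {
    for (g in names(transcripts)) {
      p <- regexpr(s, transcripts[[g]], fixed = TRUE)
      if (p > 0L) return(list(gene = g, pos = as.integer(p)))
    }
    NULL
  })
  unanchored <- vapply(anchors, is.null, logical(1))
  frags <- fragments[!unanchored, , drop = FALSE]
  anchors <- anchors[!unanchored]
  pairs <- find_overlap_pairs(guides, frags,
                              min_responder_reads = -Inf, allow_gu = allow_gu)
  if (nrow(pairs)) {
    ai <- match(pairs$responder_seq, frags$sequence)
    pairs$gene_id <- vapply(anchors[ai], `[[`, character(1), "gene")
    pairs$fragment_tx_pos <- vapply(anchors[ai], `[[`, integer(1), "pos")
    g11 <- substr(pairs$trigger_seq, 11L, 11L)
    up_base <- vapply(seq_len(nrow(pairs)), function(i) {
      p <- pairs$fragment_tx_pos[i] - 1L
      if (p < 1L) return(NA_character_)
      substr(transcripts[[pairs$gene_id[i]]], p, p)
    }, character(1))
    pairs$g11_paired <- !is.na(up_base) & nchar(g11) == 1L &
      bases_pair(g11, up_base, allow_gu = FALSE)
    if (require_g11) pairs <- pairs[pairs$g11_paired, , drop = FALSE]
  } else {
    pairs$gene_id <- character(0)
    pairs$fragment_tx_pos <- integer(0)
    pairs$g11_paired <- logical(0)
  }
  # group-size filter on the per-guide sum of surviving paired fragments
  if (nrow(pairs)) {
    tot <- tapply(pairs$responder_count, pairs$trigger_seq, sum)
    pairs$trigger_responder_reads <- as.integer(tot[pairs$trigger_seq])
    pairs <- pairs[pairs$trigger_responder_reads > min_group_reads, ,
                   drop = FALSE]
  }
  rownames(pairs) <- NULL
  attr(pairs, "n_unanchored") <- sum(unanchored)
  pairs
}

#' Pair degradome fragments with guide piRNAs
#'
#' Degradome (5'-monophosphate fragment) groups are paired with candidate
#' guide piRNAs under the cleavage geometry: 10-nt 5'-to-5' complementary
#' overlap plus 11th-nucleotide pairing against the transcript.
#'
#' @param guides [group_reads()] of candidate guide piRNAs.
#' @param degradome_reads character vector of degradome read sequences (or
#'   an already-grouped data.frame).
#' @param transcripts named character vector.
#' @param ... passed to [cleavage_pairs()].
#' @return as [cleavage_pairs()].
#' @export
pair_degradome <- function(guides, degradome_reads, transcripts, ...) {
  frags <- if (is.data.frame(degradome_reads)) degradome_reads
    else group_reads(degradome_reads, set = "degradome")
  cleavage_pairs(guides, frags, transcripts, ...)
}

#' Filter miRNA strands by Ago2 sorting preference
#'
#' Retains strands that are detectable and show a sorting preference to
#' Ago2 (RPM in Ago1 libraries strictly below RPM in Ago2 libraries).
#'
#' @param mirna_table data.frame with `rpm_ago1` and `rpm_ago2` columns.
#' @return the retained rows.
#' @export
filter_ago2_sorted <- function(mirna_table) {
  stopifnot(all(c("rpm_ago1", "rpm_ago2") %in% names(mirna_table)))
  keep <- (mirna_table$rpm_ago1 > 0 | mirna_table$rpm_ago2 > 0) &
    mirna_table$rpm_ago1 < mirna_table$rpm_ago2
  mirna_table[keep, , drop = FALSE]
}

#' Scan a target sequence for miRNA seed-match sites
#'
#' Default rule: perfect match of the reverse complement of the miRNA seed
#' (nt 2-8) in the given sequence. `seed_2_8_plus_3p` additionally requires
#' a 3' supplementary match (reverse complement of miRNA nt 13-16) within
#' 10 nt upstream of the seed site. Only the supplied strand is scanned;
#' pass the antisense sequence to scan the opposite strand.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param target target sequence to scan.
#' @param rule `"seed_2_8"` or `"seed_2_8_plus_3p"`.
#' @return integer vector of 1-based site offsets (position of the seed
#'   complement match).
#' @export
scan_mirna_sites <- function(mirna, target,
                             rule = c("seed_2_8", "seed_2_8_plus_3p")) {
  rule <- match.arg(rule)
  mirna <- dna_upper(mirna); target <- dna_upper(target)
  seed <- revcomp(substr(mirna, 2L, 8L))
  m <- gregexpr(seed, target, fixed = TRUE)[[1]]
  sites <- as.integer(m[m > 0L])
  if (rule == "seed_2_8_plus_3p" && length(sites)) {
    supp <- revcomp(substr(mirna, 13L, 16L))
    ok <- vapply(sites, function(s) {
      lo <- max(1L, s - 10L - nchar(supp))
      window <- substr(target, lo, s - 1L)
      grepl(supp, window, fixed = TRUE)
    }, logical(1))
    sites <- sites[ok]
  }
  sites
}
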