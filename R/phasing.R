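#' Head-to-tail distance histogram of positioned reads
#'
#' Phased (Zucchini-dependent) piRNA biogenesis produces trains of reads in
#' which the next piRNA's 5' end sits one base past the previous piRNA's 3'
#' end. For reads on one transcript/strand the statistic is the distance
#' `d = downstream 5' end - upstream 3' end` (3' end = last covered base,
#' so immediately adjacent reads give `d = 1`). By default each read is
#' paired with its nearest downstream neighbor (the smallest 5' end greater
#' than the read's own); `mode = "all"` counts all pairs whose distance
#' falls in the window, which is the robust choice for dense libraries.
#'
#' @param start5,end3 integer vectors: per-read 5'-most and 3'-most covered
#'   positions in a common coordinate system (e.g. transcript coordinates),
#'   same strand.
#' @param range histogram window of distances.
#' @param mode `"nearest"` or `"all"`.
#' @return named integer vector of counts over `range`; attribute
#'   `n_pairs`; empty (flagged) histogram for fewer than two reads.
#' @export
phasing_distances <- function(start5, end3, range = -20:50,
                              mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  stopifnot(length(start5) == length(end3))
  hist0 <- setNames(integer(length(range)), range)
  if (length(start5) < 2L) {
    attr(hist0, "n_pairs") <- 0L
    attr(hist0, "flagged") <- TRUE
    return(hist0)
  }
  d <- if (mode == "nearest") {
    vapply(seq_along(start5), function(i) {
      down <- start5[start5 > start5[i]]
      if (!length(down)) return(NA_integer_)
      as.integer(min(down) - end3[i])
    }, integer(1))
  } else {
    grid <- expand.grid(i = seq_along(start5), j = seq_along(start5))
    grid <- grid[start5[grid$j] > start5[grid$i], , drop = FALSE]
    as.integer(start5[grid$j] - end3[grid$i])
  }
  d <- d[!is.na(d) & d >= min(range) & d <= max(range)]
  tab <- table(factor(d, levels = range))
  out <- setNames(as.integer(tab), range)
  attr(out, "n_pairs") <- sum(out)
  out
}

#' Phasing z-score at distance one
#'
#' Summary statistic of a phasing histogram: the count at `d = 1` expressed
#' as a z-score against the background distances `d` in `[2, 50]`. Reported
#' as `Inf` ("saturated") when the background is exactly flat at zero
#' variance with signal present. This z1 stands in for the summary
#' statistic of the published phasing protocol.
#'
#' @param histogram output of [phasing_distances()] (must cover `[1, 50]`).
#' @param background distances used as background.
#' @return list with `z1`, `saturated`, `n_pairs`.
#' @export
phasing_zscore <- function(histogram, background = 2:50) {
  lv <- as.integer(names(histogram))
  stopifnot(1L %in% lv, all(background %in% lv))
  if (sum(histogram) == 0L)
    return(list(z1 = NA_real_, saturated = FALSE, n_pairs = 0L,
                flagged = TRUE))
  c1 <- histogram[["1"]]
  bg <- as.numeric(histogram[as.character(background)])
  s <- sd(bg)
  if (s == 0) {
    z <- if (c1 > mean(bg)) Inf else if (c1 < mean(bg)) -Inf else 0
    return(list(z1 = z, saturated = !is.finite(z),
                n_pairs = attr(histogram, "n_pairs") %||% sum(histogram)))
  }
  list(z1 = (c1 - mean(bg)) / s, saturated = FALSE,
       n_pairs = attr(histogram, "n_pairs") %||% sum(histogram))
}

#' Phasing analysis of one gene's assignments
#'
#' Converts genic assignments of a single gene to transcript-coordinate
#' 5'/3' ends (sense reads only) and computes the distance histogram and
#' z1 score.
#'
#' @param assignments output of [classify_hierarchical()].
#' @param gene_id gene to analyze.
#' @param assets the [genome_assets()] bundle.
#' @param mode passed to [phasing_distances()].
#' @return list with `histogram` and the [phasing_zscore()] fields.
#' @export
phasing_signature <- function(assignments, gene_id, assets,
                              mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  a <- assignments[assignments$class == "genic" &
                     assignments$gene_id %in% gene_id &
                     assignments$sense %in% TRUE &
                     !is.na(assignments$start) & !is.na(assignments$end), ,
                   drop = FALSE]
  gm <- assets$genes[[gene_id]]
  # genomic -> transcript 5' coordinate (sense reads lie within one exon)
  g5 <- if (gm$strand == "+") a$start else a$end
  tx <- assets$transcripts[[gene_id]]
  ex <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(a$chrom, IRanges::IRanges(g5, g5)),
    GenomicRanges::GRanges(gm$chrom, gm$exons), select = "first")
  keep <- !is.na(ex)
  a <- a[keep, , drop = FALSE]; g5 <- g5[keep]; ex <- ex[keep]
  tx_idx <- match(ex, tx$exon_order)
  start5 <- if (gm$strand == "+") {
    tx$exon_tx_start[tx_idx] + (g5 - IRanges::start(gm$exons)[ex])
  } else {
    tx$exon_tx_start[tx_idx] + (IRanges::end(gm$exons)[ex] - g5)
  }
  end3 <- start5 + a$length - 1L
  h <- phasing_distances(start5, end3, mode = mode)
  c(list(histogram = h), phasing_zscore(h))
}
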