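#' Trim the 3' adapter from raw reads
#'
#' Keeps, for each read, the longest prefix before the leftmost exact
#' occurrence of the adapter. Reads without an adapter match are kept whole
#' and flagged; reads that begin with the adapter (empty insert) are dropped.
#' The default adapter is the library-prep 3' adapter used for testis
#' small-RNA sequencing.
#'
#' @param reads named character vector of read sequences.
#' @param adapter adapter sequence (DNA alphabet).
#' @return list with `reads` (trimmed, named), `no_adapter` (logical, per
#'   retained read) and `n_dropped` (empty inserts).
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGCACACGTCT") {
  stopifnot(nchar(adapter) > 0)
  reads <- dna_upper(reads)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  trimmed <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  names(trimmed) <- names(reads)
  keep <- nchar(trimmed) > 0L
  list(reads = trimmed[keep], no_adapter = (pos < 0L)[keep],
       n_dropped = sum(!keep))
}

#' Select reads by length window
#'
#' @param reads named character vector.
#' @param min_len,max_len inclusive length bounds; the analysis window for
#'   piRNAs is 23-29 nt, the size-profile window 18-29 nt.
#' @return list with `reads` (retained) and `n_removed`.
#' @export
size_select <- function(reads, min_len = 23L, max_len = 29L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  len <- nchar(reads)
  keep <- len >= min_len & len <= max_len
  list(reads = reads[keep], n_removed = sum(!keep))
}

#' Hierarchically classify small-RNA reads
#'
#' Implements the sequential annotation of a size-selected library: reads
#' overlapping annotated non-piRNA loci (rRNA/tRNA/miRNA/sn/snoRNA) are
#' excluded first; remaining reads are claimed in order by piRNA clusters,
#' then transposon consensus sequences, then gene exons. Placement is exact
#' (no mismatches) and end-to-end. Reads with several equally good
#' placements inside the claiming tier are placed uniformly at random
#' ("mapped randomly", seeded); at the genic tier a read hitting exons of
#' more than one gene is discarded, while multimapping positions within a
#' single gene are kept with one seeded random position. Reads with no
#' contiguous genomic placement are matched against spliced transcripts and
#' counted as genic junction reads when they cross an exon-exon boundary
#' with at least `junction_anchor` nt on each side.
#'
#' @param reads named character vector of size-selected read sequences.
#' @param assets a [genome_assets()] bundle.
#' @param tier_mode `"sequential"` (default; cluster claims before TE) or
#'   `"independent"` (cluster and TE abundances additionally counted
#'   independently on all post-non-piRNA reads, as used for cross-library
#'   class comparisons; see `attr(,"independent_counts")`).
#' @param min_similarity identity threshold for the independent cluster/TE
#'   counting (`1` = exact; `0.8` reproduces the mismatch-allowing option).
#' @param junction_anchor minimum nt on each side of a junction.
#' @param seed integer seed for the random-placement policy.
#' @return data.frame of read assignments (one row per read) with columns
#'   `read_id`, `sequence`, `length`, `class`, `gene_id`, `locus`, `chrom`,
#'   `start`, `end`, `strand`, `sense`, `region`, `is_junction`;
#'   `attr(,"n_input")` records the input read count.
#' @export
classify_hierarchical <- function(reads, assets,
                                  tier_mode = c("sequential", "independent"),
                                  min_similarity = 1,
                                  junction_anchor = 4L, seed = 1L) {
  tier_mode <- match.arg(tier_mode)
  stopifnot(length(reads) > 0L)
  if (is.null(names(reads))) names(reads) <- paste0("r", seq_along(reads))
  reads <- dna_upper(reads)

  seqs <- unique(reads)
  seq_of_read <- match(reads, seqs)

  hits <- exact_hits(seqs, assets$sequences)
  hit_gr <- GenomicRanges::GRanges(hits$ref,
    IRanges::IRanges(hits$start, hits$end), strand = hits$strand)

  ov_np <- IRanges::overlapsAny(hit_gr, assets$non_pirna, ignore.strand = TRUE)
  ov_cl <- IRanges::overlapsAny(hit_gr, assets$clusters, ignore.strand = TRUE)
  ex_hit <- GenomicRanges::findOverlaps(hit_gr, assets$exon_gr,
                                        type = "within", ignore.strand = TRUE)
  hit_gene <- rep(NA_character_, nrow(hits))
  hit_gene[S4Vectors::queryHits(ex_hit)] <-
    assets$exon_gr$gene_id[S4Vectors::subjectHits(ex_hit)]

  # per-sequence tier decision
  n_seq <- length(seqs)
  seq_class <- rep("unassigned", n_seq)
  has_hit <- tabulate(hits$read, n_seq) > 0L
  np_seq <- unique(hits$read[ov_np])
  seq_class[np_seq] <- "non_piRNA"
  cl_seq <- setdiff(unique(hits$read[ov_cl]), np_seq)
  seq_class[cl_seq] <- "cluster"

  remaining <- which(!(seq_class %in% c("non_piRNA", "cluster")))
  te_hits <- if (length(assets$te_consensus) && length(remaining)) {
    h <- exact_hits(seqs[remaining], assets$te_consensus)
    h$read <- remaining[h$read]
    h
  } else data.frame(read = integer(0), ref = character(0), start = integer(0),
                    end = integer(0), strand = character(0))
  te_seq <- unique(te_hits$read)
  seq_class[te_seq] <- "TE"

  genic_cand <- setdiff(remaining, te_seq)
  if (length(genic_cand)) {
    sel <- hits$read %in% genic_cand & !is.na(hit_gene)
    gl <- split(hit_gene[sel], hits$read[sel])
    ng <- vapply(gl, function(g) length(unique(g)), integer(1))
    one_gene <- as.integer(names(gl))[ng == 1L]
    multi_gene <- as.integer(names(gl))[ng > 1L]
    seq_class[one_gene] <- "genic"
    seq_class[multi_gene] <- "unassigned"   # hits span >1 gene: discarded
  }

  # junction rescue: sequences with no genomic placement at all
  no_hit <- which(!has_hit & seq_class == "unassigned")
  junction_tab <- NULL
  if (length(no_hit) && length(assets$transcripts)) {
    tx_seqs <- Biostrings::DNAStringSet(
      vapply(assets$transcripts, `[[`, character(1), "sequence"))
    names(tx_seqs) <- names(assets$transcripts)
    jh <- exact_hits(seqs[no_hit], tx_seqs, strands = "+")
    if (nrow(jh)) {
      jh$read <- no_hit[jh$read]
      jx <- mapply(function(g, st, en) {
        j <- assets$transcripts[[g]]$junctions
        any(j >= st + junction_anchor - 1L & j <= en - junction_anchor)
      }, jh$ref, jh$start, jh$end)
      jh <- jh[jx, , drop = FALSE]
      if (nrow(jh)) {
        gl <- split(seq_len(nrow(jh)), jh$read)
        ok <- vapply(gl, function(ii) length(unique(jh$ref[ii])) == 1L, logical(1))
        keep_seq <- as.integer(names(gl))[ok]
        seq_class[keep_seq] <- "genic"
        junction_tab <- jh[jh$read %in% keep_seq, , drop = FALSE]
      }
    }
  }

  # expand to per-read rows and draw random placements with one seeded stream
  n_reads <- length(reads)
  cls <- seq_class[seq_of_read]
  gene_id <- rep(NA_character_, n_reads)
  locus <- rep(NA_character_, n_reads)
  chrom <- rep(NA_character_, n_reads)
  start <- rep(NA_integer_, n_reads); end <- rep(NA_integer_, n_reads)
  strand <- rep(NA_character_, n_reads)
  is_junction <- rep(FALSE, n_reads)

  pick_hits <- function(cand_rows_per_seq, read_idx) {
    # cand_rows_per_seq: list keyed by seq index -> candidate hit row numbers;
    # vectorized uniform draw of one candidate per read
    keys <- as.integer(names(cand_rows_per_seq))
    lens <- lengths(cand_rows_per_seq)
    flat <- unlist(cand_rows_per_seq, use.names = FALSE)
    offset <- c(0L, cumsum(lens))
    pos_of_seq <- integer(n_seq)
    pos_of_seq[keys] <- seq_along(keys)
    p <- pos_of_seq[seq_of_read[read_idx]]
    stopifnot(all(p > 0L))
    flat[offset[p] + sample_per_element(lens[p])]
  }

  with_seed(seed, {
    # cluster placements: uniform among cluster-overlapping hits
    cl_reads <- which(cls == "cluster")
    if (length(cl_reads)) {
      cand <- split(which(ov_cl), hits$read[ov_cl])
      rows <- pick_hits(cand, cl_reads)
      chrom[cl_reads] <- hits$ref[rows]
      start[cl_reads] <- hits$start[rows]; end[cl_reads] <- hits$end[rows]
      strand[cl_reads] <- hits$strand[rows]
      locus[cl_reads] <- "cluster"
    }
    # TE placements: uniform among consensus hits
    te_reads <- which(cls == "TE")
    if (length(te_reads) && nrow(te_hits)) {
      cand <- split(seq_len(nrow(te_hits)), te_hits$read)
      rows <- pick_hits(cand, te_reads)
      locus[te_reads] <- te_hits$ref[rows]
      start[te_reads] <- te_hits$start[rows]; end[te_reads] <- te_hits$end[rows]
      strand[te_reads] <- te_hits$strand[rows]
    }
    # genic placements: uniform among within-gene hits (intragenic multimappers)
    gn_seqs <- which(seq_class == "genic" & has_hit)
    gn_reads <- which(cls == "genic" & has_hit[seq_of_read])
    if (length(gn_reads)) {
      sel <- which(hits$read %in% gn_seqs & !is.na(hit_gene))
      cand <- split(sel, hits$read[sel])
      rows <- pick_hits(cand, gn_reads)
      chrom[gn_reads] <- hits$ref[rows]
      start[gn_reads] <- hits$start[rows]; end[gn_reads] <- hits$end[rows]
      strand[gn_reads] <- hits$strand[rows]
      gene_id[gn_reads] <- hit_gene[rows]
    }
    # junction reads: transcript placement, 5' genomic position recorded
    if (!is.null(junction_tab)) {
      jn_reads <- which(seq_of_read %in% junction_tab$read)
      if (length(jn_reads)) {
        cand <- split(seq_len(nrow(junction_tab)), junction_tab$read)
        rows <- pick_hits(cand, jn_reads)
        g <- junction_tab$ref[rows]
        gene_id[jn_reads] <- g
        is_junction[jn_reads] <- TRUE
        for (k in seq_along(jn_reads)) {
          gm <- assets$genes[[g[k]]]
          tx <- assets$transcripts[[g[k]]]
          p5 <- tx_to_genome(gm, tx, junction_tab$start[rows[k]])
          chrom[jn_reads[k]] <- gm$chrom
          start[jn_reads[k]] <- p5
          end[jn_reads[k]] <- NA_integer_
          strand[jn_reads[k]] <- gm$strand
        }
      }
    }
  })

  sense <- rep(NA, n_reads)
  region <- rep(NA_character_, n_reads)
  gn <- which(!is.na(gene_id))
  if (length(gn)) {
    sense[gn] <- strand[gn] == unname(assets$gene_strand[gene_id[gn]])
    # region of the read's 5' end (strand-aware); junction reads use their
    # recorded 5' genomic position
    p5 <- ifelse(strand[gn] == "+", start[gn],
                 ifelse(is.na(end[gn]), start[gn], end[gn]))
    ok <- !is.na(p5)
    if (any(ok) && length(assets$region_gr)) {
      pt <- GenomicRanges::GRanges(chrom[gn[ok]], IRanges::IRanges(p5[ok], p5[ok]))
      fo <- GenomicRanges::findOverlaps(pt, assets$region_gr,
                                        ignore.strand = TRUE)
      same_gene <- gene_id[gn[ok]][S4Vectors::queryHits(fo)] ==
        assets$region_gr$gene_id[S4Vectors::subjectHits(fo)]
      fo <- fo[same_gene]
      reg <- rep(NA_character_, sum(ok))
      reg[S4Vectors::queryHits(fo)] <-
        assets$region_gr$region[S4Vectors::subjectHits(fo)]
      region[gn[ok]] <- reg
    }
  }

  out <- data.frame(read_id = names(reads), sequence = reads,
                    length = nchar(reads), class = cls, gene_id = gene_id,
                    locus = locus, chrom = chrom, start = start, end = end,
                    strand = strand, sense = sense, region = region,
                    is_junction = is_junction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_input") <- n_reads

  if (tier_mode == "independent") {
    post_np <- which(!(seq_class[seq_of_read] == "non_piRNA"))
    post_np_seqs <- setdiff(seq_len(n_seq), np_seq)
    cl_ind <- unique(hits$read[ov_cl])
    te_ref <- assets$te_consensus
    te_ind <- integer(0)
    if (length(te_ref)) {
      mh <- match_reads(seqs[post_np_seqs], te_ref,
                        min_similarity = min_similarity)
      te_ind <- post_np_seqs[unique(mh$read)]
    }
    attr(out, "independent_counts") <- c(
      cluster = sum(seq_of_read[post_np] %in% cl_ind),
      TE = sum(seq_of_read[post_np] %in% te_ind))
  }
  out
}

#' Summarize assignments into a library profile
#'
#' Computes per-class and per-gene counts with the pipeline's three
#' normalizations: RPK (reads per exon kilobase), TPM (RPK scaled so genic
#' TPM sums to 1e6), and RPM (reads per million reads remaining after
#' non-piRNA removal).
#'
#' @param assignments output of [classify_hierarchical()].
#' @param assets the matching [genome_assets()] bundle.
#' @param library library label.
#' @param total_raw optional raw read count before trimming/size selection.
#' @return an object of class `LibraryProfile`: list with `library`,
#'   `total_raw`, `total_size_selected`, `total_after_nonpirna`,
#'   `class_counts`, and a per-gene data.frame `genes` with region/strand
#'   splits and `rpk`, `tpm`, `rpm` columns.
#' @export
quantify <- function(assignments, assets, library = "lib", total_raw = NA) {
  n <- nrow(assignments)
  class_counts <- table(factor(assignments$class,
    levels = c("non_piRNA", "cluster", "TE", "genic", "unassigned")))
  total_after_np <- n - as.integer(class_counts[["non_piRNA"]])
  gids <- names(assets$genes)
  gsub <- assignments[assignments$class == "genic", , drop = FALSE]
  cnt <- table(factor(gsub$gene_id, levels = gids))
  by_region <- function(r)
    table(factor(gsub$gene_id[!is.na(gsub$region) & gsub$region == r],
                 levels = gids))
  sense_cnt <- table(factor(gsub$gene_id[gsub$sense %in% TRUE], levels = gids))
  junc_cnt <- table(factor(gsub$gene_id[gsub$is_junction], levels = gids))
  ex_kb <- vapply(assets$genes, exon_length, numeric(1)) / 1000
  if (any(ex_kb <= 0)) stop("gene with zero exon length")
  rpk <- as.numeric(cnt) / ex_kb
  tpm <- if (sum(rpk) > 0) rpk * 1e6 / sum(rpk) else rpk
  rpm <- if (total_after_np > 0) as.numeric(cnt) * 1e6 / total_after_np
    else rep(0, length(cnt))
  genes <- data.frame(gene_id = gids, count = as.integer(cnt),
                      count_utr5 = as.integer(by_region("utr5")),
                      count_cds = as.integer(by_region("cds")),
                      count_utr3 = as.integer(by_region("utr3")),
                      sense_count = as.integer(sense_cnt),
                      junction_count = as.integer(junc_cnt),
                      exon_kb = ex_kb, rpk = rpk, tpm = tpm, rpm = rpm,
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  cls_rpm <- as.numeric(class_counts[c("cluster", "TE", "genic")]) * 1e6 /
    max(total_after_np, 1L)
  names(cls_rpm) <- c("cluster", "TE", "genic")
  ind <- attr(assignments, "independent_counts")
  structure(list(library = library, total_raw = total_raw,
                 total_size_selected = n,
                 total_after_nonpirna = total_after_np,
                 class_counts = c(class_counts),
                 class_rpm = cls_rpm,
                 independent_counts = ind,
                 genes = genes),
            class = "LibraryProfile")
}

#' @export
print.LibraryProfile <- function(x, ...) {
  cat("LibraryProfile", x$library, "-", x$total_size_selected,
      "reads,", x$total_after_nonpirna, "after non-piRNA removal\n")
  print(x$class_counts)
  invisible(x)
}

#' Build a coverage track from read assignments
#'
#' Per-base depth over the genomic spans of positioned reads, with the
#' bedgraph scaling factor `1e6 / reads after non-piRNA removal`.
#' Junction reads (no contiguous genomic span) are skipped.
#'
#' @param assignments output of [classify_hierarchical()].
#' @param assets the matching [genome_assets()] bundle.
#' @param scale_basis denominator of the scaling factor; defaults to the
#'   number of reads remaining after non-piRNA removal.
#' @param strand restrict to `"+"` or `"-"` reads for strand-split tracks.
#' @return a [coverage_track()].
#' @export
coverage_from_assignments <- function(assignments, assets, scale_basis = NULL,
                                      strand = NULL) {
  a <- assignments[!is.na(assignments$chrom) & !is.na(assignments$end), ,
                   drop = FALSE]
  if (!is.null(strand)) a <- a[a$strand %in% strand, , drop = FALSE]
  if (is.null(scale_basis))
    scale_basis <- sum(assignments$class != "non_piRNA")
  lens <- setNames(Biostrings::width(assets$sequences), names(assets$sequences))
  gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                               seqlengths = lens)
  cov <- GenomicRanges::coverage(gr)
  coverage_track(as.list(cov), scaling_factor = 1e6 / max(scale_basis, 1))
}
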