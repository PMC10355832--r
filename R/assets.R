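#' Construct a gene model
#'
#' A gene model carries the exon structure of a single protein-coding gene
#' together with the partition of its exon space into 5'UTR, CDS and 3'UTR.
#' Coordinates are 1-based closed genomic intervals ([IRanges::IRanges]);
#' introns are derived as the gaps between consecutive exons.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 [IRanges::IRanges] of genomic intervals. `cds`,
#'   `utr5` and `utr3` must lie inside the exon union and together partition it.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       utr5 = IRanges::IRanges(), utr3 = IRanges::IRanges()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- IRanges::reduce(BiocGenerics::sort(exons))
  if (length(exons) == 0L) stop("gene ", gene_id, ": no exons")
  exon_union <- exons
  for (part in list(cds, utr5, utr3)) {
    if (length(part) && !all(IRanges::overlapsAny(part, exon_union, type = "within")))
      stop("gene ", gene_id, ": CDS/UTR interval outside exons")
  }
  covered <- IRanges::reduce(c(cds, utr5, utr3))
  if (sum(IRanges::width(covered)) != sum(IRanges::width(exon_union)) ||
      !all(IRanges::overlapsAny(exon_union, covered, type = "within")))
    stop("gene ", gene_id, ": 5'UTR/CDS/3'UTR do not partition the exon union")
  introns <- IRanges::gaps(exons,
    start = min(IRanges::start(exons)), end = max(IRanges::end(exons)))
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = IRanges::reduce(BiocGenerics::sort(cds)),
         utr5 = IRanges::reduce(BiocGenerics::sort(utr5)),
         utr3 = IRanges::reduce(BiocGenerics::sort(utr3)),
         introns = introns),
    class = "GeneModel")
}

exon_length <- function(gene) sum(IRanges::width(gene$exons))

region_lengths <- function(gene) {
  c(utr5 = sum(IRanges::width(gene$utr5)),
    cds = sum(IRanges::width(gene$cds)),
    utr3 = sum(IRanges::width(gene$utr3)))
}

#' Assemble a genome asset bundle
#'
#' Bundles reference sequences, gene models, piRNA-cluster intervals,
#' transposon consensus sequences and non-piRNA (rRNA/tRNA/miRNA/sn/snoRNA)
#' intervals, and derives spliced transcript sequences with exon-junction
#' offsets for every gene.
#'
#' @param sequences named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param genes list of [gene_model()] objects.
#' @param clusters [GenomicRanges::GRanges] of piRNA cluster intervals.
#' @param te_consensus named [Biostrings::DNAStringSet] of transposon
#'   consensus sequences.
#' @param non_pirna [GenomicRanges::GRanges] of non-piRNA loci with a
#'   metadata column `class` in rRNA/tRNA/miRNA/snRNA/snoRNA.
#' @param triggers optional data.frame of trigger small RNAs with columns
#'   `trigger_id`, `sequence` (and optionally per-library RPM columns).
#' @return an object of class `GenomeAssets`.
#' @export
genome_assets <- function(sequences, genes,
                          clusters = GenomicRanges::GRanges(),
                          te_consensus = Biostrings::DNAStringSet(),
                          non_pirna = GenomicRanges::GRanges(),
                          triggers = NULL) {
  stopifnot(is(sequences, "DNAStringSet"), !is.null(names(sequences)))
  chrom_len <- setNames(Biostrings::width(sequences), names(sequences))
  check_within <- function(gr, what) {
    if (length(gr) == 0L) return(invisible())
    seq <- as.character(GenomeInfoDb::seqnames(gr))
    if (!all(seq %in% names(chrom_len)))
      stop(what, ": unknown chromosome")
    if (any(BiocGenerics::start(gr) < 1L) ||
        any(BiocGenerics::end(gr) > chrom_len[seq]))
      stop(what, ": interval outside chromosome bounds")
  }
  check_within(clusters, "clusters")
  check_within(non_pirna, "non_pirna")
  for (g in genes) {
    if (!g$chrom %in% names(chrom_len) ||
        max(IRanges::end(g$exons)) > chrom_len[[g$chrom]])
      stop("gene ", g$gene_id, ": exons outside chromosome")
  }
  genes <- genes[order(vapply(genes, `[[`, character(1), "gene_id"))]
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  assets <- structure(
    list(sequences = sequences, genes = genes, clusters = clusters,
         te_consensus = te_consensus, non_pirna = non_pirna,
         triggers = triggers),
    class = "GenomeAssets")
  assets$exon_gr <- exon_granges(assets)
  assets$region_gr <- region_granges(assets)
  assets$gene_strand <- vapply(assets$genes, `[[`, character(1), "strand")
  assets$transcripts <- build_transcripts(assets)
  assets
}

# flat GRanges of 5'UTR/CDS/3'UTR intervals tagged with gene_id and region
region_granges <- function(assets) {
  rows <- lapply(assets$genes, function(g) {
    parts <- list(utr5 = g$utr5, cds = g$cds, utr3 = g$utr3)
    parts <- parts[vapply(parts, length, integer(1)) > 0L]
    if (length(parts) == 0L) return(NULL)
    data.frame(chrom = g$chrom,
               start = unlist(lapply(parts, IRanges::start)),
               end = unlist(lapply(parts, IRanges::end)),
               region = rep(names(parts), vapply(parts, length, integer(1))),
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$region <- df$region
  gr$gene_id <- df$gene_id
  gr
}

# flat GRanges of all exons, tagged with gene_id; used for fast overlap
exon_granges <- function(assets) {
  rows <- lapply(assets$genes, function(g) {
    data.frame(chrom = g$chrom, start = IRanges::start(g$exons),
               end = IRanges::end(g$exons), strand = g$strand,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$gene_id <- df$gene_id
  gr
}

# spliced transcript (sense strand) plus junction offsets: junction i sits
# between transcript positions j_i and j_i + 1
build_transcripts <- function(assets) {
  lapply(assets$genes, function(g) {
    chrom_seq <- assets$sequences[[g$chrom]]
    pieces <- as.character(Biostrings::extractAt(chrom_seq, g$exons))
    widths <- IRanges::width(g$exons)
    if (g$strand == "+") {
      seq <- paste(pieces, collapse = "")
      exon_order <- seq_along(pieces)
    } else {
      seq <- paste(rev(as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(pieces)))),
        collapse = "")
      exon_order <- rev(seq_along(pieces))
      widths <- rev(widths)
    }
    ends <- cumsum(widths)
    junctions <- if (length(ends) > 1L) ends[-length(ends)] else integer(0)
    list(gene_id = g$gene_id, sequence = seq, junctions = junctions,
         exon_order = exon_order, exon_tx_end = ends,
         exon_tx_start = c(1L, head(ends, -1L) + 1L))
  })
}

# map transcript coordinates (1-based, 5'->3' of the mRNA) to genomic positions
tx_to_genome <- function(gene, tx, pos) {
  i <- findInterval(pos - 1L, c(0L, tx$exon_tx_end))
  off <- pos - tx$exon_tx_start[i]
  ex <- tx$exon_order[i]
  if (gene$strand == "+") {
    IRanges::start(gene$exons)[ex] + off
  } else {
    IRanges::end(gene$exons)[ex] - off
  }
}

#' Load a genome asset bundle from standard files
#'
#' Reads a genome FASTA, a GFF3 of gene models (gene/exon/CDS/UTR features),
#' and optional BED files of piRNA clusters and non-piRNA loci plus a
#' transposon-consensus FASTA, and returns a validated [genome_assets()]
#' bundle. Genes whose CDS/UTR structure violates the exon partition (for
#' example a CDS extending into an intron) are rejected with a warning; the
#' number of rejected genes is available as `attr(assets, "n_rejected")`.
#'
#' @param genome_fasta path to the genome FASTA.
#' @param gff3 path to the gene-model GFF3 (1-based closed, per the format).
#' @param clusters_bed,nonpirna_bed optional BED paths (0-based half-open on
#'   disk; converted on import). The non-piRNA BED carries the RNA class in
#'   its name column.
#' @param te_fasta optional transposon consensus FASTA.
#' @param triggers_tsv optional TSV of trigger small RNAs.
#' @return a `GenomeAssets` object.
#' @export
load_assets <- function(genome_fasta, gff3, clusters_bed = NULL,
                        te_fasta = NULL, nonpirna_bed = NULL,
                        triggers_tsv = NULL) {
  sequences <- Biostrings::readDNAStringSet(genome_fasta)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  gff <- rtracklayer::import(gff3)
  genes <- list(); n_rejected <- 0L
  gene_rows <- gff[gff$type == "gene"]
  for (i in seq_along(gene_rows)) {
    gid <- gene_rows$ID[i]
    kids <- gff[!is.na(as.character(gff$Parent)) &
                  as.character(gff$Parent) == gid]
    pick <- function(type) {
      r <- IRanges::ranges(kids[kids$type == type])
      IRanges::reduce(BiocGenerics::sort(r))
    }
    gm <- tryCatch(
      gene_model(gid,
                 chrom = as.character(GenomeInfoDb::seqnames(gene_rows))[i],
                 strand = as.character(BiocGenerics::strand(gene_rows))[i],
                 exons = pick("exon"), cds = pick("CDS"),
                 utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR")),
      error = function(e) {
        warning("rejecting gene ", gid, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(gm)) n_rejected <- n_rejected + 1L else genes[[gid]] <- gm
  }
  clusters <- if (!is.null(clusters_bed)) rtracklayer::import(clusters_bed)
    else GenomicRanges::GRanges()
  non_pirna <- GenomicRanges::GRanges()
  if (!is.null(nonpirna_bed)) {
    non_pirna <- rtracklayer::import(nonpirna_bed)
    non_pirna$class <- sub("_.*$", "", non_pirna$name %||% "rRNA")
  }
  te <- if (!is.null(te_fasta)) Biostrings::readDNAStringSet(te_fasta)
    else Biostrings::DNAStringSet()
  names(te) <- sub("\\s.*$", "", names(te))
  triggers <- if (!is.null(triggers_tsv))
    read.delim(triggers_tsv, stringsAsFactors = FALSE) else NULL
  assets <- genome_assets(sequences, genes, clusters = clusters,
                          te_consensus = te, non_pirna = non_pirna,
                          triggers = triggers)
  attr(assets, "n_rejected") <- n_rejected
  assets
}

#' Write a genome asset bundle to standard files
#'
#' Inverse of [load_assets()]: emits `genome.fa`, `genes.gff3`,
#' `clusters.bed`, `nonpirna.bed`, `te_consensus.fa` and `triggers.tsv`
#' under `dir`. A write/read round trip reproduces identical interval
#' structures and sequences.
#'
#' @param assets a `GenomeAssets` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_assets <- function(assets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             clusters = file.path(dir, "clusters.bed"),
             nonpirna = file.path(dir, "nonpirna.bed"),
             te = file.path(dir, "te_consensus.fa"),
             triggers = file.path(dir, "triggers.tsv"))
  Biostrings::writeXStringSet(assets$sequences, paths["genome"])
  feats <- list()
  for (g in assets$genes) {
    mk <- function(r, type) {
      if (length(r) == 0L) return(NULL)
      gr <- GenomicRanges::GRanges(g$chrom, r, strand = g$strand)
      gr$type <- type
      gr$ID <- if (type == "gene") g$gene_id else NA_character_
      gr$Parent <- if (type == "gene") NA_character_ else g$gene_id
      gr$phase <- NA_integer_
      if (type == "CDS") {
        w <- IRanges::width(r)
        if (g$strand == "-") w <- rev(w)
        ph <- (3L - c(0L, cumsum(w)[-length(w)]) %% 3L) %% 3L
        gr$phase <- if (g$strand == "-") rev(ph) else ph
      }
      gr
    }
    span <- IRanges::IRanges(min(IRanges::start(g$exons)),
                             max(IRanges::end(g$exons)))
    feats <- c(feats, list(mk(span, "gene"), mk(g$exons, "exon"),
                           mk(g$cds, "CDS"), mk(g$utr5, "five_prime_UTR"),
                           mk(g$utr3, "three_prime_UTR")))
  }
  feats <- feats[!vapply(feats, is.null, logical(1))]
  gff <- if (length(feats)) unname(do.call(c, feats)) else GenomicRanges::GRanges()
  if (length(gff)) {
    gff$type <- factor(gff$type)
    gff$Parent <- ifelse(is.na(gff$Parent), "", gff$Parent)
  }
  rtracklayer::export(gff, paths["gff"], format = "gff3")
  rtracklayer::export(assets$clusters, paths["clusters"], format = "bed")
  np <- assets$non_pirna
  if (length(np)) np$name <- paste0(np$class, "_", seq_along(np))
  rtracklayer::export(np, paths["nonpirna"], format = "bed")
  Biostrings::writeXStringSet(assets$te_consensus, paths["te"])
  if (!is.null(assets$triggers))
    write.table(assets$triggers, paths["triggers"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @export
print.GenomeAssets <- function(x, ...) {
  cat("GenomeAssets:", length(x$sequences), "sequence(s),",
      length(x$genes), "gene(s),", length(x$clusters), "cluster interval(s),",
      length(x$te_consensus), "TE consensus, ",
      length(x$non_pirna), "non-piRNA locus/loci\n")
  invisible(x)
}

#' Build a coverage track
#'
#' Per-base coverage with a library scaling factor, the in-memory analogue of
#' a bedgraph produced by `bedtools genomecov -scale`.
#'
#' @param coverage named list (or [IRanges::RleList]) of per-base coverage,
#'   one element per chromosome.
#' @param scaling_factor multiplier applied on export, conventionally
#'   `1e6 / reads remaining after non-piRNA removal`.
#' @return an object of class `CoverageTrack`.
#' @export
coverage_track <- function(coverage, scaling_factor = 1) {
  cov <- lapply(coverage, function(v) if (is(v, "Rle")) v else S4Vectors::Rle(v))
  if (any(vapply(cov, function(v) any(S4Vectors::runValue(v) < 0), logical(1))))
    stop("coverage values must be >= 0")
  structure(list(coverage = cov, scaling_factor = scaling_factor),
            class = "CoverageTrack")
}

#' Write a coverage track as bedgraph
#'
#' Emits scaled coverage as bedgraph (0-based half-open on disk), with runs
#' of equal value merged and zero-coverage positions omitted.
#'
#' @param track a [coverage_track()].
#' @param out output path.
#' @return invisibly, `out`.
#' @export
write_bedgraph <- function(track, out) {
  stopifnot(is(track, "CoverageTrack"))
  grs <- lapply(names(track$coverage), function(chrom) {
    v <- track$coverage[[chrom]]
    if (length(v) == 0L) return(GenomicRanges::GRanges())
    ir <- IRanges::IRanges(S4Vectors::start(v), S4Vectors::end(v))
    val <- S4Vectors::runValue(v)
    keep <- val != 0
    if (!any(keep)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, ir[keep],
                           score = val[keep] * track$scaling_factor)
  })
  gr <- do.call(c, c(grs, list(GenomicRanges::GRanges())))
  if (length(gr) == 0L) {
    file.create(out)
  } else {
    rtracklayer::export(gr, out, format = "bedGraph")
  }
  invisible(out)
}

#' Merge coverage tracks into a union table
#'
#' Position-wise union of several tracks (the `bedtools unionbedg` layout):
#' the genome is cut at every interval boundary of every track and each
#' resulting interval reports one scaled value per track.
#'
#' @param tracks named list of [coverage_track()] objects.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open, as in
#'   bedgraph) and one value column per track.
#' @export
merge_coverage <- function(tracks) {
  stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$coverage))))
  out <- list()
  for (chrom in chroms) {
    covs <- lapply(tracks, function(t) t$coverage[[chrom]])
    lens <- vapply(covs, function(v) if (is.null(v)) 0L else length(v), integer(1))
    n <- max(lens)
    if (n == 0L) next
    mat <- vapply(seq_along(covs), function(i) {
      v <- covs[[i]]
      x <- if (is.null(v)) numeric(n) else
        c(as.numeric(v), numeric(n - length(v)))
      x * tracks[[i]]$scaling_factor
    }, numeric(n))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = n)
    key <- apply(mat, 1, paste, collapse = "\r")
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    rows <- mat[ends, , drop = FALSE]
    keep <- rowSums(rows != 0) > 0
    df <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                     rows[keep, , drop = FALSE])
    names(df)[-(1:3)] <- names(tracks)
    out[[chrom]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
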