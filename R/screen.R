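#' Small-RNA/mRNA enrichment ratio
#'
#' The screen's y-axis value: abundance of 23-29 nt RNAs mapping to a
#' gene's exons (TPM) relative to the gene's mRNA abundance (TPM). Genes
#' at or below the retention threshold are dominated by mRNA decay
#' fragments and are excluded from the piRNA host screen.
#'
#' @param srna_tpm,mrna_tpm numeric vectors (matched genes).
#' @param pseudo pseudocount added to both numerator and denominator.
#' @param threshold retention threshold (strict `>`).
#' @return data.frame with `ratio` and `retain`.
#' @export
enrichment_ratio <- function(srna_tpm, mrna_tpm, pseudo = 0.5, threshold = 10) {
  stopifnot(all(srna_tpm >= 0), all(mrna_tpm >= 0))
  ratio <- (srna_tpm + pseudo) / (mrna_tpm + pseudo)
  data.frame(ratio = ratio, retain = ratio > threshold)
}

#' Read-length profile of a gene (18-29 nt window)
#'
#' Length proportions are computed within 18-29 nt reads; with several
#' libraries the per-library proportion vectors are averaged. The profile
#' peaks like a piRNA population when the modal length falls in 24-26 nt;
#' decay-fragment profiles are broad across 18-29 nt.
#'
#' @param lengths integer vector of read lengths, or a list of such vectors
#'   (one per library) to be averaged.
#' @param range length window (inclusive).
#' @return list with `proportions` (named numeric over the window),
#'   `peak_24_26` (logical), `peak_mass` (summed 24-26 proportion) and
#'   `n_reads`.
#' @export
size_profile <- function(lengths, range = 18:29) {
  libs <- if (is.list(lengths)) lengths else list(lengths)
  props <- lapply(libs, function(l) {
    l <- l[l >= min(range) & l <= max(range)]
    if (length(l) == 0L) return(NULL)
    as.numeric(table(factor(l, levels = range))) / length(l)
  })
  props <- props[!vapply(props, is.null, logical(1))]
  n <- sum(vapply(libs, length, integer(1)))
  if (length(props) == 0L)
    return(list(proportions = setNames(rep(NA_real_, length(range)),
                                       range),
                peak_24_26 = NA, peak_mass = NA_real_, n_reads = 0L))
  p <- setNames(Reduce(`+`, props) / length(props), range)
  peak_at <- as.integer(names(p)[which.max(p)])
  list(proportions = p, peak_24_26 = peak_at %in% 24:26,
       peak_mass = sum(p[as.character(24:26)]), n_reads = n)
}

#' Positional nucleotide probabilities of reads
#'
#' Empirical base probabilities at read positions 1..23 (the shared prefix
#' of 23-29 nt reads), the quantity behind a piRNA sequence logo. The 5' U
#' bias of Piwi/Aub-bound piRNAs appears as a high T probability (DNA
#' alphabet) at position 1.
#'
#' @param reads character vector of read sequences (>= 23 nt each), or a
#'   data.frame with `sequence` and `count` columns.
#' @param positions positions to profile.
#' @return matrix positions x c(A,C,G,T) of probabilities; attribute
#'   `u1` holds the position-1 U(T) fraction.
#' @export
nt_probability <- function(reads, positions = 1:23) {
  if (is.data.frame(reads)) {
    seqs <- rep(reads$sequence, reads$count)
  } else seqs <- reads
  seqs <- dna_upper(seqs)
  stopifnot(all(nchar(seqs) >= max(positions)))
  mat <- matrix(0, nrow = length(positions), ncol = 4,
                dimnames = list(positions, c("A", "C", "G", "T")))
  for (i in seq_along(positions)) {
    b <- substr(seqs, positions[i], positions[i])
    tab <- table(factor(b, levels = c("A", "C", "G", "T")))
    mat[i, ] <- as.numeric(tab) / length(seqs)
  }
  attr(mat, "u1") <- mat[1, "T"]
  mat
}

#' Immunoprecipitation enrichment (bound/total)
#'
#' Ratio of a gene's mean abundance across IP libraries to its abundance in
#' total RNA, with a pseudocount guarding empty denominators.
#'
#' @param total_tpm numeric vector of per-gene abundance in total RNA.
#' @param ip_tpm list of numeric vectors (one per IP library) or a single
#'   vector; the mean across libraries is used.
#' @param pseudo pseudocount.
#' @return numeric vector of enrichment ratios.
#' @export
ip_enrichment <- function(total_tpm, ip_tpm, pseudo = 0.5) {
  if (!is.list(ip_tpm)) ip_tpm <- list(ip_tpm)
  ip_mean <- Reduce(`+`, ip_tpm) / length(ip_tpm)
  (ip_mean + pseudo) / (total_tpm + pseudo)
}

#' Tier host genes by Aub-IP abundance
#'
#' Strict-inequality tiers of the mean Aub-IP RPM, following the screen's
#' RPM > 100 and RPM > 10 gene groups.
#'
#' @param aub_rpm numeric vector of mean Aub-IP RPM per gene.
#' @param thresholds descending strict thresholds.
#' @return factor with levels `rpm_gt_100`, `rpm_gt_10`, `below`.
#' @export
tier_hosts <- function(aub_rpm, thresholds = c(100, 10)) {
  labs <- c(paste0("rpm_gt_", thresholds), "below")
  idx <- vapply(aub_rpm, function(r) {
    hit <- which(r > thresholds)
    if (length(hit)) hit[1] else length(thresholds) + 1L
  }, integer(1))
  factor(labs[idx], levels = labs)
}

#' Region density of reads over a gene
#'
#' Read count divided by region length for 5'UTR, CDS and 3'UTR, plus
#' relative densities normalized to sum to one. CDS-piRNA host genes show
#' CDS-dominated density, unlike classical genic piRNA producers whose
#' reads concentrate in the 3'UTR.
#'
#' @param gene a [gene_model()].
#' @param counts named numeric, counts per region (`utr5`, `cds`, `utr3`).
#' @return data.frame with `region`, `length`, `count`, `density`,
#'   `relative`; zero-length regions carry `NA` density and are flagged.
#' @export
region_density <- function(gene, counts) {
  len <- region_lengths(gene)
  cnt <- counts[c("utr5", "cds", "utr3")]
  dens <- ifelse(len > 0, as.numeric(cnt) / len, NA_real_)
  tot <- sum(dens, na.rm = TRUE)
  rel <- if (tot > 0) ifelse(is.na(dens), NA_real_, dens / tot)
    else rep(NA_real_, 3)
  data.frame(region = c("utr5", "cds", "utr3"), length = as.numeric(len),
             count = as.numeric(cnt), density = dens, relative = rel,
             flagged = len == 0, stringsAsFactors = FALSE)
}

#' Paired comparison of region densities across a gene cohort
#'
#' Two-tailed paired t-test of per-gene relative densities between two
#' regions (CDS vs each UTR in the screen's box plots).
#'
#' @param density_list list of [region_density()] outputs, one per gene.
#' @param region_a,region_b regions to compare.
#' @return `htest` from [stats::t.test()].
#' @export
region_density_test <- function(density_list, region_a = "cds",
                                region_b = "utr3") {
  a <- vapply(density_list, function(d) d$relative[d$region == region_a],
              numeric(1))
  b <- vapply(density_list, function(d) d$relative[d$region == region_b],
              numeric(1))
  keep <- !is.na(a) & !is.na(b)
  t.test(a[keep], b[keep], paired = TRUE, alternative = "two.sided")
}

#' Sense-strand fraction of a gene's reads
#'
#' @param sense logical vector (read strand equals gene strand), or counts
#'   via `sense_count`/`total`.
#' @param sense_count,total alternative count interface.
#' @return fraction in `[0,1]`, `NA` when no reads (flagged via attribute).
#' @export
sense_fraction <- function(sense = NULL, sense_count = NULL, total = NULL) {
  if (!is.null(sense)) {
    sense_count <- sum(sense); total <- length(sense)
  }
  if (total == 0L) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sense_count / total
}

#' Count exon-exon junction-spanning reads
#'
#' A read is a junction read when it matches the spliced transcript exactly,
#' crosses an exon-exon boundary with at least `anchor` nt on each side, and
#' has no equal-quality contiguous genomic placement.
#'
#' @param reads character vector of read sequences.
#' @param gene_id gene to test.
#' @param assets the [genome_assets()] bundle (supplies transcript,
#'   junction offsets and the genome for the contiguous-placement check).
#' @param anchor minimum anchor length.
#' @return integer count; attribute `which` marks the qualifying reads.
#' @export
junction_reads <- function(reads, gene_id, assets, anchor = 4L) {
  tx <- assets$transcripts[[gene_id]]
  if (is.null(tx)) stop("unknown gene ", gene_id)
  seqs <- dna_upper(reads)
  txset <- Biostrings::DNAStringSet(setNames(tx$sequence, gene_id))
  th <- exact_hits(unique(seqs), txset, strands = "+")
  genome_hit <- exact_hits(unique(seqs), assets$sequences)
  has_genomic <- unique(genome_hit$read)
  ok_seq <- logical(length(unique(seqs)))
  for (i in seq_len(nrow(th))) {
    j <- tx$junctions
    crosses <- any(j >= th$start[i] + anchor - 1L & j <= th$end[i] - anchor)
    if (crosses && !(th$read[i] %in% has_genomic)) ok_seq[th$read[i]] <- TRUE
  }
  which_reads <- ok_seq[match(seqs, unique(seqs))]
  out <- sum(which_reads)
  attr(out, "which") <- which_reads
  out
}

#' Assemble per-gene screen records
#'
#' Computes, for every gene, the metrics of the CDS-piRNA host screen:
#' small-RNA/mRNA enrichment ratio, 18-29 nt size profile with 24-26 nt
#' peak test, positional nucleotide probabilities and 5' U fraction,
#' Aub/Piwi IP enrichment, mean Aub-IP RPM and tier, region densities,
#' sense fraction and junction-read count.
#'
#' @param total_profiles list of [quantify()] profiles of total libraries
#'   (23-29 nt window).
#' @param total_assignments list of assignment tables matching
#'   `total_profiles` but classified in the 18-29 nt window (size-profile
#'   mode); pass the 23-29 tables to profile the analysis window only.
#' @param aub_profiles,piwi_profiles lists of IP-library profiles.
#' @param mrna_tpm named numeric of per-gene mRNA TPM (mean over mRNA
#'   libraries).
#' @param assets the [genome_assets()] bundle.
#' @param pseudo pseudocount for ratio metrics.
#' @return data.frame, one `GeneScreenRecord` row per gene.
#' @export
screen_hosts <- function(total_profiles, total_assignments,
                         aub_profiles, piwi_profiles = NULL,
                         mrna_tpm, assets, pseudo = 0.5) {
  gids <- names(assets$genes)
  get_gene_vec <- function(profiles, col) {
    m <- vapply(profiles, function(p)
      p$genes[[col]][match(gids, p$genes$gene_id)], numeric(length(gids)))
    rowMeans(matrix(m, nrow = length(gids)))
  }
  srna_tpm <- get_gene_vec(total_profiles, "tpm")
  mrna <- mrna_tpm[gids]
  mrna[is.na(mrna)] <- 0
  er <- enrichment_ratio(srna_tpm, mrna, pseudo = pseudo)

  aub_tpm <- get_gene_vec(aub_profiles, "tpm")
  aub_rpm <- get_gene_vec(aub_profiles, "rpm")
  aub_enr <- ip_enrichment(srna_tpm, list(aub_tpm), pseudo = pseudo)
  piwi_enr <- if (!is.null(piwi_profiles))
    ip_enrichment(srna_tpm, list(get_gene_vec(piwi_profiles, "tpm")),
                  pseudo = pseudo)
    else rep(NA_real_, length(gids))

  # per-gene length profiles and 5'U from the (wide-window) assignments
  lengths_by_gene <- lapply(total_assignments, function(a) {
    g <- a[a$class == "genic", c("gene_id", "length")]
    split(g$length, factor(g$gene_id, levels = gids))
  })
  seqs_by_gene <- lapply(total_assignments, function(a) {
    g <- a[a$class == "genic" & a$length >= 23L, c("gene_id", "sequence")]
    split(g$sequence, factor(g$gene_id, levels = gids))
  })

  peak <- logical(length(gids)); peak_mass <- numeric(length(gids))
  u1 <- rep(NA_real_, length(gids)); n_reads <- integer(length(gids))
  for (i in seq_along(gids)) {
    sp <- size_profile(lapply(lengths_by_gene, `[[`, i))
    peak[i] <- isTRUE(sp$peak_24_26); peak_mass[i] <- sp$peak_mass
    n_reads[i] <- sp$n_reads
    seqs <- unlist(lapply(seqs_by_gene, `[[`, i), use.names = FALSE)
    if (length(seqs))
      u1[i] <- attr(nt_probability(seqs, positions = 1L), "u1")
  }

  counts_region <- function(col) get_gene_vec(total_profiles, col)
  cnt <- get_gene_vec(total_profiles, "count")
  sense_cnt <- get_gene_vec(total_profiles, "sense_count")
  junc <- get_gene_vec(total_profiles, "junction_count")
  dens <- lapply(seq_along(gids), function(i)
    region_density(assets$genes[[gids[i]]],
                   c(utr5 = counts_region("count_utr5")[i],
                     cds = counts_region("count_cds")[i],
                     utr3 = counts_region("count_utr3")[i])))
  rel_cds <- vapply(dens, function(d) d$relative[d$region == "cds"], numeric(1))
  rel_utr3 <- vapply(dens, function(d) d$relative[d$region == "utr3"], numeric(1))
  rel_utr5 <- vapply(dens, function(d) d$relative[d$region == "utr5"], numeric(1))

  data.frame(
    gene_id = gids, srna_tpm_23_29 = srna_tpm, mrna_tpm = as.numeric(mrna),
    enrichment_ratio = er$ratio, retain = er$retain,
    n_reads_18_29 = n_reads, peak_24_26 = peak, peak_mass_24_26 = peak_mass,
    u1_fraction = u1,
    aub_enrichment = aub_enr, piwi_enrichment = piwi_enr,
    aub_rpm = aub_rpm, tier = tier_hosts(aub_rpm),
    rel_density_utr5 = rel_utr5, rel_density_cds = rel_cds,
    rel_density_utr3 = rel_utr3,
    sense_fraction = ifelse(cnt > 0, sense_cnt / cnt, NA_real_),
    junction_count = junc,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Call CDS-piRNA host genes
#'
#' Composite call over the screen metrics: a gene is called when its
#' small-RNA/mRNA enrichment ratio exceeds `ratio_min`, its 18-29 nt size
#' profile peaks at 24-26 nt, its 5' U fraction reaches `u1_min`, and its
#' Aub IP enrichment reaches `e_min`.
#'
#' @param records output of [screen_hosts()].
#' @param ratio_min,u1_min,e_min thresholds (ratio strict, others `>=`).
#' @return `records` with an added logical `call` column.
#' @export
call_hosts <- function(records, ratio_min = 10, u1_min = 0.5, e_min = 2) {
  records$call <- records$enrichment_ratio > ratio_min &
    records$peak_24_26 %in% TRUE &
    !is.na(records$u1_fraction) & records$u1_fraction >= u1_min &
    !is.na(records$aub_enrichment) & records$aub_enrichment >= e_min
  records
}
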