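#' Simulation specification for synthetic testis small-RNA data
#'
#' Defines the study conditions emulated by the generator: a toy genome with
#' protein-coding genes, piRNA clusters (TE-fragment rich), transposon
#' consensus sequences and non-piRNA loci; planted CDS-piRNA host genes with
#' a 24-26 nt length mode, 5' U bias and sense-strand dominance; an
#' mRNA-level-proportional decay-fragment background with a broad 18-29 nt
#' profile; Aub/Piwi-IP enrichment; trigger-responder pairs with an exact
#' 10-nt 5'-to-5' overlap; phased read trains; and per-class depletion
#' factors for mutant libraries.
#'
#' Any field can be overridden; defaults are the package's reference
#' conditions (see the methods vignette for the rationale of each choice).
#'
#' @param ... named overrides of the defaults listed below.
#' @return an object of class `SimulationSpec`.
#' @export
simulation_spec <- function(...) {
  spec <- list(
    seed = 1L,
    # genome geometry
    n_chroms = 2L, chrom_length = 320000L,
    n_host_genes = 20L, n_piwi_genes = 2L, n_decoy_genes = 200L,
    utr5_range = c(100L, 200L), cds_codon_range = c(200L, 400L),
    utr3_range = c(200L, 400L), n_intron_range = c(1L, 3L),
    intron_range = c(60L, 120L), intergenic_gap = c(80L, 250L),
    n_cluster_loci = 3L, cluster_length = 8000L,
    n_te_families = 4L, te_length_range = c(2500L, 4000L),
    n_non_pirna_loci = 20L, non_pirna_length_range = c(120L, 1500L),
    plant_repeat_gene = TRUE, repeat_unit_length = 300L, repeat_copies = 2L,
    # expression
    mrna_meanlog = log(20), mrna_sdlog = 1,
    host_mrna_factor = 0.15,
    # library composition (read counts per library before size selection)
    class_counts = c(host = 12000L, piwi_gene = 2000L, decay = 58000L,
                     cluster = 108000L, TE = 34000L, non_piRNA = 15000L),
    # piRNA population
    pirna_length_probs = c(`23` = 0.05, `24` = 0.25, `25` = 0.30,
                           `26` = 0.25, `27` = 0.10, `28` = 0.04, `29` = 0.01),
    first_nt_U_probability = 0.8,
    sense_fraction = 0.95,
    antisense_host_sense_fraction = 0.1,
    junction_read_fraction = 0.02,
    junction_anchor = 4L,
    host_region_weights = c(utr5 = 0.05, cds = 0.85, utr3 = 0.10),
    piwi_region_weights = c(utr5 = 0.05, cds = 0.15, utr3 = 0.80),
    decay_length_range = c(18L, 29L),
    # broad 18-29 nt decay profile sloping toward short fragments, as decay
    # intermediates do; NULL = linearly decreasing weights over the range
    decay_length_probs = NULL,
    # IP enrichment factors per class (bound/total sampling weight)
    ip_factors = list(
      aub_ip = c(host = 10, piwi_gene = 1, decay = 1, cluster = 10,
                 TE = 10, non_piRNA = 1),
      piwi_ip = c(host = 1, piwi_gene = 10, decay = 1, cluster = 10,
                  TE = 10, non_piRNA = 1)),
    # trigger / responder planting
    n_triggers = 4L, trigger_length = 22L,
    responder_group_counts = c(`24` = 25L, `25` = 20L, `26` = 15L),
    # phased trains
    n_phased_genes = 5L, trains_per_gene = 30L, max_train_reads = 6L,
    # mutant conditions: per-class library-weight multipliers
    mutant_depletion = c(host = 0.6, piwi_gene = 1, decay = 1, cluster = 1,
                         TE = 1, non_piRNA = 1),
    # mRNA-seq / degradome
    mrna_read_length = 75L, mrna_depth = 50000L,
    degradome_read_length = 25L, degradome_background = 12000L,
    n_cleavage_targets = 4L, cleavage_guide_length = 25L,
    cleavage_guide_reads = 30L, degradome_reads_per_site = 60L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown SimulationSpec field(s): ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  stopifnot(spec$first_nt_U_probability >= 0, spec$first_nt_U_probability <= 1,
            all(spec$class_counts >= 0), all(spec$mutant_depletion > 0),
            abs(sum(spec$pirna_length_probs) - 1) < 1e-8)
  structure(spec, class = "SimulationSpec")
}

# sample an integer uniformly in [range[1], range[2]]
runif_int <- function(n, range) {
  range[1] + as.integer(floor(runif(n) * (range[2] - range[1] + 1L)))
}

#' Build toy genome assets with planted ground truth
#'
#' Generates random chromosomes and places non-overlapping gene models,
#' piRNA clusters with embedded TE-consensus fragments, and non-piRNA loci;
#' selects host, Piwi-host and decoy genes; plants trigger small RNAs with
#' their target sites, cleavage guides with degradome target sites, and
#' (optionally) one host gene carrying a ~300-nt tandem repeat inside its
#' CDS so that intragenic multimapping is exercised. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return a [genome_assets()] bundle; `attr(assets, "ground_truth")` lists
#'   host/decoy gene sets, per-gene mRNA levels, trigger and cleavage-guide
#'   records.
#' @export
build_toy_assets <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  with_seed(spec$seed, build_toy_assets_impl(spec))
}

build_toy_assets_impl <- function(spec) {
  n_genes <- spec$n_host_genes + spec$n_piwi_genes + spec$n_decoy_genes
  chrom_names <- sprintf("chr%d", seq_len(spec$n_chroms))
  seqs <- Biostrings::DNAStringSet(random_dna(spec$n_chroms, spec$chrom_length))
  names(seqs) <- chrom_names
  chr_seq_chars <- lapply(seq_along(seqs), function(i)
    strsplit(as.character(seqs[[i]]), "")[[1]])
  names(chr_seq_chars) <- chrom_names

  # allocate loci round-robin across chromosomes, left to right
  cursor <- setNames(rep(1L, spec$n_chroms), chrom_names)
  place <- function(chrom, len) {
    gap <- runif_int(1L, spec$intergenic_gap)
    start <- cursor[[chrom]] + gap
    if (start + len - 1L > spec$chrom_length)
      stop("chromosome too short to place loci; increase chrom_length ",
           "or reduce locus counts")
    cursor[[chrom]] <<- start + len
    start
  }

  repeat_gene_idx <- if (spec$plant_repeat_gene && spec$n_host_genes > 0) 1L
    else 0L
  genes <- vector("list", n_genes)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  roles <- c(rep("host", spec$n_host_genes),
             rep("piwi", spec$n_piwi_genes),
             rep("decoy", spec$n_decoy_genes))
  # shuffle gene order along the genome so roles are not positionally clumped
  order_idx <- sample.int(n_genes)
  for (k in seq_len(n_genes)) {
    i <- order_idx[k]
    chrom <- chrom_names[1L + (k - 1L) %% spec$n_chroms]
    utr5 <- runif_int(1L, spec$utr5_range)
    cds_len <- 3L * runif_int(1L, spec$cds_codon_range)
    utr3 <- runif_int(1L, spec$utr3_range)
    is_repeat <- (i == repeat_gene_idx)
    if (is_repeat)
      cds_len <- max(cds_len,
                     spec$repeat_unit_length * (spec$repeat_copies + 1L))
    tx_len <- utr5 + cds_len + utr3
    n_intr <- runif_int(1L, spec$n_intron_range)
    intr_len <- runif_int(n_intr, spec$intron_range)
    # junction positions inside the transcript, kept off region boundaries
    jx <- sort(sample(seq(30L, tx_len - 30L), n_intr))
    while (any(diff(c(0L, jx, tx_len)) < 30L))
      jx <- sort(sample(seq(30L, tx_len - 30L), n_intr))
    span <- tx_len + sum(intr_len)
    gstart <- place(chrom, span)
    strand <- sample(c("+", "-"), 1L)
    # exon genomic intervals from transcript blocks (+ strand layout first)
    block_len <- diff(c(0L, jx, tx_len))
    if (strand == "-") block_len <- rev(block_len)
    ex_start <- gstart + c(0L, cumsum(head(block_len, -1L) + intr_len))
    exons <- IRanges::IRanges(ex_start, width = block_len)
    # project transcript regions (utr5 | cds | utr3) onto the genome
    tx_regions <- list(utr5 = c(1L, utr5), cds = c(utr5 + 1L, utr5 + cds_len),
                       utr3 = c(utr5 + cds_len + 1L, tx_len))
    proj <- project_tx_regions(tx_regions, exons, strand)
    gm <- gene_model(gene_ids[i], chrom, strand, exons,
                     cds = proj$cds, utr5 = proj$utr5, utr3 = proj$utr3)
    genes[[i]] <- gm
    # write the repeat unit into the genome inside the CDS
    if (is_repeat) {
      unit <- random_dna(1L, spec$repeat_unit_length)
      rep_seq <- strsplit(strrep(unit, spec$repeat_copies), "")[[1]]
      tx_off <- utr5 + 10L   # repeat block starts shortly after the CDS start
      gpos <- tx_block_genomic_positions(gm, tx_off, length(rep_seq))
      if (!is.null(gpos)) {
        ins <- if (strand == "+") rep_seq else
          rev(comp_base(rep_seq))
        chr_seq_chars[[chrom]][gpos] <- ins
      }
    }
  }
  # rebuild sequences after repeat insertion
  seqs <- Biostrings::DNAStringSet(vapply(chr_seq_chars, paste,
                                          character(1), collapse = ""))
  names(seqs) <- chrom_names

  # TE consensus families; clusters embed fragments of them
  te_len <- runif_int(spec$n_te_families, spec$te_length_range)
  te <- Biostrings::DNAStringSet(random_dna(spec$n_te_families, te_len))
  names(te) <- sprintf("TE%d", seq_len(spec$n_te_families))
  cl_chrom <- character(0); cl_start <- integer(0)
  for (ci in seq_len(spec$n_cluster_loci)) {
    chrom <- chrom_names[1L + (ci - 1L) %% spec$n_chroms]
    cstart <- place(chrom, spec$cluster_length)
    # drop ~3 TE fragments of 500 nt into the cluster body
    if (spec$n_te_families > 0) {
      for (f in seq_len(3L)) {
        fam <- sample(spec$n_te_families, 1L)
        flen <- min(500L, te_len[fam])
        fstart <- sample(te_len[fam] - flen + 1L, 1L)
        frag <- substr(as.character(te[[fam]]), fstart, fstart + flen - 1L)
        at <- cstart + sample(spec$cluster_length - flen, 1L) - 1L
        if (sample(c(TRUE, FALSE), 1L)) frag <- revcomp(frag)
        chr_seq_chars[[chrom]][at:(at + flen - 1L)] <- strsplit(frag, "")[[1]]
      }
    }
    cl_chrom <- c(cl_chrom, chrom); cl_start <- c(cl_start, cstart)
  }
  clusters <- GenomicRanges::GRanges(cl_chrom,
    IRanges::IRanges(cl_start, width = spec$cluster_length))
  seqs <- Biostrings::DNAStringSet(vapply(chr_seq_chars, paste,
                                          character(1), collapse = ""))
  names(seqs) <- chrom_names

  np_classes <- c("rRNA", "tRNA", "miRNA", "snRNA", "snoRNA")
  np <- GenomicRanges::GRanges()
  if (spec$n_non_pirna_loci > 0) {
    np_len <- runif_int(spec$n_non_pirna_loci, spec$non_pirna_length_range)
    np_chrom <- chrom_names[1L + (seq_len(spec$n_non_pirna_loci) - 1L) %%
                              spec$n_chroms]
    np_start <- vapply(seq_len(spec$n_non_pirna_loci), function(i)
      place(np_chrom[i], np_len[i]), integer(1))
    np <- GenomicRanges::GRanges(np_chrom,
      IRanges::IRanges(np_start, width = np_len))
    np$class <- np_classes[1L + (seq_len(spec$n_non_pirna_loci) - 1L) %%
                             length(np_classes)]
  }

  assets <- genome_assets(seqs, genes, clusters = clusters, te_consensus = te,
                          non_pirna = np)

  # mRNA levels: decoys lognormal; host/piwi-host steady-state mRNA reduced
  # by piRNA-directed cleavage
  levels <- rlnorm(n_genes, spec$mrna_meanlog, spec$mrna_sdlog)
  levels[roles != "decoy"] <- levels[roles != "decoy"] * spec$host_mrna_factor
  names(levels) <- gene_ids

  host_ids <- gene_ids[roles == "host"]
  piwi_ids <- gene_ids[roles == "piwi"]
  decoy_ids <- gene_ids[roles == "decoy"]

  # the antisense repeat gene follows its own (miRNA-directed) route and is
  # kept free of planted sense responders and junction reads
  sense_hosts <- setdiff(host_ids,
    if (repeat_gene_idx > 0) gene_ids[repeat_gene_idx] else character(0))
  triggers <- plant_trigger_sites(assets, sense_hosts, spec$n_triggers,
                                  spec$trigger_length, "si")
  guides <- plant_trigger_sites(assets, decoy_ids, spec$n_cleavage_targets,
                                spec$cleavage_guide_length, "guide")
  if (nrow(guides)) guides$count <- spec$cleavage_guide_reads
  assets$triggers <- triggers

  attr(assets, "ground_truth") <- list(
    roles = setNames(roles, gene_ids),
    host_genes = host_ids, piwi_genes = piwi_ids, decoy_genes = decoy_ids,
    repeat_gene = if (repeat_gene_idx > 0) gene_ids[repeat_gene_idx]
      else NA_character_,
    sense_hosts = sense_hosts,
    phased_genes = head(setdiff(host_ids,
      if (repeat_gene_idx > 0) gene_ids[repeat_gene_idx] else character(0)),
      spec$n_phased_genes),
    mrna_levels = levels,
    triggers = triggers,
    cleavage_guides = guides)
  assets
}

# genomic positions (ordered along the transcript) of a transcript block;
# NULL if the block is not contained in a single run of exons
tx_block_genomic_positions <- function(gene, tx_start, len) {
  tx_pos <- seq(tx_start, tx_start + len - 1L)
  tx <- list(exon_tx_end = cumsum(if (gene$strand == "+")
      IRanges::width(gene$exons) else rev(IRanges::width(gene$exons))),
    exon_order = if (gene$strand == "+") seq_along(gene$exons)
      else rev(seq_along(gene$exons)))
  tx$exon_tx_start <- c(1L, head(tx$exon_tx_end, -1L) + 1L)
  if (max(tx_pos) > max(tx$exon_tx_end)) return(NULL)
  vapply(tx_pos, function(p) tx_to_genome(gene, tx, p), numeric(1))
}

# project transcript-coordinate regions onto genomic IRanges via the exons
project_tx_regions <- function(tx_regions, exons, strand) {
  w <- IRanges::width(exons)
  if (strand == "+") {
    ends <- cumsum(w); starts <- c(1L, head(ends, -1L) + 1L)
    g_start <- IRanges::start(exons); dir <- 1L
    ex_idx <- seq_along(exons)
  } else {
    ends <- cumsum(rev(w)); starts <- c(1L, head(ends, -1L) + 1L)
    g_start <- rev(IRanges::end(exons)); dir <- -1L
    ex_idx <- rev(seq_along(exons))
  }
  out <- lapply(tx_regions, function(r) {
    pieces <- list()
    for (e in seq_along(ends)) {
      lo <- max(r[1], starts[e]); hi <- min(r[2], ends[e])
      if (lo > hi) next
      gp1 <- g_start[e] + dir * (lo - starts[e])
      gp2 <- g_start[e] + dir * (hi - starts[e])
      pieces[[length(pieces) + 1L]] <-
        IRanges::IRanges(min(gp1, gp2), max(gp1, gp2))
    }
    if (length(pieces)) IRanges::reduce(do.call(c, pieces)) else IRanges::IRanges()
  })
  out
}

# choose trigger/guide target sites on transcripts; each guide is the exact
# reverse complement of a transcript window that lies within one exon and
# whose cleavage-position base is T (so responders begin with U, as secondary
# piRNAs do); cleavage falls opposite guide nt 10/11
plant_trigger_sites <- function(assets, candidate_genes, n, guide_len, prefix) {
  if (n == 0L) return(data.frame())
  genes <- sample(rep(candidate_genes, length.out = n))
  rows <- lapply(seq_len(n), function(i) {
    g <- genes[i]
    tx <- assets$transcripts[[g]]
    txseq <- strsplit(tx$sequence, "")[[1]]
    bounds <- cbind(tx$exon_tx_start, tx$exon_tx_end)
    for (attempt in 1:200) {
      e <- sample(nrow(bounds), 1L)
      if (bounds[e, 2] - bounds[e, 1] + 1L < guide_len + 2L) next
      p <- sample(seq(bounds[e, 1], bounds[e, 2] - guide_len + 1L), 1L)
      s <- p + guide_len - 10L          # cleavage: 5' end of the 3' fragment
      if (s + 29L > bounds[e, 2]) next  # responders must fit in the exon
      if (txseq[s] != "T") next
      window <- substr(tx$sequence, p, p + guide_len - 1L)
      return(data.frame(trigger_id = sprintf("%s%d", prefix, i),
                        sequence = revcomp(window), gene_id = g,
                        tx_start = p, cleavage_tx_pos = s,
                        stringsAsFactors = FALSE))
    }
    stop("could not place trigger site on gene ", g)
  })
  do.call(rbind, rows)
}

# --- read sampling machinery ------------------------------------------------

# per-gene candidate 5' start table: transcript positions, their exonic
# head-room (distance to exon end) and first base
gene_start_table <- function(assets, gene_id) {
  tx <- assets$transcripts[[gene_id]]
  gm <- assets$genes[[gene_id]]
  txseq <- strsplit(tx$sequence, "")[[1]]
  n <- length(txseq)
  exon_of <- findInterval(seq_len(n) - 1L, c(0L, tx$exon_tx_end))
  headroom <- tx$exon_tx_end[exon_of] - seq_len(n) + 1L
  leftroom <- seq_len(n) - tx$exon_tx_start[exon_of] + 1L
  rl <- region_lengths(gm)
  region <- rep("cds", n)
  region[seq_len(rl[["utr5"]])] <- "utr5"
  if (rl[["utr3"]] > 0) region[(n - rl[["utr3"]] + 1L):n] <- "utr3"
  list(tx = tx, gm = gm, seq = txseq, headroom = headroom,
       leftroom = leftroom, region = region, n = n)
}

# draw `n_reads` sense/antisense piRNA-like reads from one gene with a
# planted 5'U probability and region weights; returns transcript-space spans
draw_gene_reads <- function(tab, n_reads, spec, sense_fraction) {
  if (n_reads == 0L)
    return(data.frame(tx_start = integer(0), len = integer(0),
                      sense = logical(0)))
  lens <- as.integer(names(spec$pirna_length_probs))[
    sample.int(length(spec$pirna_length_probs), n_reads, replace = TRUE,
               prob = spec$pirna_length_probs)]
  sense <- runif(n_reads) < sense_fraction
  wantU <- runif(n_reads) < spec$first_nt_U_probability
  rw <- spec$host_region_weights
  region <- names(rw)[sample.int(length(rw), n_reads, replace = TRUE, prob = rw)]
  tx_start <- integer(n_reads)
  for (k in seq_len(n_reads)) {
    L <- lens[k]
    if (sense[k]) {
      ok <- tab$region == region[k] & tab$headroom >= L
      base <- tab$seq
      target <- "T"
    } else {
      # antisense read: 5' end at transcript position e, span [e-L+1, e];
      # 5' base is the complement of the transcript base at e
      ok <- tab$region == region[k] & tab$leftroom >= L
      base <- tab$seq
      target <- "A"
    }
    isU <- base == target
    cand <- if (wantU[k]) which(ok & isU) else which(ok & !isU)
    if (!length(cand)) cand <- which(ok)
    if (!length(cand)) cand <- which(tab$headroom >= L & tab$leftroom >= 1L)
    p <- cand[sample_per_element(length(cand))]
    tx_start[k] <- if (sense[k]) p else p - L + 1L
  }
  data.frame(tx_start = tx_start, len = lens, sense = sense)
}

# sequence of a transcript-space span, read on the sense or antisense strand
span_sequence <- function(tab, tx_start, len, sense) {
  s <- substr(tab$tx$sequence, tx_start, tx_start + len - 1L)
  if (sense) s else revcomp(s)
}

# genomic 5' position and strand of a transcript-space read
span_genomic <- function(tab, tx_start, len, sense) {
  p5_tx <- if (sense) tx_start else tx_start + len - 1L
  g5 <- tx_to_genome(tab$gm, tab$tx, p5_tx)
  strand <- if (sense) tab$gm$strand else setdiff(c("+", "-"), tab$gm$strand)
  c(pos = g5, strand = strand)
}

#' Simulate a small-RNA sequencing library
#'
#' Draws reads per class (planted host-gene piRNAs including responder,
#' phased-train and junction reads; Piwi-host 3'UTR piRNAs; decay
#' fragments scaling with mRNA level; cluster and TE piRNAs; non-piRNA
#' fragments), applies the library type's IP enrichment factors and the
#' condition's per-class depletion factors to the class weights, and emits
#' reads with a per-read truth table. Identical `spec` + `seed` give
#' byte-identical output.
#'
#' @param assets output of [build_toy_assets()].
#' @param spec the [simulation_spec()] used to build `assets`.
#' @param library `"total"`, `"aub_ip"` or `"piwi_ip"`.
#' @param condition `"wt"` or `"mutant"` (applies `spec$mutant_depletion`).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `class`, `gene_id`/`locus`, `sense`, `length`,
#'   `tx_start`, `is_junction`, `is_phased`, `trigger_id`, `library`).
#' @export
simulate_srna_library <- function(assets, spec,
                                  library = c("total", "aub_ip", "piwi_ip"),
                                  condition = c("wt", "mutant"),
                                  seed = spec$seed) {
  library <- match.arg(library)
  condition <- match.arg(condition)
  truth_meta <- attr(assets, "ground_truth")
  stopifnot(!is.null(truth_meta))
  with_seed(seed,
    simulate_srna_library_impl(assets, spec, library, condition, truth_meta))
}

simulate_srna_library_impl <- function(assets, spec, library, condition, gt) {
  weights <- as.numeric(spec$class_counts)
  names(weights) <- names(spec$class_counts)
  if (library != "total")
    weights <- weights * spec$ip_factors[[library]][names(weights)]
  if (condition == "mutant")
    weights <- weights * spec$mutant_depletion[names(weights)]
  depth <- sum(spec$class_counts)
  counts <- round(weights / sum(weights) * depth)

  parts <- list()

  # --- host-gene piRNAs (plain + responders + phased + junction) ----------
  # Each host gene's total piRNA output is allocated proportional to
  # mRNA level x exon length (precursor mass); responder, phased and
  # junction reads are carved out of the gene's own allocation so that the
  # library-type and condition factors scale every planted feature alike.
  n_host <- counts[["host"]]
  if (n_host > 0 && length(gt$host_genes)) {
    host_scale <- n_host / spec$class_counts[["host"]]
    ex_len <- vapply(assets$genes[gt$host_genes], exon_length, numeric(1))
    w <- gt$mrna_levels[gt$host_genes] * ex_len
    alloc <- as.integer(rmultinom(1, n_host, w))
    names(alloc) <- gt$host_genes
    used <- setNames(integer(length(alloc)), gt$host_genes)
    emit_host <- function(df) {
      parts[[length(parts) + 1L]] <<- df
      used[unique(df$gene_id)] <<- used[unique(df$gene_id)] +
        as.integer(table(factor(df$gene_id, levels = unique(df$gene_id))))
    }
    # responder reads: exact 10-nt 5'-to-5' overlap with each trigger
    if (nrow(gt$triggers %||% data.frame())) {
      for (i in seq_len(nrow(gt$triggers))) {
        tr <- gt$triggers[i, ]
        tab <- gene_start_table(assets, tr$gene_id)
        for (L in as.integer(names(spec$responder_group_counts))) {
          cnt <- round(spec$responder_group_counts[[as.character(L)]] *
                         host_scale)
          if (cnt == 0L) next
          emit_host(data.frame(
            class = "host", gene_id = tr$gene_id, locus = NA_character_,
            sequence = rep(span_sequence(tab, tr$cleavage_tx_pos, L, TRUE), cnt),
            sense = TRUE, length = L, tx_start = tr$cleavage_tx_pos,
            is_junction = FALSE, is_phased = FALSE,
            trigger_id = tr$trigger_id, stringsAsFactors = FALSE))
        }
      }
    }
    # phased trains: head-to-tail reads, next 5' one base past the last 3';
    # train extension prefers lengths whose downstream base is U (Zuc-like)
    for (g in gt$phased_genes) {
      tab <- gene_start_table(assets, g)
      n_trains <- max(round(spec$trains_per_gene * host_scale), 0L)
      for (t in seq_len(n_trains)) {
        start_cand <- which(tab$region == "cds" & tab$seq == "T" &
                              tab$headroom >= 29L * spec$max_train_reads)
        if (!length(start_cand))
          start_cand <- which(tab$region == "cds" & tab$seq == "T")
        if (!length(start_cand)) next
        p <- start_cand[sample_per_element(length(start_cand))]
        lens_avail <- as.integer(names(spec$pirna_length_probs))
        for (r in seq_len(spec$max_train_reads)) {
          nxt <- p + lens_avail
          okL <- lens_avail[nxt <= tab$n & tab$seq[pmin(nxt, tab$n)] == "T" &
                              tab$headroom[p] >= lens_avail]
          if (!length(okL)) {
            okL <- lens_avail[tab$headroom[p] >= lens_avail]
            if (!length(okL)) break
            L <- okL[sample_per_element(length(okL))]
            last <- TRUE
          } else {
            pr <- spec$pirna_length_probs[as.character(okL)]
            L <- okL[sample.int(length(okL), 1L, prob = pr)]
            last <- FALSE
          }
          emit_host(data.frame(
            class = "host", gene_id = g, locus = NA_character_,
            sequence = span_sequence(tab, p, L, TRUE),
            sense = TRUE, length = L, tx_start = p,
            is_junction = FALSE, is_phased = TRUE,
            trigger_id = NA_character_, stringsAsFactors = FALSE))
          if (last) break
          p <- p + L
          if (tab$headroom[p] < min(lens_avail)) break
        }
      }
    }
    # junction-spanning reads from spliced transcripts
    n_junc <- round(n_host * spec$junction_read_fraction)
    if (n_junc > 0) {
      jpool <- gt$sense_hosts %||% gt$host_genes
      jg <- sample(jpool, n_junc, replace = TRUE,
                   prob = alloc[jpool] + 1)
      for (g in unique(jg)) {
        tab <- gene_start_table(assets, g)
        jx <- tab$tx$junctions
        if (!length(jx)) next
        m <- sum(jg == g)
        lens <- as.integer(names(spec$pirna_length_probs))[
          sample.int(length(spec$pirna_length_probs), m, replace = TRUE,
                     prob = spec$pirna_length_probs)]
        for (k in seq_len(m)) {
          j <- jx[sample_per_element(length(jx))]
          a <- spec$junction_anchor
          lo <- max(1L, j + a - lens[k] + 1L)
          hi <- min(j - a + 1L, tab$n - lens[k] + 1L)
          if (lo > hi) next
          wantU <- runif(1) < spec$first_nt_U_probability
          cand <- seq(lo, hi)
          isU <- tab$seq[cand] == "T"
          pool <- if (wantU) cand[isU] else cand[!isU]
          if (!length(pool)) pool <- cand
          s <- pool[sample_per_element(length(pool))]
          emit_host(data.frame(
            class = "host", gene_id = g, locus = NA_character_,
            sequence = span_sequence(tab, s, lens[k], TRUE),
            sense = TRUE, length = lens[k], tx_start = s,
            is_junction = TRUE, is_phased = FALSE,
            trigger_id = NA_character_, stringsAsFactors = FALSE))
        }
      }
    }
    # plain reads fill each gene's remaining allocation
    for (g in gt$host_genes) {
      n_plain <- max(alloc[[g]] - used[[g]], 0L)
      if (n_plain == 0L) next
      tab <- gene_start_table(assets, g)
      sf <- if (!is.na(gt$repeat_gene) && g == gt$repeat_gene)
        spec$antisense_host_sense_fraction else spec$sense_fraction
      d <- draw_gene_reads(tab, n_plain, spec, sf)
      emit_host(data.frame(
        class = "host", gene_id = g, locus = NA_character_,
        sequence = vapply(seq_len(nrow(d)), function(k)
          span_sequence(tab, d$tx_start[k], d$len[k], d$sense[k]), character(1)),
        sense = d$sense, length = d$len, tx_start = d$tx_start,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE))
    }
  }

  # --- Piwi-host (3'UTR-dominant) piRNAs ----------------------------------
  n_piwi <- counts[["piwi_gene"]]
  if (n_piwi > 0 && length(gt$piwi_genes)) {
    alloc <- as.integer(rmultinom(1, n_piwi,
      rep(1, length(gt$piwi_genes))))
    spec_piwi <- spec
    spec_piwi$host_region_weights <- spec$piwi_region_weights
    for (j in seq_along(gt$piwi_genes)) {
      g <- gt$piwi_genes[j]
      if (alloc[j] == 0L) next
      tab <- gene_start_table(assets, g)
      d <- draw_gene_reads(tab, alloc[j], spec_piwi, spec$sense_fraction)
      parts[[length(parts) + 1L]] <- data.frame(
        class = "piwi_gene", gene_id = g, locus = NA_character_,
        sequence = vapply(seq_len(nrow(d)), function(k)
          span_sequence(tab, d$tx_start[k], d$len[k], d$sense[k]), character(1)),
        sense = d$sense, length = d$len, tx_start = d$tx_start,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  # --- decay fragments: rate proportional to mRNA level, broad 18-29 nt ---
  n_decay <- counts[["decay"]]
  if (n_decay > 0) {
    gids <- names(gt$mrna_levels)
    decay_lens <- seq(spec$decay_length_range[1], spec$decay_length_range[2])
    decay_probs <- spec$decay_length_probs %||%
      (rev(seq_along(decay_lens)) / sum(seq_along(decay_lens)))
    alloc <- as.integer(rmultinom(1, n_decay, gt$mrna_levels))
    for (j in seq_along(gids)) {
      if (alloc[j] == 0L) next
      g <- gids[j]
      tab <- gene_start_table(assets, g)
      lens <- decay_lens[sample.int(length(decay_lens), alloc[j],
                                    replace = TRUE, prob = decay_probs)]
      starts <- integer(alloc[j])
      for (k in seq_len(alloc[j])) {
        cand <- which(tab$headroom >= lens[k])
        starts[k] <- cand[sample_per_element(length(cand))]
      }
      parts[[length(parts) + 1L]] <- data.frame(
        class = "decay", gene_id = g, locus = NA_character_,
        sequence = vapply(seq_len(alloc[j]), function(k)
          span_sequence(tab, starts[k], lens[k], TRUE), character(1)),
        sense = TRUE, length = lens, tx_start = starts,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  # --- cluster piRNAs ------------------------------------------------------
  n_cl <- counts[["cluster"]]
  if (n_cl > 0 && length(assets$clusters)) {
    w <- GenomicRanges::width(assets$clusters)
    alloc <- as.integer(rmultinom(1, n_cl, w))
    for (ci in seq_along(assets$clusters)) {
      if (alloc[ci] == 0L) next
      chrom <- as.character(GenomeInfoDb::seqnames(assets$clusters))[ci]
      cs <- BiocGenerics::start(assets$clusters)[ci]
      ce <- BiocGenerics::end(assets$clusters)[ci]
      lens <- as.integer(names(spec$pirna_length_probs))[
        sample.int(length(spec$pirna_length_probs), alloc[ci], replace = TRUE,
                   prob = spec$pirna_length_probs)]
      starts <- cs + as.integer(floor(runif(alloc[ci]) * (ce - cs + 1L - lens)))
      minus <- runif(alloc[ci]) < 0.5
      seqs <- substring(as.character(assets$sequences[[chrom]]),
                        starts, starts + lens - 1L)
      seqs[minus] <- revcomp(seqs[minus])
      parts[[length(parts) + 1L]] <- data.frame(
        class = "cluster", gene_id = NA_character_,
        locus = sprintf("cluster%d", ci), sequence = seqs,
        sense = !minus, length = lens, tx_start = starts,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  # --- TE piRNAs (from consensus; may be absent from the genome) ----------
  n_te <- counts[["TE"]]
  if (n_te > 0 && length(assets$te_consensus)) {
    w <- Biostrings::width(assets$te_consensus)
    alloc <- as.integer(rmultinom(1, n_te, w))
    for (fi in seq_along(assets$te_consensus)) {
      if (alloc[fi] == 0L) next
      lens <- as.integer(names(spec$pirna_length_probs))[
        sample.int(length(spec$pirna_length_probs), alloc[fi], replace = TRUE,
                   prob = spec$pirna_length_probs)]
      starts <- 1L + as.integer(floor(runif(alloc[fi]) * (w[fi] - lens + 1L)))
      minus <- runif(alloc[fi]) < 0.5
      seqs <- substring(as.character(assets$te_consensus[[fi]]),
                        starts, starts + lens - 1L)
      seqs[minus] <- revcomp(seqs[minus])
      parts[[length(parts) + 1L]] <- data.frame(
        class = "TE", gene_id = NA_character_,
        locus = names(assets$te_consensus)[fi], sequence = seqs,
        sense = !minus, length = lens, tx_start = starts,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  # --- non-piRNA fragments -------------------------------------------------
  n_np <- counts[["non_piRNA"]]
  if (n_np > 0 && length(assets$non_pirna)) {
    w <- GenomicRanges::width(assets$non_pirna)
    alloc <- as.integer(rmultinom(1, n_np, w))
    for (li in seq_along(assets$non_pirna)) {
      if (alloc[li] == 0L) next
      chrom <- as.character(GenomeInfoDb::seqnames(assets$non_pirna))[li]
      cs <- BiocGenerics::start(assets$non_pirna)[li]
      ce <- BiocGenerics::end(assets$non_pirna)[li]
      lens <- pmin(runif_int(alloc[li], spec$decay_length_range), ce - cs + 1L)
      starts <- cs + as.integer(floor(runif(alloc[li]) * (ce - cs + 2L - lens)))
      seqs <- substring(as.character(assets$sequences[[chrom]]),
                        starts, starts + lens - 1L)
      parts[[length(parts) + 1L]] <- data.frame(
        class = "non_piRNA", gene_id = NA_character_,
        locus = assets$non_pirna$class[li], sequence = seqs,
        sense = TRUE, length = lens, tx_start = starts,
        is_junction = FALSE, is_phased = FALSE, trigger_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, parts)
  rownames(truth) <- NULL
  truth$library <- library
  truth$condition <- condition
  truth$read_id <- sprintf("%s_%s_%06d", library, condition,
                           seq_len(nrow(truth)))
  reads <- setNames(truth$sequence, truth$read_id)
  list(reads = reads, truth = truth)
}

#' Simulate an mRNA-seq library
#'
#' Reads of fixed length sampled from spliced transcripts with per-gene
#' counts multinomial in the planted mRNA levels.
#'
#' @inheritParams simulate_srna_library
#' @return list with `reads` and `truth` (per-read gene and position).
#' @export
simulate_mrna_library <- function(assets, spec, seed = spec$seed) {
  gt <- attr(assets, "ground_truth")
  with_seed(seed, {
    lvl <- gt$mrna_levels
    # sequencing yield per gene scales with molar level x transcript length
    tx_len <- nchar(vapply(assets$transcripts[names(lvl)], `[[`,
                           character(1), "sequence"))
    alloc <- as.integer(rmultinom(1, spec$mrna_depth, lvl * tx_len))
    parts <- list()
    for (j in seq_along(lvl)) {
      if (alloc[j] == 0L) next
      g <- names(lvl)[j]
      tx <- assets$transcripts[[g]]
      L <- min(spec$mrna_read_length, nchar(tx$sequence))
      starts <- 1L + as.integer(floor(runif(alloc[j]) *
                                        (nchar(tx$sequence) - L + 1L)))
      parts[[length(parts) + 1L]] <- data.frame(
        gene_id = g, tx_start = starts,
        sequence = substring(tx$sequence, starts, starts + L - 1L),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, parts)
    truth$read_id <- sprintf("mrna_%06d", seq_len(nrow(truth)))
    list(reads = setNames(truth$sequence, truth$read_id), truth = truth)
  })
}

#' Simulate a degradome (5'-monophosphate fragment) library
#'
#' Degradome read 5' ends are placed at the planted cleavage sites (the
#' transcript base paired to nt 10 of each cleavage guide) plus a uniform
#' background across transcripts sampled proportional to mRNA level.
#'
#' @inheritParams simulate_srna_library
#' @param planted include reads at the planted cleavage sites.
#' @return list with `reads` and `truth` (gene, 5' transcript position,
#'   guide id or NA for background).
#' @export
simulate_degradome_library <- function(assets, spec, seed = spec$seed,
                                       planted = TRUE) {
  gt <- attr(assets, "ground_truth")
  with_seed(seed, {
    parts <- list()
    L <- spec$degradome_read_length
    if (planted && nrow(gt$cleavage_guides %||% data.frame())) {
      for (i in seq_len(nrow(gt$cleavage_guides))) {
        gd <- gt$cleavage_guides[i, ]
        tx <- assets$transcripts[[gd$gene_id]]
        s <- gd$cleavage_tx_pos
        parts[[length(parts) + 1L]] <- data.frame(
          gene_id = gd$gene_id, tx_start = s,
          guide_id = gd$trigger_id,
          sequence = rep(substr(tx$sequence, s, s + L - 1L),
                         spec$degradome_reads_per_site),
          stringsAsFactors = FALSE)
      }
    }
    n_bg <- spec$degradome_background
    if (n_bg > 0) {
      lvl <- gt$mrna_levels
      alloc <- as.integer(rmultinom(1, n_bg, lvl))
      for (j in seq_along(lvl)) {
        if (alloc[j] == 0L) next
        g <- names(lvl)[j]
        tx <- assets$transcripts[[g]]
        n <- nchar(tx$sequence)
        starts <- 1L + as.integer(floor(runif(alloc[j]) * (n - L + 1L)))
        parts[[length(parts) + 1L]] <- data.frame(
          gene_id = g, tx_start = starts, guide_id = NA_character_,
          sequence = substring(tx$sequence, starts, starts + L - 1L),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, parts)
    truth$read_id <- sprintf("deg_%06d", seq_len(nrow(truth)))
    list(reads = setNames(truth$sequence, truth$read_id), truth = truth)
  })
}

#' Simulate matched mRNA-seq and degradome libraries
#'
#' @inheritParams simulate_srna_library
#' @return list with elements `mrna` and `degradome`, each a `reads` +
#'   `truth` pair.
#' @export
simulate_mrna_and_degradome <- function(assets, spec, seed = spec$seed) {
  list(mrna = simulate_mrna_library(assets, spec, seed = seed),
       degradome = simulate_degradome_library(assets, spec, seed = seed + 1L))
}

#' Write reads as FASTQ
#'
#' Constant quality (Q40, Phred+33 `I`); sequencing-error and quality
#' realism are out of scope for the generator.
#'
#' @param reads named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_library_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  invisible(path)
}

#' Quantify an mRNA-seq library against transcripts
#'
#' Exact end-to-end placement of mRNA reads on the spliced transcripts;
#' returns per-gene counts and TPM (reads per transcript kilobase,
#' library-normalized to 1e6).
#'
#' @param reads named character vector of mRNA reads.
#' @param assets the [genome_assets()] bundle.
#' @return data.frame with `gene_id`, `count`, `tpm`.
#' @export
quantify_mrna <- function(reads, assets) {
  tx_seqs <- Biostrings::DNAStringSet(
    vapply(assets$transcripts, `[[`, character(1), "sequence"))
  names(tx_seqs) <- names(assets$transcripts)
  seqs <- unique(reads)
  hits <- exact_hits(seqs, tx_seqs, strands = "+")
  gene_of_seq <- rep(NA_character_, length(seqs))
  gl <- split(hits$ref, hits$read)
  uniq <- vapply(gl, function(g) length(unique(g)) == 1L, logical(1))
  gene_of_seq[as.integer(names(gl))[uniq]] <-
    vapply(gl[uniq], `[[`, character(1), 1L)
  gene <- gene_of_seq[match(reads, seqs)]
  cnt <- table(factor(gene, levels = names(assets$transcripts)))
  kb <- nchar(vapply(assets$transcripts, `[[`, character(1), "sequence")) / 1000
  rpk <- as.numeric(cnt) / kb
  tpm <- if (sum(rpk) > 0) rpk * 1e6 / sum(rpk) else rpk
  data.frame(gene_id = names(assets$transcripts), count = as.integer(cnt),
             tpm = tpm, stringsAsFactors = FALSE, row.names = NULL)
}
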