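# Deterministic miniature assets for the classifier-hierarchy tests.
#
# The genome is assembled from explicit segments so that membership of a
# read in each annotation tier is known by construction:
#   - `shared30` occurs inside both an rRNA locus and gene g1's first exon
#   - `clTE40` lies inside the cluster and is copied into the TE consensus
#   - `twogene24` occurs in an exon of g1 and in g2's exon
#   - `triple25` occurs three times inside g2's exon (intragenic multimapper)

fixed_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_mini_assets <- function() {
  shared30 <- fixed_dna(30, 101)
  clTE40 <- fixed_dna(40, 102)
  twogene24 <- fixed_dna(24, 103)
  triple25 <- fixed_dna(25, 104)

  # gene g1: exon1 [101,160], intron, exon2 [211,300]
  ex1 <- paste0(fixed_dna(10, 105), shared30, fixed_dna(20, 106))   # 60 nt
  ex2 <- paste0(fixed_dna(30, 107), twogene24, fixed_dna(36, 108))  # 90 nt
  intron <- fixed_dna(50, 109)
  # rRNA locus [351,430]
  rrna <- paste0(fixed_dna(25, 110), shared30, fixed_dna(25, 111))  # 80 nt
  # cluster [481,680]
  cluster <- paste0(fixed_dna(80, 112), clTE40, fixed_dna(80, 113)) # 200 nt
  # gene g2: single exon [731,910]
  g2ex <- paste0(fixed_dna(15, 114), triple25, triple25, fixed_dna(10, 115),
                 triple25, twogene24, fixed_dna(56, 116))           # 180 nt
  chrom <- paste0(fixed_dna(100, 117), ex1, intron, ex2,
                  fixed_dna(50, 118), rrna, fixed_dna(50, 119), cluster,
                  fixed_dna(50, 120), g2ex, fixed_dna(90, 121))
  seqs <- Biostrings::DNAStringSet(chrom)
  names(seqs) <- "chrM"

  g1 <- gene_model("g1", "chrM", "+",
    exons = IRanges::IRanges(c(101L, 211L), c(160L, 300L)),
    utr5 = IRanges::IRanges(101L, 120L),
    cds = IRanges::IRanges(c(121L, 211L), c(160L, 270L)),
    utr3 = IRanges::IRanges(271L, 300L))
  g2 <- gene_model("g2", "chrM", "+",
    exons = IRanges::IRanges(731L, 910L),
    utr5 = IRanges::IRanges(731L, 750L),
    cds = IRanges::IRanges(751L, 870L),
    utr3 = IRanges::IRanges(871L, 910L))

  clusters <- GenomicRanges::GRanges("chrM", IRanges::IRanges(481L, 680L))
  np <- GenomicRanges::GRanges("chrM", IRanges::IRanges(351L, 430L))
  np$class <- "rRNA"
  te <- Biostrings::DNAStringSet(paste0(fixed_dna(60, 122), clTE40,
                                        fixed_dna(60, 123)))
  names(te) <- "TEX"

  assets <- genome_assets(seqs, list(g1, g2), clusters = clusters,
                          te_consensus = te, non_pirna = np)
  list(assets = assets, shared30 = shared30, clTE40 = clTE40,
       twogene24 = twogene24, triple25 = triple25)
}

# tiny spec for fast simulation-based unit tests
small_spec <- function(...) {
  simulation_spec(
    n_chroms = 1L, chrom_length = 120000L,
    n_host_genes = 4L, n_piwi_genes = 1L, n_decoy_genes = 20L,
    n_cluster_loci = 1L, n_te_families = 2L, n_non_pirna_loci = 5L,
    class_counts = c(host = 2000L, piwi_gene = 400L, decay = 5000L,
                     cluster = 8000L, TE = 3000L, non_piRNA = 2000L),
    n_triggers = 2L, n_phased_genes = 1L, trains_per_gene = 10L,
    n_cleavage_targets = 2L, mrna_depth = 8000L,
    degradome_background = 3000L,
    ...)
}
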