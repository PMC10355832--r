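test_that("asset building is deterministic and honors locus counts", {
  spec <- small_spec()
  a1 <- build_toy_assets(spec)
  a2 <- build_toy_assets(spec)
  expect_identical(as.character(a1$sequences), as.character(a2$sequences))
  expect_identical(length(a1$genes), 25L)
  expect_identical(length(a1$clusters), 1L)
  expect_identical(length(a1$te_consensus), 2L)
  # non-overlapping gene placement
  gr <- a1$exon_gr
  expect_identical(
    sum(IRanges::width(IRanges::reduce(IRanges::ranges(gr)))),
    sum(IRanges::width(IRanges::ranges(gr))))
  # byte-identical serialized assets under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_assets(a1, d1); write_assets(a2, d2)
  for (f in c("genome.fa", "genes.gff3", "clusters.bed"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a spec that cannot fit fails with a sizing hint
  expect_error(build_toy_assets(small_spec(chrom_length = 5000L)),
               "chromosome too short")
})

test_that("library simulation is reproducible and conserves counts", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  l1 <- simulate_srna_library(assets, spec, "total", seed = 9)
  l2 <- simulate_srna_library(assets, spec, "total", seed = 9)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  l3 <- simulate_srna_library(assets, spec, "total", seed = 10)
  expect_false(identical(l1$reads, l3$reads))
  # truth table covers every emitted read exactly once
  expect_identical(nrow(l1$truth), length(l1$reads))
  expect_identical(l1$truth$read_id, names(l1$reads))
  expect_identical(unname(l1$truth$sequence), unname(l1$reads))
  # FASTQ round trip is byte-identical under one seed
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_library_fastq(l1$reads, f1)
  write_library_fastq(l2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the planted 5'U probability is recovered empirically", {
  # isolate the first-nucleotide machinery: plain host reads only
  spec <- small_spec(
    class_counts = c(host = 10000L, piwi_gene = 0L, decay = 0L,
                     cluster = 0L, TE = 0L, non_piRNA = 0L),
    n_triggers = 0L, n_phased_genes = 0L, junction_read_fraction = 0,
    plant_repeat_gene = FALSE)
  assets <- build_toy_assets(spec)
  lib <- simulate_srna_library(assets, spec, "total", seed = 21)
  host <- lib$truth[lib$truth$class == "host", ]
  expect_gte(nrow(host), 9900L)
  u1 <- mean(substr(host$sequence, 1, 1) == "T")
  expect_lt(abs(u1 - 0.8), 0.02)
  # length distribution follows the configured piRNA profile
  p26 <- mean(host$length == 26L)
  expect_lt(abs(p26 - 0.25), 0.03)
})

test_that("responder reads satisfy the 10-nt overlap by construction", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  lib <- simulate_srna_library(assets, spec, "total", seed = 12)
  resp <- lib$truth[!is.na(lib$truth$trigger_id), ]
  expect_gt(nrow(resp), 0L)
  trig_seq <- setNames(gt$triggers$sequence, gt$triggers$trigger_id)
  expect_true(all(substr(resp$sequence, 1, 10) ==
                    revcomp(substr(trig_seq[resp$trigger_id], 1, 10))))
})

test_that("IP enrichment factors shift the host/decay composition", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  tot <- simulate_srna_library(assets, spec, "total", seed = 14)$truth
  ip <- simulate_srna_library(assets, spec, "aub_ip", seed = 15)$truth
  ratio_tot <- sum(tot$class == "host") / sum(tot$class == "decay")
  ratio_ip <- sum(ip$class == "host") / sum(ip$class == "decay")
  enr <- spec$ip_factors$aub_ip[["host"]] / spec$ip_factors$aub_ip[["decay"]]
  expect_lt(abs(ratio_ip / ratio_tot - enr) / enr, 0.1)
})

test_that("mutant depletion scales the host class by the planted factor", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  wt <- simulate_srna_library(assets, spec, "aub_ip", "wt", seed = 16)$truth
  mu <- simulate_srna_library(assets, spec, "aub_ip", "mutant", seed = 16)$truth
  f_host <- sum(mu$class == "host") / sum(wt$class == "host")
  f_cl <- sum(mu$class == "cluster") / sum(wt$class == "cluster")
  expect_lt(abs(f_host - 0.6), 0.05)
  expect_gt(f_cl, 0.98)
})

test_that("mRNA read counts follow expression at fixed transcript length", {
  spec <- small_spec(n_host_genes = 0L, n_piwi_genes = 0L, n_decoy_genes = 2L,
                     n_triggers = 0L, n_phased_genes = 0L,
                     n_cleavage_targets = 0L, plant_repeat_gene = FALSE,
                     utr5_range = c(150L, 150L),
                     cds_codon_range = c(300L, 300L),
                     utr3_range = c(300L, 300L), mrna_depth = 4000L)
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  gt$mrna_levels[] <- c(10, 30)
  attr(assets, "ground_truth") <- gt
  m <- simulate_mrna_library(assets, spec, seed = 18)
  cnt <- table(factor(m$truth$gene_id, levels = names(gt$mrna_levels)))
  expect_lt(abs(cnt[[1]] - 1000), 150)
  expect_lt(abs(cnt[[2]] - 3000), 150)
  # and quantification recovers the expression ratio as TPM
  q <- quantify_mrna(m$reads, assets)
  expect_lt(abs(q$tpm[2] / q$tpm[1] - 3), 0.5)
})

test_that("background degradome 5' ends are uniform along the transcript", {
  spec <- small_spec(n_host_genes = 0L, n_piwi_genes = 0L, n_decoy_genes = 1L,
                     n_triggers = 0L, n_phased_genes = 0L,
                     n_cleavage_targets = 0L, plant_repeat_gene = FALSE,
                     degradome_background = 5000L)
  assets <- build_toy_assets(spec)
  deg <- simulate_degradome_library(assets, spec, seed = 19, planted = FALSE)
  pos <- deg$truth$tx_start
  n_spots <- max(pos)
  br <- seq(0, n_spots, length.out = 11)
  h <- table(cut(pos, br))
  expect_gt(suppressWarnings(chisq.test(as.numeric(h))$p.value), 0.01)
})

test_that("planted degradome reads start at the base paired to guide nt 10", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  both <- simulate_mrna_and_degradome(assets, spec, seed = 20)
  planted <- both$degradome$truth[!is.na(both$degradome$truth$guide_id), ]
  gd <- gt$cleavage_guides[match(planted$guide_id,
                                 gt$cleavage_guides$trigger_id), ]
  expect_identical(planted$tx_start, gd$cleavage_tx_pos)
  # geometry: fragment first base pairs guide nt 10, upstream base guide nt 11
  for (i in seq_len(nrow(planted))) {
    tx <- assets$transcripts[[planted$gene_id[i]]]$sequence
    s <- planted$tx_start[i]
    g <- gd$sequence[i]
    expect_identical(substr(tx, s, s), comp_base(substr(g, 10, 10)))
    expect_identical(substr(tx, s - 1, s - 1), comp_base(substr(g, 11, 11)))
  }
})

test_that("the repeat-bearing gene yields intragenic multimappers", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  gm <- assets$genes[[gt$repeat_gene]]
  # some 25-nt window of the tandem-repeat CDS occurs >= 2 times genomically
  tx <- assets$transcripts[[gt$repeat_gene]]$sequence
  utr5_len <- unname(region_lengths(gm)[["utr5"]])
  found <- FALSE
  for (s in seq(utr5_len + 11L, utr5_len + 200L, by = 10L)) {
    hits <- match_reads(substr(tx, s, s + 24L), assets$sequences)
    if (nrow(hits) >= 2L) { found <- TRUE; break }
  }
  expect_true(found)
})
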