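test_that("enrichment ratio and retention follow the strict threshold", {
  out <- enrichment_ratio(c(120, 9, 0), c(4, 1, 0), pseudo = c(0, 0, 0.5))
  expect_equal(out$ratio, c(30, 9, 1))
  expect_identical(out$retain, c(TRUE, FALSE, FALSE))
  # ratio exactly at the threshold is excluded (strict >)
  expect_false(enrichment_ratio(100, 10, pseudo = 0)$retain)
})

test_that("size profiles report proportions and the 24-26 nt peak", {
  sp <- size_profile(rep(c(24, 25, 26), c(3, 5, 2)))
  expect_equal(unname(sp$proportions[c("24", "25", "26")]), c(0.3, 0.5, 0.2))
  expect_equal(sum(sp$proportions), 1)
  expect_true(sp$peak_24_26)
  # monotone decay-like profile peaks at 18, not 24-26
  decayish <- rep(18:29, times = 12:1)
  expect_false(size_profile(decayish)$peak_24_26)
  # multi-library mode averages per-library proportion vectors
  two <- size_profile(list(rep(24, 10), rep(26, 30)))
  expect_equal(unname(two$proportions[c("24", "26")]), c(0.5, 0.5))
  # no reads in window -> flagged NA record
  expect_true(is.na(size_profile(integer(0))$peak_24_26))
})

test_that("positional nucleotide probabilities match hand counts", {
  reads <- c(paste0("T", strrep("A", 24)), paste0("T", strrep("C", 24)),
             paste0("T", strrep("G", 24)), paste0("A", strrep("T", 24)))
  m <- nt_probability(reads)
  expect_equal(m["1", "T"], 0.75)
  expect_equal(attr(m, "u1"), 0.75)
  expect_equal(unname(rowSums(m)), rep(1, 23))
  one <- nt_probability(rep(paste0("G", strrep("A", 22), "C"), 3))
  expect_equal(unname(one["1", ]), c(0, 0, 1, 0))
})

test_that("IP enrichment averages libraries with a pseudocount guard", {
  expect_equal(ip_enrichment(10, list(90, 110), pseudo = 0), 10)
  expect_equal(ip_enrichment(10, 0), 0.5 / 10.5)
  expect_gt(ip_enrichment(0, 0), 0)
})

test_that("host tiers use strict inequalities", {
  tiers <- tier_hosts(c(150, 100, 10.5, 10, 0))
  expect_identical(as.character(tiers),
                   c("rpm_gt_100", "rpm_gt_10", "rpm_gt_10", "below", "below"))
})

test_that("region densities divide counts by region length", {
  gm <- gene_model("x", "c", "+",
    exons = IRanges::IRanges(1, 1300),
    utr5 = IRanges::IRanges(1, 100),
    cds = IRanges::IRanges(101, 1100),
    utr3 = IRanges::IRanges(1101, 1300))
  d <- region_density(gm, c(utr5 = 0, cds = 500, utr3 = 10))
  expect_equal(d$density, c(0, 0.5, 0.05))
  expect_equal(d$relative, c(0, 0.909, 0.091), tolerance = 1e-3)
  expect_equal(sum(d$relative), 1)
})

test_that("CDS-planted gene cohorts show CDS > 3'UTR density", {
  # 14 genes with CDS-biased reads, multinomial sampling noise
  set.seed(57)
  dens <- lapply(1:14, function(i) {
    gm <- gene_model(paste0("h", i), "c", "+",
      exons = IRanges::IRanges(1, 1450),
      utr5 = IRanges::IRanges(1, 150),
      cds = IRanges::IRanges(151, 1050),
      utr3 = IRanges::IRanges(1051, 1450))
    cnt <- as.integer(rmultinom(1, 400, c(0.05, 0.85, 0.10)))
    region_density(gm, setNames(cnt, c("utr5", "cds", "utr3")))
  })
  tt <- region_density_test(dens, "cds", "utr3")
  expect_lt(tt$p.value, 0.01)
  expect_gt(tt$estimate, 0)
})

test_that("sense fraction handles counts and the zero-read flag", {
  expect_equal(sense_fraction(c(rep(TRUE, 90), rep(FALSE, 10))), 0.9)
  out <- sense_fraction(sense_count = 0, total = 0)
  expect_true(is.na(out))
  expect_true(attr(out, "flagged"))
})

test_that("junction reads require anchored spliced-only placements", {
  mini <- make_mini_assets()
  a <- mini$assets
  tx <- a$transcripts[["g1"]]           # junction at transcript offset 60
  j <- tx$junctions[1]
  straddle <- substr(tx$sequence, j - 11L, j + 13L)   # 12 + 13 anchors
  inside <- substr(tx$sequence, 10L, 34L)             # fully in exon 1
  genomic <- as.character(Biostrings::subseq(a$sequences[[1]], 150, 174))
  n <- junction_reads(c(straddle, inside, genomic), "g1", a)
  expect_identical(as.integer(n), 1L)
  expect_identical(attr(n, "which"), c(TRUE, FALSE, FALSE))
  # anchors below the minimum are not counted
  tiny_anchor <- substr(tx$sequence, j - 1L, j + 22L)
  expect_identical(as.integer(junction_reads(tiny_anchor, "g1", a)), 0L)
})

test_that("the host call is the conjunction of all four conditions", {
  rec <- data.frame(
    gene_id = c("ok", "low_ratio", "broad", "low_u", "not_bound"),
    enrichment_ratio = c(30, 9, 30, 30, 30),
    peak_24_26 = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    u1_fraction = c(0.8, 0.8, 0.8, 0.3, 0.8),
    aub_enrichment = c(5, 5, 5, 5, 1.2))
  out <- call_hosts(rec)
  expect_identical(out$gene_id[out$call], "ok")
})

test_that("enrichment ratio is invariant to library depth", {
  # TPM/TPM: doubling the simulated depth leaves the ratio unchanged
  spec1 <- small_spec()
  spec2 <- small_spec(class_counts = small_spec()$class_counts * 2L)
  assets <- build_toy_assets(spec1)
  q <- function(spec, seed) {
    lib <- simulate_srna_library(assets, spec, "total", seed = seed)
    sel <- size_select(lib$reads, 23, 29)
    asg <- classify_hierarchical(sel$reads, assets, seed = seed)
    quantify(asg, assets)
  }
  p1 <- q(spec1, 30); p2 <- q(spec2, 30)
  m <- simulate_mrna_library(assets, spec1, seed = 31)
  mq <- quantify_mrna(m$reads, assets)
  r1 <- enrichment_ratio(p1$genes$tpm, mq$tpm)$ratio
  r2 <- enrichment_ratio(p2$genes$tpm, mq$tpm)$ratio
  busy <- p1$genes$count > 100
  expect_true(any(busy))
  expect_lt(max(abs(log2(r1[busy] / r2[busy]))), 0.25)
})
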