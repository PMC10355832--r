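test_that("adapter trimming keeps the prefix before the leftmost match", {
  adapter <- "AGATCGGAAGAGCACACGTCT"
  r <- c(a = paste0("ACGT", adapter, "NNN"), b = "ACGTACGTACGTACGT",
         c = paste0(adapter, "ACGT"))
  out <- trim_adapter(r)
  expect_identical(unname(out$reads[["a"]]), "ACGT")
  expect_identical(unname(out$reads[["b"]]), "ACGTACGTACGTACGT")
  expect_identical(unname(out$no_adapter), c(FALSE, TRUE))
  expect_identical(out$n_dropped, 1L)
  # leftmost occurrence wins when the adapter appears twice
  r2 <- c(d = paste0("TTT", adapter, "CCC", adapter))
  expect_identical(unname(trim_adapter(r2)$reads[["d"]]), "TTT")
})

test_that("size selection applies inclusive bounds", {
  r <- setNames(strrep("A", c(22, 23, 29, 30, 18)),
                paste0("r", 1:5))
  out <- size_select(r, 23, 29)
  expect_identical(names(out$reads), c("r2", "r3"))
  expect_identical(out$n_removed, 3L)
  wide <- size_select(r, 18, 29)
  expect_true("r5" %in% names(wide$reads))
})

test_that("match_reads agrees with a naive sliding-window oracle", {
  set.seed(42)
  ref <- Biostrings::DNAStringSet(c(
    refA = paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                 collapse = ""),
    refB = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")))
  # reads: genuine windows (some reverse-complemented, some mutated) + noise
  reads <- character(0)
  for (i in 1:12) {
    st <- sample(700, 1)
    w <- substr(as.character(ref[["refA"]]), st, st + 24)
    if (i %% 3 == 0) w <- revcomp(w)
    if (i %% 4 == 0) substr(w, 5, 5) <- "A"
    reads <- c(reads, w)
  }
  reads <- c(reads, vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""),
    character(1)))
  for (sim in c(1, 0.88)) {
    got <- match_reads(reads, ref, min_similarity = sim)
    for (i in seq_along(reads)) {
      exp_i <- oracle_match(reads[i], ref, min_similarity = sim)
      got_i <- got[got$read == i, c("ref", "start", "end", "strand", "identity")]
      o <- order(exp_i$ref, exp_i$start, exp_i$strand)
      o2 <- order(got_i$ref, got_i$start, got_i$strand)
      expect_equal(unname(as.list(got_i[o2, ])), unname(as.list(exp_i[o, ])),
                   tolerance = 1e-12)
    }
  }
})

test_that("similarity thresholds follow the 80%-identity rule", {
  set.seed(7)
  refseq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  ref <- Biostrings::DNAStringSet(c(r = refseq))
  window <- substr(refseq, 50, 74)                  # 25 nt
  mm5 <- window; for (p in c(2, 6, 10, 14, 18)) substr(mm5, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(mm5, p, p))[1]
  mm6 <- mm5; substr(mm6, 22, 22) <-
    setdiff(c("A", "C", "G", "T"), substr(mm6, 22, 22))[1]
  hits5 <- match_reads(mm5, ref, min_similarity = 0.8)
  expect_true(any(hits5$start == 50 & abs(hits5$identity - 0.8) < 1e-9))
  hits6 <- match_reads(mm6, ref, min_similarity = 0.8)
  expect_false(any(hits6$start == 50))
})

test_that("classification honors the non-piRNA > cluster > TE > genic order", {
  mini <- make_mini_assets()
  a <- mini$assets
  reads <- c(
    np = substr(mini$shared30, 1, 25),       # rRNA locus AND g1 exon
    cl = substr(mini$clTE40, 5, 30),         # cluster AND TE consensus
    te = as.character(Biostrings::subseq(a$te_consensus[[1]], 5, 29)),
    two = mini$twogene24,                    # exons of two genes
    multi = mini$triple25,                   # 3 positions inside g2
    gen = as.character(Biostrings::subseq(a$sequences[[1]], 231, 255)))
  out <- classify_hierarchical(reads, a, seed = 5)
  cls <- setNames(out$class, out$read_id)
  expect_identical(cls[["np"]], "non_piRNA")
  expect_identical(cls[["cl"]], "cluster")
  expect_identical(cls[["te"]], "TE")
  expect_identical(cls[["two"]], "unassigned")
  expect_identical(cls[["multi"]], "genic")
  expect_identical(out$gene_id[out$read_id == "multi"], "g2")
  expect_identical(cls[["gen"]], "genic")
  expect_identical(out$gene_id[out$read_id == "gen"], "g1")
  # seeded reproducibility of the random intragenic placement
  again <- classify_hierarchical(reads, a, seed = 5)
  expect_identical(out, again)
  # the multimapper position is one of the three planted copies
  p <- out$start[out$read_id == "multi"]
  expect_true(p %in% c(746L, 771L, 806L))
})

test_that("antisense placements are reported on the minus strand", {
  mini <- make_mini_assets()
  a <- mini$assets
  fwd <- as.character(Biostrings::subseq(a$sequences[[1]], 231, 255))
  out <- classify_hierarchical(c(x = revcomp(fwd)), a, seed = 1)
  expect_identical(out$class, "genic")
  expect_identical(out$strand, "-")
  expect_false(out$sense)
  expect_identical(out$start, 231L)
})

test_that("quantification reproduces the TPM and RPM definitions", {
  mini <- make_mini_assets()
  a <- mini$assets
  # g1 exon length 150 nt, g2 exon length 180 nt
  r1 <- as.character(Biostrings::subseq(a$sequences[[1]], 231, 255))
  r2 <- as.character(Biostrings::subseq(a$sequences[[1]], 760, 784))
  reads <- setNames(c(rep(r1, 5), rep(r2, 18)), paste0("q", 1:23))
  out <- classify_hierarchical(reads, a, seed = 1)
  prof <- quantify(out, a, "toy")
  g <- prof$genes
  expect_equal(g$rpk[g$gene_id == "g1"], 5 / 0.150)
  expect_equal(g$rpk[g$gene_id == "g2"], 18 / 0.180)
  expect_equal(sum(g$tpm), 1e6)
  expect_equal(g$tpm[g$gene_id == "g1"], 1e6 / 4)   # RPK ratio 1:3
  expect_equal(g$rpm, g$count * 1e6 / prof$total_after_nonpirna)
  expect_equal(sum(prof$class_counts), attr(out, "n_input"))
})

test_that("read coverage and scaling build correct tracks", {
  mini <- make_mini_assets()
  a <- mini$assets
  r <- as.character(Biostrings::subseq(a$sequences[[1]], 231, 255))
  out <- classify_hierarchical(c(x = r), a, seed = 1)
  tr <- coverage_from_assignments(out, a, scale_basis = 2e6)
  v <- as.numeric(tr$coverage$chrM)
  expect_equal(which(v == 1), 231:255)
  expect_equal(tr$scaling_factor, 0.5)
})
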