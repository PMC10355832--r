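test_that("identical reads are grouped with conserved counts", {
  g <- group_reads(c("AAAA", "AAAA", "CCCC"))
  expect_identical(g$sequence[order(g$sequence)], c("AAAA", "CCCC"))
  expect_identical(sum(g$count), 3L)
  expect_identical(g$count[g$sequence == "AAAA"], 2L)
  n <- group_reads(replicate(8, paste(sample(c("A", "C"), 12, replace = TRUE),
                                      collapse = "")))
  expect_identical(sum(n$count), 8L)
  expect_identical(nrow(group_reads(character(0))), 0L)
})

test_that("a constructed complementary pair is reported", {
  trig <- data.frame(sequence = "ACGTACGTACTTTTTTTTTTTT", count = 5L,
                     set = "si")
  resp <- data.frame(sequence = "GTACGTACGTAAAACCCCGGGGTTT", count = 11L,
                     set = "pi")
  out <- find_overlap_pairs(trig, resp)
  expect_identical(nrow(out), 1L)
  expect_identical(out$overlap_len, 10L)
  expect_true(out$wobble_free)
  # invariant re-checked independently of the implementation
  expect_identical(substr(out$responder_seq, 1, 10),
                   revcomp(substr(out$trigger_seq, 1, 10)))
})

test_that("the G-U wobble rule is applied at the right geometry", {
  # trigger nt 1 (G) pairs responder nt 10; make that a G.T pair
  trig <- data.frame(sequence = "GACGTACGTACCCCCCCCCCCC", count = 1L,
                     set = "si")
  wc <- revcomp(substr(trig$sequence, 1, 10))      # TACGTACGTC
  resp_wc <- data.frame(sequence = paste0(wc, "AAAAAAAAAAAAAAA"),
                        count = 20L, set = "pi")
  wob <- sub("C$", "T", wc)                        # G.U at trigger pos 1
  resp_gu <- data.frame(sequence = paste0(wob, "AAAAAAAAAAAAAAA"),
                        count = 20L, set = "pi")
  expect_identical(nrow(find_overlap_pairs(trig, resp_wc)), 1L)
  expect_identical(nrow(find_overlap_pairs(trig, resp_gu)), 0L)
  out <- find_overlap_pairs(trig, resp_gu, allow_gu = TRUE)
  expect_identical(nrow(out), 1L)
  expect_false(out$wobble_free)
  # allow_gu output is a superset of the strict output
  both <- rbind(resp_wc, resp_gu)
  strict <- find_overlap_pairs(trig, both)
  loose <- find_overlap_pairs(trig, both, allow_gu = TRUE)
  expect_true(all(strict$responder_seq %in% loose$responder_seq))
})

test_that("the responder-read threshold is strictly greater than", {
  trig <- data.frame(sequence = "ACGTACGTACTTTTTTTTTTTT", count = 1L,
                     set = "si")
  resp <- data.frame(sequence = "GTACGTACGTAAAACCCCGGGGTTT", count = 10L,
                     set = "pi")
  expect_identical(nrow(find_overlap_pairs(trig, resp)), 0L)
  resp$count <- 11L
  expect_identical(nrow(find_overlap_pairs(trig, resp)), 1L)
})

test_that("pair search matches the brute-force comparator on random groups", {
  set.seed(11)
  triggers <- random_groups(120, set = "si")
  responders <- random_groups(120, set = "pi")
  # spike in guaranteed partners so the comparison is not vacuous
  picks <- sample(nrow(triggers), 25)
  planted <- data.frame(
    sequence = paste0(revcomp(substr(triggers$sequence[picks], 1, 10)),
                      vapply(1:25, function(i)
                        paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                              collapse = ""), character(1))),
    count = sample(1:40, 25, replace = TRUE), set = "pi")
  responders <- rbind(responders, planted)
  responders <- responders[!duplicated(responders$sequence), ]
  for (gu in c(FALSE, TRUE)) for (thr in c(0, 10)) {
    got <- find_overlap_pairs(triggers, responders, min_responder_reads = thr,
                              allow_gu = gu)
    got <- got[order(got$trigger_seq, got$responder_seq),
               c("trigger_seq", "responder_seq")]
    rownames(got) <- NULL
    exp <- oracle_overlap_pairs(triggers, responders,
                                min_responder_reads = thr, allow_gu = gu)
    rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("cleavage pairing enforces 11th-nucleotide transcript pairing", {
  set.seed(3)
  tx <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  # guide perfectly complementary to transcript window [p, p+24]
  p <- 100L
  guide <- revcomp(substr(tx, p, p + 24L))
  s <- p + 25L - 10L                    # fragment 5' end (cleavage site)
  frag <- substr(tx, s, s + 24L)
  guides <- data.frame(sequence = guide, count = 30L, set = "pi")
  frags <- data.frame(sequence = frag, count = 15L, set = "deg")
  txs <- c(nejA = tx)
  out <- cleavage_pairs(guides, frags, txs, require_g11 = TRUE)
  expect_identical(nrow(out), 1L)
  expect_true(out$g11_paired)
  expect_identical(out$gene_id, "nejA")
  expect_identical(out$fragment_tx_pos, s)
  # mutate the base paired by guide nt 11 -> excluded under require_g11
  tx_mut <- tx
  substr(tx_mut, s - 1L, s - 1L) <-
    setdiff(c("A", "C", "G", "T"),
            c(substr(tx, s - 1L, s - 1L), comp_base(substr(guide, 11, 11))))[1]
  frag_mut <- substr(tx_mut, s, s + 24L)
  out_mut <- cleavage_pairs(guides,
                            data.frame(sequence = frag_mut, count = 15L,
                                       set = "deg"),
                            c(nejA = tx_mut), require_g11 = TRUE)
  expect_identical(nrow(out_mut), 0L)
  out_loose <- cleavage_pairs(guides,
                              data.frame(sequence = frag_mut, count = 15L,
                                         set = "deg"),
                              c(nejA = tx_mut), require_g11 = FALSE)
  expect_identical(nrow(out_loose), 1L)
  expect_false(out_loose$g11_paired)
})

test_that("without the g11 rule cleavage pairing reduces to plain overlap", {
  set.seed(19)
  tx <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
              collapse = "")
  txs <- c(t1 = tx)
  guides <- list(); frags <- list()
  for (i in 1:100) {
    p <- sample(4000, 1)
    guide <- revcomp(substr(tx, p, p + 21L))
    # half the guides get mismatches in the overlap region
    if (i %% 2 == 0) {
      mp <- sample(1:10, 2)
      for (q in mp) substr(guide, q, q) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(guide, q, q)), 1)
    }
    s <- p + 22L - 10L
    guides[[i]] <- data.frame(sequence = guide,
                              count = sample(5:40, 1), set = "pi")
    frags[[i]] <- data.frame(sequence = substr(tx, s, s + 23L),
                             count = sample(5:40, 1), set = "deg")
  }
  guides <- do.call(rbind, guides); guides <- guides[!duplicated(guides$sequence), ]
  frags <- do.call(rbind, frags); frags <- frags[!duplicated(frags$sequence), ]
  a <- cleavage_pairs(guides, frags, txs, require_g11 = FALSE,
                      min_group_reads = 10)
  b <- find_overlap_pairs(guides, frags, min_responder_reads = 10)
  key <- function(d) {
    d <- d[order(d$trigger_seq, d$responder_seq),
           c("trigger_seq", "responder_seq", "responder_count")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(a), key(b))
})

test_that("degradome pairing recovers planted cleavage sites", {
  spec <- small_spec()
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  deg <- simulate_degradome_library(assets, spec, seed = 4)
  txs <- vapply(assets$transcripts, `[[`, character(1), "sequence")
  guides <- data.frame(sequence = gt$cleavage_guides$sequence,
                       count = gt$cleavage_guides$count, set = "pi")
  out <- pair_degradome(guides, deg$reads, txs, require_g11 = TRUE)
  expect_true(all(gt$cleavage_guides$sequence %in% out$trigger_seq))
  got <- out[match(gt$cleavage_guides$sequence, out$trigger_seq), ]
  expect_identical(got$gene_id, gt$cleavage_guides$gene_id)
  expect_identical(got$fragment_tx_pos, gt$cleavage_guides$cleavage_tx_pos)
  # background-only degradome yields no pair above threshold
  bg <- simulate_degradome_library(assets, spec, seed = 5, planted = FALSE)
  out_bg <- pair_degradome(guides, bg$reads, txs, require_g11 = TRUE)
  expect_identical(nrow(out_bg), 0L)
})

test_that("Ago2-sorting filter keeps strictly Ago2-preferred strands", {
  tab <- data.frame(mirna = c("a-3p", "b-5p", "c-3p", "d-5p"),
                    rpm_ago1 = c(5, 50, 7, 0),
                    rpm_ago2 = c(50, 5, 7, 0))
  out <- filter_ago2_sorted(tab)
  expect_identical(out$mirna, "a-3p")
})

test_that("miRNA seed scanning finds planted sites on the right strand", {
  set.seed(23)
  mirna <- "TGAGGTAGTAGGTTGTATAGTT"
  seed_rc <- revcomp(substr(mirna, 2, 8))
  backbone <- gsub(seed_rc, "AAAAAAA",
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
    fixed = TRUE)
  target <- paste0(substr(backbone, 1, 150), seed_rc,
                   substr(backbone, 151, 400))
  sites <- scan_mirna_sites(mirna, target)
  expect_identical(sites, 151L)
  # antisense-only construct: sites on the reverse strand only
  anti <- revcomp(target)
  expect_identical(length(scan_mirna_sites(mirna, anti)), 0L)
  expect_true(length(scan_mirna_sites(mirna, revcomp(anti))) == 1L)
})

test_that("seed-match counts on random sequence track the 1/4^7 expectation", {
  set.seed(29)
  L <- 163840L   # expectation L / 4^7 = 10 sites
  target <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  n <- length(scan_mirna_sites("TGAGGTAGTAGGTTGTATAGTT", target))
  expect_gte(n, 2L)   # Poisson(10), far tails excluded
  expect_lte(n, 25L)
})
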