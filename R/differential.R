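# Condition comparisons: per-class and per-gene RPM fold changes across
# replicate pairs, cross-condition correlation of gene fold changes, and
# degradome enrichment.

fc_with_pseudo <- function(case, control, pseudo = 0.5) {
  use_pseudo <- case == 0 | control == 0
  num <- ifelse(use_pseudo, case + pseudo, case)
  den <- ifelse(use_pseudo, control + pseudo, control)
  list(fc = num / den, pseudo_used = use_pseudo)
}

class_rpm <- function(profile, cls, gene_set = NULL) {
  if (cls == "genic" && !is.null(gene_set)) {
    g <- profile$genes
    sum(g$rpm[g$gene_id %in% gene_set])
  } else {
    profile$class_rpm[[cls]]
  }
}

#' Class-level RPM fold changes between conditions
#'
#' Groups each library's reads as cluster mappers, TE mappers or exon
#' (genic) mappers and computes per-replicate-pair RPM fold changes
#' (case/control), summarized as mean and SD over pairs. The exon-mapper
#' class can be restricted to a gene set (for example the Aub-IP RPM > 10
#' tier) to enrich CDS-piRNA producers.
#'
#' @param case_profiles,control_profiles lists of [quantify()] profiles,
#'   paired by position (replicate 1 with replicate 1, and so on).
#' @param classes classes to compare.
#' @param gene_set optional gene ids restricting the genic class.
#' @param pseudo RPM pseudocount applied when either side is zero.
#' @return data.frame with one `FoldChangeRecord` row per class: `unit`,
#'   `fc_mean`, `fc_sd`, `n_pairs`, `pseudo_used`, plus per-pair columns
#'   `fc_1`, `fc_2`, ...
#' @export
class_fold_change <- function(case_profiles, control_profiles,
                              classes = c("cluster", "TE", "genic"),
                              gene_set = NULL, pseudo = 0.5) {
  stopifnot(length(case_profiles) == length(control_profiles),
            length(case_profiles) >= 1L)
  n <- length(case_profiles)
  rows <- lapply(classes, function(cls) {
    case <- vapply(case_profiles, class_rpm, numeric(1), cls, gene_set)
    ctrl <- vapply(control_profiles, class_rpm, numeric(1), cls, gene_set)
    f <- fc_with_pseudo(case, ctrl, pseudo)
    out <- data.frame(unit = cls, fc_mean = mean(f$fc),
                      fc_sd = if (n > 1) sd(f$fc) else NA_real_,
                      n_pairs = n, pseudo_used = any(f$pseudo_used),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) out[[paste0("fc_", i)]] <- f$fc[i]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Gene-level RPM fold-change matrix
#'
#' Per-gene fold changes for each replicate pair plus a per-gene mean, and
#' a cohort summary (mean and SD of the per-gene mean fold change across
#' the gene set).
#'
#' @inheritParams class_fold_change
#' @param genes gene ids to analyze.
#' @return data.frame with one row per gene (`fc_1` .. `fc_n`, `fc_mean`);
#'   `attr(,"cohort")` holds `mean` and `sd` across genes.
#' @export
gene_fold_change_matrix <- function(case_profiles, control_profiles, genes,
                                    pseudo = 0.5) {
  stopifnot(length(case_profiles) == length(control_profiles))
  n <- length(case_profiles)
  per_pair <- lapply(seq_len(n), function(i) {
    gc <- case_profiles[[i]]$genes
    gg <- control_profiles[[i]]$genes
    case <- gc$rpm[match(genes, gc$gene_id)]
    ctrl <- gg$rpm[match(genes, gg$gene_id)]
    fc_with_pseudo(case, ctrl, pseudo)$fc
  })
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (i in seq_len(n)) out[[paste0("fc_", i)]] <- per_pair[[i]]
  out$fc_mean <- rowMeans(as.matrix(out[, paste0("fc_", seq_len(n)),
                                        drop = FALSE]))
  attr(out, "cohort") <- c(mean = mean(out$fc_mean), sd = sd(out$fc_mean))
  out
}

#' Correlation of gene fold changes between two conditions
#'
#' Pearson correlation of per-gene fold changes, computed on log2 fold
#' changes by default (fold changes are ratio-scaled).
#'
#' @param fc_a,fc_b numeric vectors over a matched gene universe.
#' @param log2_transform correlate `log2(fc)` rather than raw `fc`.
#' @return Pearson `r`; `NA` (flagged) for zero-variance input.
#' @export
fc_correlation <- function(fc_a, fc_b, log2_transform = TRUE) {
  stopifnot(length(fc_a) == length(fc_b), length(fc_a) >= 3L)
  keep <- is.finite(fc_a) & is.finite(fc_b) & fc_a > 0 & fc_b > 0
  a <- fc_a[keep]; b <- fc_b[keep]
  if (log2_transform) { a <- log2(a); b <- log2(b) }
  if (sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "zero variance"
    return(out)
  }
  cor(a, b, method = "pearson")
}

#' Degradome enrichment relative to polyadenylated transcripts
#'
#' Per-gene ratio of degradome fragment abundance (TPM) to polyadenylated
#' transcript abundance (TPM); genes under active piRNA-directed cleavage
#' accumulate 5'-monophosphate fragments in excess of their mRNA level.
#'
#' @param degradome_tpm,polya_tpm named numeric vectors (matched genes).
#' @param pseudo pseudocount.
#' @param genes optional subset of gene ids.
#' @return data.frame ranked by decreasing enrichment.
#' @export
degradome_enrichment <- function(degradome_tpm, polya_tpm, pseudo = 0.5,
                                 genes = NULL) {
  if (is.null(genes)) genes <- names(degradome_tpm)
  d <- degradome_tpm[genes]; p <- polya_tpm[genes]
  enr <- (d + pseudo) / (p + pseudo)
  out <- data.frame(gene_id = genes, degradome_tpm = as.numeric(d),
                    polya_tpm = as.numeric(p), enrichment = as.numeric(enr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
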