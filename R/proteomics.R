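#' Normalize spectral-count tables
#'
#' TurboID/BioID spectral counts: a pseudo value of 0.5 is added to every
#' identified protein, then counts are normalized by the total (adjusted)
#' peptide count of each run so that each normalized column sums to one.
#'
#' @param count_table numeric matrix or data.frame, proteins x runs, raw
#'   spectral counts.
#' @param pseudo pseudo value added to every entry.
#' @param per_condition optional factor/character of length `ncol` grouping
#'   runs into conditions; when given, totals are computed per condition
#'   rather than per run.
#' @return list with `adjusted` and `normalized` matrices.
#' @export
normalize_counts <- function(count_table, pseudo = 0.5, per_condition = NULL) {
  m <- as.matrix(count_table)
  if (length(m) == 0L) stop("empty count table")
  stopifnot(all(m >= 0))
  adj <- m + pseudo
  if (is.null(per_condition)) {
    norm <- sweep(adj, 2, colSums(adj), "/")
  } else {
    stopifnot(length(per_condition) == ncol(m))
    totals <- tapply(colSums(adj), per_condition, sum)
    norm <- sweep(adj, 2, as.numeric(totals[per_condition]), "/")
  }
  list(adjusted = adj, normalized = norm)
}

#' Spectral-count enrichment test
#'
#' For each protein: enrichment = mean normalized value in bait runs over
#' mean normalized value in control runs, and a two-tailed unpaired t-test
#' on the normalized values (Student's pooled-variance by default; Welch by
#' flag). Proteins with `p < p_cut` are flagged significant.
#'
#' @param normalized normalized matrix from [normalize_counts()].
#' @param bait_runs,control_runs column names or indices.
#' @param var_equal pooled-variance t-test (`TRUE`) or Welch (`FALSE`).
#' @param p_cut significance threshold.
#' @return data.frame of `ProteinEnrichmentRecord` rows: `protein_id`,
#'   `enrichment`, `p`, `significant`.
#' @export
enrichment_test <- function(normalized, bait_runs, control_runs,
                            var_equal = TRUE, p_cut = 0.01) {
  b <- normalized[, bait_runs, drop = FALSE]
  ctl <- normalized[, control_runs, drop = FALSE]
  enr <- rowMeans(b) / rowMeans(ctl)
  p <- vapply(seq_len(nrow(normalized)), function(i) {
    x <- as.numeric(b[i, ]); y <- as.numeric(ctl[i, ])
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (sd(c(x, y)) == 0) return(1)
    tryCatch(t.test(x, y, var.equal = var_equal,
                    alternative = "two.sided")$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  ids <- rownames(normalized) %||% as.character(seq_len(nrow(normalized)))
  data.frame(protein_id = ids, enrichment = enr, p = p,
             significant = !is.na(p) & p < p_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
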