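#' Run the CDS-piRNA host screen end-to-end on simulated libraries
#'
#' Convenience orchestration of the full pipeline on synthetic data: builds
#' toy assets, simulates total and Aub-IP small-RNA libraries plus an
#' mRNA-seq library, classifies every small-RNA library hierarchically
#' (23-29 nt analysis window and 18-29 nt size-profile window for the total
#' libraries), quantifies profiles, assembles screen records and calls host
#' genes.
#'
#' @param spec a [simulation_spec()].
#' @param seed base seed; library seeds are derived by small offsets.
#' @param n_total,n_aub numbers of total and Aub-IP replicate libraries.
#' @return list with `assets`, `spec`, `libraries` (reads + truth),
#'   `assignments`, `profiles`, `mrna`, `records` (with `call` column) and
#'   `truth` (the planted ground truth).
#' @export
run_host_screen <- function(spec = simulation_spec(), seed = spec$seed,
                            n_total = 2L, n_aub = 2L) {
  spec$seed <- seed
  assets <- build_toy_assets(spec)
  gt <- attr(assets, "ground_truth")
  libs <- list(); assigns <- list(); assigns_wide <- list(); profiles <- list()
  k <- 0L
  for (i in seq_len(n_total)) {
    k <- k + 1L
    lib <- simulate_srna_library(assets, spec, "total", seed = seed + k)
    sel <- size_select(lib$reads, 23L, 29L)
    a <- classify_hierarchical(sel$reads, assets, seed = seed + 100L + k)
    wide <- size_select(lib$reads, 18L, 29L)
    aw <- classify_hierarchical(wide$reads, assets, seed = seed + 200L + k)
    libs[[paste0("total_", i)]] <- lib
    assigns[[paste0("total_", i)]] <- a
    assigns_wide[[paste0("total_", i)]] <- aw
    profiles[[paste0("total_", i)]] <-
      quantify(a, assets, library = paste0("total_", i),
               total_raw = length(lib$reads))
  }
  aub_profiles <- list(); aub_assigns <- list()
  for (i in seq_len(n_aub)) {
    k <- k + 1L
    lib <- simulate_srna_library(assets, spec, "aub_ip", seed = seed + k)
    sel <- size_select(lib$reads, 23L, 29L)
    a <- classify_hierarchical(sel$reads, assets, seed = seed + 100L + k)
    libs[[paste0("aub_ip_", i)]] <- lib
    aub_assigns[[paste0("aub_ip_", i)]] <- a
    aub_profiles[[paste0("aub_ip_", i)]] <-
      quantify(a, assets, library = paste0("aub_ip_", i),
               total_raw = length(lib$reads))
  }
  mrna <- simulate_mrna_library(assets, spec, seed = seed + 50L)
  mrna_q <- quantify_mrna(mrna$reads, assets)
  mrna_tpm <- setNames(mrna_q$tpm, mrna_q$gene_id)
  records <- screen_hosts(
    total_profiles = profiles,
    total_assignments = assigns_wide,
    aub_profiles = aub_profiles,
    mrna_tpm = mrna_tpm, assets = assets)
  records <- call_hosts(records)
  list(assets = assets, spec = spec, libraries = libs,
       total_assignments = assigns, wide_assignments = assigns_wide,
       aub_assignments = aub_assigns,
       profiles = profiles, aub_profiles = aub_profiles,
       mrna = list(reads = mrna, quant = mrna_q), records = records,
       truth = gt)
}

#' Screen performance against planted truth
#'
#' Sensitivity and precision of the host call against the generator's
#' planted host-gene set.
#'
#' @param records output of [call_hosts()].
#' @param truth ground-truth list from the asset builder.
#' @return named numeric with `sensitivity`, `precision`, `n_called`.
#' @export
screen_performance <- function(records, truth) {
  called <- records$gene_id[records$call]
  hosts <- truth$host_genes
  tp <- length(intersect(called, hosts))
  c(sensitivity = if (length(hosts)) tp / length(hosts) else NA_real_,
    precision = if (length(called)) tp / length(called) else NA_real_,
    n_called = length(called))
}
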