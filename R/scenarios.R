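#' Build a synthetic soil-crust-like community
#'
#' Draws a community of `n_taxa` OTUs with lognormal baseline abundances
#' and a bimodal GC-content distribution: a dominant low-GC mode
#' (normal, mean 0.45, sd 0.04, clipped to \[0.33, 0.55\]) standing in for
#' the cyanobacterial/proteobacterial bulk of a biological soil crust, and
#' a minority high-GC mode (mean 0.67, sd 0.015, clipped to \[0.62, 0.72\],
#' probability `p_high_gc`) standing in for an actinobacteria-like guild.
#' Under the default gradient geometry only the high-GC guild straddles the
#' heavy/light boundary in the unlabeled state, which keeps the null REF
#' calibration of the scoring stage honest (see the methods vignette).
#'
#' `n_labeled` taxa are marked as isotope incorporators: their baseline
#' abundance is fixed at `labeled_abundance` each (so they clear the
#' whole-community abundance threshold by design), their atom-fraction
#' excess is set to `afe`, and their trophic ground truth to `"fixer"`;
#' all other taxa are `"inert"` with `afe = 0`.
#'
#' @param n_taxa Number of taxa (default 50).
#' @param n_labeled Number of labeled taxa (default 0; the null community).
#' @param afe Atom-fraction excess assigned to labeled taxa.
#' @param labeled_abundance Baseline abundance of each labeled taxon.
#' @param p_high_gc Probability a taxon belongs to the high-GC guild.
#' @param sdlog Lognormal spread of the unlabeled abundances.
#' @param seed Integer seed.
#' @return A community tibble suitable for [simulate_experiment()].
#' @export
sim_community <- function(n_taxa = 50L, n_labeled = 0L, afe = 0.9,
                          labeled_abundance = 0.03, p_high_gc = 0.1,
                          sdlog = 1.1, seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  n_labeled <- as.integer(n_labeled)
  if (n_labeled < 0L || n_labeled > n_taxa) {
    stop("`n_labeled` must lie in [0, n_taxa]", call. = FALSE)
  }
  if (n_labeled * labeled_abundance >= 1) {
    stop("labeled taxa would exceed the whole community", call. = FALSE)
  }
  set.seed(as.integer(seed))
  high <- stats::runif(n_taxa) < p_high_gc
  gc <- ifelse(high,
               pmin(pmax(stats::rnorm(n_taxa, 0.67, 0.015), 0.62), 0.72),
               pmin(pmax(stats::rnorm(n_taxa, 0.45, 0.04), 0.33), 0.55))
  ab <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)
  labeled <- rep(FALSE, n_taxa)
  if (n_labeled > 0L) labeled[sample.int(n_taxa, n_labeled)] <- TRUE
  ab[!labeled] <- ab[!labeled] / sum(ab[!labeled]) *
    (1 - n_labeled * labeled_abundance)
  ab[labeled] <- labeled_abundance
  tibble::tibble(
    taxon_id = sprintf("OTU_%03d", seq_len(n_taxa)),
    gc_content = gc,
    baseline_abundance = ab,
    atom_fraction_excess = ifelse(labeled, afe, 0),
    trophic_truth = ifelse(labeled, "fixer", "inert")
  )
}
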