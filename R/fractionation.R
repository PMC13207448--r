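#' Assign gradient fractions to the light or heavy pool
#'
#' Fractions are split at a buoyant-density threshold (1.7274 g/mL in the
#' study this package follows: fractions denser than the threshold carry
#' the isotopically heavy DNA). A fraction exactly at the threshold goes to
#' the side named by `equality_rule`; the default (`"heavy"`) reflects that
#' the reported heavy range starts at the threshold itself.
#'
#' @param meta Fraction metadata tibble with a `buoyant_density` column
#'   (g/mL), e.g. the `meta` element of a [simulate_gradient()] run or the
#'   output of [read_fraction_metadata()].
#' @param bd_threshold Stratification threshold, g/mL.
#' @param equality_rule `"heavy"` or `"light"`: pool receiving fractions at
#'   exactly the threshold.
#' @return `meta` with an added factor column `pool` (`"light"`/`"heavy"`).
#' @export
stratify_fractions <- function(meta, bd_threshold = 1.7274,
                               equality_rule = c("heavy", "light")) {
  equality_rule <- match.arg(equality_rule)
  if (nrow(meta) == 0L) stop("no fractions to stratify", call. = FALSE)
  bd <- meta$buoyant_density
  if (any(!is.finite(bd))) stop("non-finite buoyant density", call. = FALSE)
  heavy <- if (equality_rule == "heavy") bd >= bd_threshold else bd > bd_threshold
  if (all(heavy) || all(!heavy)) {
    warning("all fractions fell on one side of the threshold (",
            bd_threshold, " g/mL)", call. = FALSE)
  }
  meta$pool <- factor(ifelse(heavy, "heavy", "light"),
                      levels = c("light", "heavy"))
  meta
}

#' Pool fractions into one relative-abundance vector
#'
#' The pooled abundance of a taxon is the weighted mean of its per-fraction
#' relative abundances, `sum_f w_f * share_{taxon,f}`, with weights
#' normalized over the pooled fractions:
#' * `"dna_quantity"` (default) weights each fraction by its DNA quantity,
#'   emulating physical pooling of the fraction DNA before sequencing;
#' * `"counts"` weights by total reads, equivalent to relative abundances
#'   of the summed raw counts;
#' * `"equal"` averages the per-fraction proportions.
#'
#' Fractions with zero reads (and, for `"dna_quantity"`, zero DNA) carry no
#' weight, so the pooled vector always sums to 1.
#'
#' @param counts Taxa-by-fractions count matrix (column names = sample ids).
#' @param dna_quantity Numeric vector of per-fraction DNA quantities,
#'   aligned with `counts` columns; required for the default weighting.
#' @param weighting Weighting scheme (see above).
#' @return Named numeric vector of pooled relative abundances (sums to 1).
#' @export
pool_counts <- function(counts, dna_quantity = NULL,
                        weighting = c("dna_quantity", "counts", "equal")) {
  weighting <- match.arg(weighting)
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("no fractions to pool", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  tot <- colSums(counts)
  w <- switch(weighting,
    dna_quantity = {
      if (is.null(dna_quantity) || length(dna_quantity) != ncol(counts)) {
        stop("`dna_quantity` must match the pooled fractions", call. = FALSE)
      }
      dna_quantity
    },
    counts = tot,
    equal = rep(1, ncol(counts))
  )
  w[tot == 0] <- 0  # a fraction with no reads contributes nothing
  if (sum(w) <= 0) stop("zero total pooling weight", call. = FALSE)
  w <- w / sum(w)
  share <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), "/")
  drop(share %*% w)
}

#' Build the four pooled profiles feeding the REF statistic
#'
#' Stratifies the fractions of a paired 12C/13C treatment at the BD
#' threshold and pools each (isotope, pool) cell into a relative-abundance
#' vector over the union of the taxa seen in either treatment (a taxon
#' absent from a pool gets abundance 0).
#'
#' @param counts Taxa-by-samples count matrix covering both isotopes.
#' @param meta Fraction metadata tibble (one row per column of `counts`)
#'   with `sample_id`, `isotope` and `buoyant_density`; `dna_quantity` is
#'   required for the default weighting.
#' @param bd_threshold,equality_rule Passed to [stratify_fractions()].
#' @param weighting Passed to [pool_counts()].
#' @return A tibble with `taxon_id`, `heavy_13C`, `light_13C`, `heavy_12C`,
#'   `light_12C`; each column sums to 1.
#' @export
build_profiles <- function(counts, meta, bd_threshold = 1.7274,
                           equality_rule = c("heavy", "light"),
                           weighting = c("dna_quantity", "counts", "equal")) {
  equality_rule <- match.arg(equality_rule)
  weighting <- match.arg(weighting)
  counts <- as.matrix(counts)
  if (!all(meta$sample_id %in% colnames(counts))) {
    stop("metadata sample_id missing from the count table", call. = FALSE)
  }
  if (!all(c("12C", "13C") %in% meta$isotope)) {
    stop("both 12C and 13C treatments are required", call. = FALSE)
  }
  meta <- stratify_fractions(meta, bd_threshold, equality_rule)
  taxa <- sort(rownames(counts))
  cell <- function(iso, pool) {
    sel <- meta$isotope == iso & meta$pool == pool
    if (!any(sel)) {
      stop("no ", pool, " fractions in the ", iso, " treatment", call. = FALSE)
    }
    sub <- counts[, meta$sample_id[sel], drop = FALSE]
    pool_counts(sub, dna_quantity = meta$dna_quantity[sel],
                weighting = weighting)[taxa]
  }
  tibble::tibble(
    taxon_id = taxa,
    heavy_13C = cell("13C", "heavy"),
    light_13C = cell("13C", "light"),
    heavy_12C = cell("12C", "heavy"),
    light_12C = cell("12C", "light")
  )
}

#' @rdname build_profiles
#' @param experiment A [simulate_experiment()] result.
#' @export
build_profiles_from_experiment <- function(experiment, bd_threshold = 1.7274,
                                           equality_rule = c("heavy", "light"),
                                           weighting = c("dna_quantity",
                                                         "counts", "equal")) {
  stopifnot(inherits(experiment, "sip_experiment"))
  counts <- cbind(experiment$run_12C$counts, experiment$run_13C$counts)
  meta <- rbind(experiment$run_12C$meta, experiment$run_13C$meta)
  build_profiles(counts, meta, bd_threshold,
                 match.arg(equality_rule), match.arg(weighting))
}
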