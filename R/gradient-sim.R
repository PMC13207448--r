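#' Configuration for a simulated CsCl buoyant-density gradient
#'
#' Collects the physical and sequencing parameters of a simulated isopycnic
#' ultracentrifugation run. Defaults mirror a typical DNA-SIP setup: twelve
#' fractions spanning 1.690--1.775 g/mL, a within-taxon band spread of
#' 0.004 g/mL, a full-labeling density shift of 0.036 g/mL, and the
#' Schildkraut relation between genomic GC content and unlabeled buoyant
#' density (BD = 1.660 + 0.098 * GC).
#'
#' @param n_fractions Number of gradient fractions collected (>= 2).
#' @param bd_min,bd_max Buoyant-density range of the gradient, g/mL.
#' @param density_sd Within-taxon spread of DNA buoyant density, g/mL.
#' @param shift_per_afe Density shift per unit atom-fraction excess, g/mL.
#' @param schildkraut_intercept,schildkraut_slope Coefficients of the
#'   GC-to-density relation, g/mL and g/mL per GC fraction.
#' @param depth_per_fraction Sequencing depth (reads) drawn per fraction.
#' @param dna_total Total DNA mass loaded on the gradient (mass units;
#'   the default emulates a ~5 ug load).
#' @param seed Integer seed for the experiment's pseudo-random stream.
#'
#' @return A list of class `gradient_config`.
#' @export
#' @examples
#' cfg <- gradient_config(seed = 1)
#' unlabeled_bd(0.5, cfg)
gradient_config <- function(n_fractions = 12L,
                            bd_min = 1.690,
                            bd_max = 1.775,
                            density_sd = 0.004,
                            shift_per_afe = 0.036,
                            schildkraut_intercept = 1.660,
                            schildkraut_slope = 0.098,
                            depth_per_fraction = 50000L,
                            dna_total = 5,
                            seed = 1L) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 2L) {
    stop("`n_fractions` must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(bd_min) || !is.finite(bd_max) || bd_min <= 0 || bd_max <= bd_min) {
    stop("need 0 < bd_min < bd_max", call. = FALSE)
  }
  if (density_sd <= 0) stop("`density_sd` must be positive", call. = FALSE)
  if (shift_per_afe < 0) stop("`shift_per_afe` must be >= 0", call. = FALSE)
  if (depth_per_fraction < 1) stop("`depth_per_fraction` must be >= 1", call. = FALSE)
  if (dna_total <= 0) stop("`dna_total` must be positive", call. = FALSE)
  structure(
    list(
      n_fractions = n_fractions,
      bd_min = bd_min,
      bd_max = bd_max,
      density_sd = density_sd,
      shift_per_afe = shift_per_afe,
      schildkraut_intercept = schildkraut_intercept,
      schildkraut_slope = schildkraut_slope,
      depth_per_fraction = as.integer(depth_per_fraction),
      dna_total = dna_total,
      seed = as.integer(seed)
    ),
    class = "gradient_config"
  )
}

#' Unlabeled buoyant density of genomic DNA from its GC content
#'
#' Applies the Schildkraut relation: BD = intercept + slope * GC.
#'
#' @param gc_content GC content as a fraction in \[0, 1\] (vectorized).
#' @param config A [gradient_config()].
#' @return Buoyant density in g/mL.
#' @export
unlabeled_bd <- function(gc_content, config = gradient_config()) {
  if (any(!is.finite(gc_content)) || any(gc_content < 0) || any(gc_content > 1)) {
    stop("`gc_content` must lie in [0, 1]", call. = FALSE)
  }
  config$schildkraut_intercept + config$schildkraut_slope * gc_content
}

#' Buoyant density after heavy-isotope incorporation
#'
#' A taxon whose DNA carries an atom-fraction excess `afe` of the heavy
#' isotope bands at `bd_unlabeled + shift_per_afe * afe`.
#'
#' @param bd_unlabeled Unlabeled buoyant density, g/mL (vectorized).
#' @param afe Atom-fraction excess in \[0, 1\] (vectorized).
#' @param config A [gradient_config()].
#' @return Buoyant density in g/mL.
#' @export
labeled_bd <- function(bd_unlabeled, afe, config = gradient_config()) {
  if (any(!is.finite(afe)) || any(afe < 0) || any(afe > 1)) {
    stop("`afe` must lie in [0, 1]", call. = FALSE)
  }
  bd_unlabeled + config$shift_per_afe * afe
}

#' Fraction bins of a gradient
#'
#' Fractions are equal-width bins over `[bd_min, bd_max]`, half-open
#' `[low, high)` with the densest bin closed at the top. Fraction numbering
#' runs from high to low density (fraction 1 is the densest), matching the
#' convention in which the heavy DNA peak sits at a lower fraction index
#' than the light peak. The bin midpoint is reported as the fraction's BD.
#'
#' @param config A [gradient_config()].
#' @return A tibble with `fraction_index`, `bd_low`, `bd_high`,
#'   `buoyant_density` (midpoint).
#' @export
fraction_bins <- function(config = gradient_config()) {
  breaks <- seq(config$bd_min, config$bd_max, length.out = config$n_fractions + 1L)
  n <- config$n_fractions
  # fraction 1 = densest bin
  low <- rev(breaks[seq_len(n)])
  high <- rev(breaks[seq_len(n) + 1L])
  tibble::tibble(
    fraction_index = seq_len(n),
    bd_low = low,
    bd_high = high,
    buoyant_density = (low + high) / 2
  )
}

validate_community <- function(community) {
  req <- c("taxon_id", "gc_content", "baseline_abundance",
           "atom_fraction_excess", "trophic_truth")
  missing <- setdiff(req, names(community))
  if (length(missing)) {
    stop("community is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(community) == 0L) stop("community must be nonempty", call. = FALSE)
  if (anyDuplicated(community$taxon_id)) {
    stop("duplicate taxon_id in community", call. = FALSE)
  }
  if (abs(sum(community$baseline_abundance) - 1) > 1e-9) {
    stop("baseline abundances must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(community$gc_content < 0 | community$gc_content > 1)) {
    stop("gc_content out of [0, 1]", call. = FALSE)
  }
  if (any(community$atom_fraction_excess < 0 | community$atom_fraction_excess > 1)) {
    stop("atom_fraction_excess out of [0, 1]", call. = FALSE)
  }
  invisible(community)
}

#' Expected per-fraction DNA mass for each taxon
#'
#' Each taxon's DNA bands as a normal density centered on its (possibly
#' shifted) buoyant density with spread `density_sd`; the mass landing in
#' each fraction is the integral of that density over the fraction's bin,
#' renormalized to the part of the band inside the gradient so that mass
#' is conserved across fractions.
#'
#' @param community Tibble with columns `taxon_id`, `gc_content`,
#'   `baseline_abundance`, `atom_fraction_excess`, `trophic_truth`.
#' @param config A [gradient_config()].
#' @return A taxa-by-fractions matrix of DNA mass (rownames = taxon ids,
#'   columns ordered by `fraction_index`).
#' @export
taxon_fraction_masses <- function(community, config = gradient_config()) {
  validate_community(community)
  bins <- fraction_bins(config)
  mu <- labeled_bd(unlabeled_bd(community$gc_content, config),
                   community$atom_fraction_excess, config)
  sd <- config$density_sd
  total <- config$dna_total * community$baseline_abundance
  in_range <- stats::pnorm(config$bd_max, mu, sd) - stats::pnorm(config$bd_min, mu, sd)
  lost <- in_range < 1e-12
  if (any(lost)) {
    stop("all DNA mass outside the gradient for taxon ",
         paste(community$taxon_id[lost], collapse = ", "), call. = FALSE)
  }
  m <- vapply(seq_len(nrow(bins)), function(f) {
    p <- stats::pnorm(bins$bd_high[f], mu, sd) - stats::pnorm(bins$bd_low[f], mu, sd)
    total * p / in_range
  }, numeric(nrow(community)))
  m <- matrix(m, nrow = nrow(community),
              dimnames = list(community$taxon_id, NULL))
  colnames(m) <- sprintf("F%02d", bins$fraction_index)
  m
}

#' Simulate one density-gradient fractionation run
#'
#' Distributes each taxon's DNA over the gradient's fractions (see
#' [taxon_fraction_masses()]) and draws per-fraction sequencing counts from
#' a multinomial with probabilities proportional to per-taxon mass in that
#' fraction. A fraction with no DNA yields zero counts.
#'
#' @param community Community tibble (see [taxon_fraction_masses()]).
#' @param config A [gradient_config()].
#' @param seed Integer seed for this run's random stream; defaults to
#'   `config$seed`.
#' @param isotope Label recorded in the run's metadata, `"12C"` or `"13C"`.
#' @param compartment,phase Metadata labels carried through to outputs.
#' @return A list of class `sip_gradient` with elements `meta` (tibble:
#'   `sample_id`, `isotope`, `compartment`, `phase`, `fraction_index`,
#'   `buoyant_density`, `dna_quantity`), `counts` (taxa x fractions integer
#'   matrix), and `masses` (the expected-mass matrix).
#' @export
simulate_gradient <- function(community, config = gradient_config(),
                              seed = config$seed, isotope = "13C",
                              compartment = "BSC", phase = "RP") {
  isotope <- match.arg(isotope, c("12C", "13C"))
  masses <- taxon_fraction_masses(community, config)
  bins <- fraction_bins(config)
  set.seed(as.integer(seed))
  counts <- vapply(seq_len(ncol(masses)), function(f) {
    mass <- masses[, f]
    if (sum(mass) <= 0) return(integer(length(mass)))
    drop(stats::rmultinom(1L, config$depth_per_fraction, prob = mass))
  }, integer(nrow(masses)))
  counts <- matrix(counts, nrow = nrow(masses))
  rownames(counts) <- rownames(masses)
  sample_id <- paste0(isotope, "_", colnames(masses))
  colnames(counts) <- sample_id
  meta <- tibble::tibble(
    sample_id = sample_id,
    isotope = isotope,
    compartment = compartment,
    phase = phase,
    fraction_index = bins$fraction_index,
    buoyant_density = bins$buoyant_density,
    dna_quantity = colSums(masses)
  )
  structure(list(meta = meta, counts = counts, masses = masses),
            class = "sip_gradient")
}

#' Simulate a paired 12C/13C SIP experiment
#'
#' Runs [simulate_gradient()] twice on the same community: once with all
#' atom-fraction excesses forced to zero (the 12C control) and once as
#' given (the 13C treatment). An unfractionated whole-community sample is
#' also drawn from the baseline abundances, standing in for the original
#' (pre-fractionation) sequencing library that supplies whole-community
#' relative abundances. Sub-seeds for the three draws are derived
#' deterministically from `config$seed`, so identical seed and
#' configuration reproduce identical tables.
#'
#' @param community Community tibble; `atom_fraction_excess > 0` marks the
#'   ground-truth labeled taxa.
#' @param config A [gradient_config()].
#' @param compartment,phase Metadata labels.
#' @return A list of class `sip_experiment`: `run_12C` and `run_13C`
#'   (`sip_gradient` objects), `community_counts` (named integer vector of
#'   the unfractionated sample), `community`, `config`, and `truth`
#'   (taxon ids with `atom_fraction_excess > 0`).
#' @export
simulate_experiment <- function(community, config = gradient_config(),
                                compartment = "BSC", phase = "RP") {
  validate_community(community)
  set.seed(config$seed)
  sub <- sample.int(2147483646L, 3L)
  unlabeled <- community
  unlabeled$atom_fraction_excess <- 0
  run_12C <- simulate_gradient(unlabeled, config, seed = sub[1L],
                               isotope = "12C", compartment = compartment,
                               phase = phase)
  run_13C <- simulate_gradient(community, config, seed = sub[2L],
                               isotope = "13C", compartment = compartment,
                               phase = phase)
  set.seed(sub[3L])
  comm_counts <- drop(stats::rmultinom(1L, config$depth_per_fraction,
                                       prob = community$baseline_abundance))
  names(comm_counts) <- community$taxon_id
  structure(
    list(run_12C = run_12C, run_13C = run_13C,
         community_counts = comm_counts,
         community = community, config = config,
         compartment = compartment, phase = phase,
         truth = community$taxon_id[community$atom_fraction_excess > 0]),
    class = "sip_experiment"
  )
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat("Simulated SIP experiment (", x$compartment, "/", x$phase, "): ",
      nrow(x$community), " taxa, ", x$config$n_fractions,
      " fractions per run, ", length(x$truth), " labeled taxa\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the OTU-by-sample count table (TSV), the fraction metadata (CSV),
#' the unfractionated community counts (TSV) and the ground-truth labeled
#' set (JSON) in the dialect the readers in this package accept.
#'
#' @param experiment A `sip_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_sip_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sip_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- cbind(experiment$run_12C$counts, experiment$run_13C$counts)
  meta <- rbind(experiment$run_12C$meta, experiment$run_13C$meta)
  paths <- c(
    counts = file.path(dir, "fraction_counts.tsv"),
    metadata = file.path(dir, "fraction_metadata.csv"),
    community = file.path(dir, "community_counts.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_otu_table(counts, paths[["counts"]])
  meta_out <- meta
  names(meta_out)[names(meta_out) == "buoyant_density"] <- "buoyant_density_g_per_ml"
  readr::write_csv(meta_out, paths[["metadata"]])
  readr::write_tsv(
    tibble::tibble(taxon_id = names(experiment$community_counts),
                   count = unname(experiment$community_counts)),
    paths[["community"]]
  )
  jsonlite::write_json(
    list(labeled_taxa = experiment$truth,
         seed = experiment$config$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
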