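#' Relative enrichment factor (REF)
#'
#' REF compares a taxon's heavy-to-light abundance ratio between the 13C
#' treatment and the 12C control:
#' `REF = (heavy_13C / light_13C) / (heavy_12C / light_12C)`.
#' Values above 1 indicate that the taxon's DNA moved toward the heavy
#' pool under the labeled substrate, i.e. isotope incorporation.
#'
#' Zero handling: a zero in any of `light_13C`, `heavy_12C` or `light_12C`
#' makes the ratio undefined and REF is returned as `NA` (the taxon can
#' then never be called active). A zero numerator (`heavy_13C`) simply
#' gives REF 0. When `detection_floor > 0`, zeros in the three
#' denominator-side components are replaced by the floor before the ratio
#' is formed — a detection-limit substitution for taxa whose DNA has left
#' one pool entirely (e.g. fully labeled genomes vanish from the 13C-light
#' pool). The numerator is never floored, so absence from the heavy pool
#' cannot manufacture enrichment. A floor of one read-equivalent,
#' `1 / depth`, is the suggested exploratory setting; the default (0)
#' applies no substitution.
#'
#' @param profile Pooled-profile tibble from [build_profiles()].
#' @param taxon_id Optional single taxon id; if given, the scalar REF for
#'   that taxon is returned (error if absent from the profile).
#' @param detection_floor Relative abundance substituted for zeros in
#'   `light_13C`, `heavy_12C`, `light_12C` (default 0 = off).
#' @return With `taxon_id`: a single number (or `NA`). Otherwise `profile`
#'   with an added `ref_value` column.
#' @export
compute_ref <- function(profile, taxon_id = NULL, detection_floor = 0) {
  req <- c("taxon_id", "heavy_13C", "light_13C", "heavy_12C", "light_12C")
  missing <- setdiff(req, names(profile))
  if (length(missing)) {
    stop("profile is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (detection_floor < 0) stop("`detection_floor` must be >= 0", call. = FALSE)
  floor0 <- function(x) ifelse(x == 0 & detection_floor > 0, detection_floor, x)
  l13 <- floor0(profile$light_13C)
  h12 <- floor0(profile$heavy_12C)
  l12 <- floor0(profile$light_12C)
  ref <- ifelse(l13 == 0 | h12 == 0 | l12 == 0, NA_real_,
                (profile$heavy_13C / l13) / (h12 / l12))
  if (!is.null(taxon_id)) {
    i <- match(taxon_id, profile$taxon_id)
    if (is.na(i)) stop("unknown taxon: ", taxon_id, call. = FALSE)
    return(ref[i])
  }
  profile$ref_value <- ref
  profile
}

#' Score taxa and call the active ones
#'
#' Combines REF scoring with the dual activity threshold used to identify
#' active substrate assimilators: a taxon is active when `ref_value`
#' strictly exceeds `ref_threshold` (default 1.0) AND its whole-community
#' relative abundance strictly exceeds `ra_threshold` (default 1%). The
#' abundance criterion applies to the unfractionated community, not the
#' heavy pool. Taxa with undefined REF are never active.
#'
#' @param profile Pooled-profile tibble from [build_profiles()].
#' @param community_ra Named numeric vector of whole-community relative
#'   abundances (fractions of 1), or a two-column tibble/data.frame
#'   (`taxon_id`, abundance). Taxa absent from it get abundance 0.
#' @param ref_threshold,ra_threshold Strict lower activity thresholds.
#' @param detection_floor Passed to [compute_ref()].
#' @return A tibble (one row per taxon) with the four pooled abundances,
#'   `ref_value`, `heavy_ra` (= `heavy_13C`), `community_ra` and `active`,
#'   ordered by descending `ref_value` (undefined last), ties broken by
#'   `taxon_id`.
#' @export
ref_results <- function(profile, community_ra, ref_threshold = 1.0,
                        ra_threshold = 0.01, detection_floor = 0) {
  if (is.data.frame(community_ra)) {
    community_ra <- stats::setNames(community_ra[[2L]], community_ra[[1L]])
  }
  if (any(community_ra < 0)) stop("negative community abundance", call. = FALSE)
  # raw counts (summing beyond 1) are converted to relative abundances;
  # values already on the [0, 1] scale are taken as given
  if (sum(community_ra) > 1 + 1e-6) {
    community_ra <- community_ra / sum(community_ra)
  }
  res <- compute_ref(profile, detection_floor = detection_floor)
  res$heavy_ra <- res$heavy_13C
  ra <- community_ra[res$taxon_id]
  ra[is.na(ra)] <- 0
  res$community_ra <- unname(ra)
  res$active <- !is.na(res$ref_value) &
    res$ref_value > ref_threshold &
    res$community_ra > ra_threshold
  res[order(-ifelse(is.na(res$ref_value), -Inf, res$ref_value),
            res$taxon_id), , drop = FALSE]
}

#' Active taxon ids
#'
#' @param results A [ref_results()] tibble.
#' @return Character vector of active taxon ids, ordered by descending REF
#'   (ties by taxon id).
#' @export
call_active <- function(results) {
  results$taxon_id[results$active]
}

#' Classify a labeled taxon as carbon fixer or transformer
#'
#' Looks a semicolon-delimited lineage up in a trophic reference table.
#' An exact lineage match wins; otherwise, with
#' `neighbor_rule = "nearest_annotated_lineage"`, the deepest shared
#' lineage prefix with any annotated reference entry decides (the
#' phylogenetic-neighbor heuristic: unclassified taxa inherit the
#' annotation of their closest annotated relative). If nothing matches —
#' or annotations conflict at the matched depth — the conservative
#' `default_class` applies: a labeled taxon without autotrophy evidence is
#' presumed a transformer (a heterotroph acquiring label via
#' cross-feeding).
#'
#' @param lineage Character vector of semicolon-delimited lineages (e.g.
#'   `"Bacteria;Cyanobacteria;...;Scytonema hyalinum"`).
#' @param reference Tibble/data.frame with columns `lineage` and `class`
#'   (`"fixer"`/`"transformer"`); lineages must be unique.
#' @param neighbor_rule `"nearest_annotated_lineage"` or `"none"`.
#' @param default_class Class assigned when no evidence is found.
#' @return Character vector in `{fixer, transformer, unknown}`.
#' @export
classify_trophic <- function(lineage, reference,
                             neighbor_rule = c("nearest_annotated_lineage",
                                               "none"),
                             default_class = c("transformer", "unknown")) {
  neighbor_rule <- match.arg(neighbor_rule)
  default_class <- match.arg(default_class)
  if (!all(c("lineage", "class") %in% names(reference))) {
    stop("reference needs `lineage` and `class` columns", call. = FALSE)
  }
  if (anyDuplicated(reference$lineage)) {
    stop("duplicate lineages in the trophic reference", call. = FALSE)
  }
  split_ranks <- function(x) trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  ref_ranks <- lapply(reference$lineage, split_ranks)
  vapply(lineage, function(lin) {
    q <- split_ranks(lin)
    q <- q[nzchar(q)]
    if (length(q) == 0L) stop("empty lineage", call. = FALSE)
    exact <- vapply(ref_ranks, function(r) identical(r, q), logical(1L))
    if (any(exact)) return(reference$class[exact][1L])
    if (neighbor_rule == "none") return(default_class)
    for (depth in rev(seq_along(q))) {
      hit <- vapply(ref_ranks, function(r) {
        length(r) >= depth && identical(r[seq_len(depth)], q[seq_len(depth)])
      }, logical(1L))
      if (any(hit)) {
        cls <- unique(reference$class[hit])
        return(if (length(cls) == 1L) cls else default_class)
      }
    }
    default_class
  }, character(1L), USE.NAMES = FALSE)
}

#' Relative biomass of a taxon or group
#'
#' Relative biomass = RA x C: a group's share of the community times the
#' extractable DNA concentration of the sample, in the units of `dna_conc`
#' (conventionally ug DNA per g soil).
#'
#' @param ra Relative abundance in \[0, 1\] (vectorized).
#' @param dna_conc DNA concentration, >= 0 (ug per g soil).
#' @return `ra * dna_conc`.
#' @export
relative_biomass <- function(ra, dna_conc) {
  if (any(ra < 0 | ra > 1)) stop("`ra` must lie in [0, 1]", call. = FALSE)
  if (any(dna_conc < 0)) stop("`dna_conc` must be >= 0", call. = FALSE)
  ra * dna_conc
}

#' Community share of the active carbon fixers
#'
#' Sums the whole-community relative abundances of the active taxa
#' classified as fixers, in percent. Internal math is unrounded; round at
#' presentation only.
#'
#' @param results Tibble with `active`, `trophic_class` and `community_ra`
#'   columns (e.g. [ref_results()] output augmented with `trophic_class`,
#'   or one group of the packaged study fixture).
#' @return Percentage in \[0, 100\] (0 for an empty set).
#' @export
fixer_community_fraction <- function(results) {
  sel <- results$active & results$trophic_class == "fixer"
  100 * sum(results$community_ra[sel])
}

#' Fixer share of the labeled taxa
#'
#' Among the unique labeled (active) taxa of a group — conventionally a
#' compartment, pooling its phases — the percentage classified as fixers.
#'
#' @param labeled Tibble with `taxon_id` and `trophic_class` for the
#'   labeled taxa (rows may repeat across phases; taxa are deduplicated).
#' @return Percentage, or `NA` (with a warning) when no taxa are labeled.
#' @export
fixer_share_of_labeled <- function(labeled) {
  ids <- unique(labeled$taxon_id)
  if (length(ids) == 0L) {
    warning("no labeled taxa; share undefined", call. = FALSE)
    return(NA_real_)
  }
  cls <- labeled$trophic_class[match(ids, labeled$taxon_id)]
  if (anyNA(cls)) stop("every labeled taxon must be classified", call. = FALSE)
  100 * sum(cls == "fixer") / length(ids)
}

#' Count unique active taxa within a grouping
#'
#' @param results Tibble with `taxon_id`, `active`, and grouping columns
#'   (`phase`, `compartment`).
#' @param by `"phase"`, `"compartment"`, `c("phase", "compartment")`, or
#'   `"none"` for the global union.
#' @return A tibble with the grouping columns and `n_active` (unique
#'   active taxon ids per group), or a single-row tibble for `"none"`.
#' @export
count_active <- function(results, by = "none") {
  act <- results[results$active, , drop = FALSE]
  if (identical(by, "none")) {
    return(tibble::tibble(n_active = length(unique(act$taxon_id))))
  }
  bad <- setdiff(by, c("phase", "compartment"))
  if (length(bad)) {
    stop("unknown grouping key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(act, dplyr::across(dplyr::all_of(by))),
                   n_active = dplyr::n_distinct(.data$taxon_id),
                   .groups = "drop")
}
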