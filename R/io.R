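#' Read an OTU count/abundance table
#'
#' Expects a TSV whose header row holds sample ids and whose first column
#' holds taxon ids (the dialect [write_otu_table()] emits).
#'
#' @param path Path to the TSV.
#' @return A taxa-by-samples numeric matrix.
#' @export
read_otu_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) stop("OTU table needs taxon ids plus >= 1 sample",
                           call. = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    stop("malformed OTU table at line ", prob$row[1L] + 1L, ": ",
         prob$expected[1L], call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in OTU table", call. = FALSE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value at line ", bad[["row"]] + 1L, call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at line ", bad[["row"]] + 1L, call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write an OTU table as TSV
#'
#' @param m Taxa-by-samples matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(m, path) {
  out <- tibble::as_tibble(m, rownames = "taxon_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read fraction metadata
#'
#' Expects a CSV with columns `sample_id`, `isotope` (12C/13C),
#' `compartment` (BSC/US), `phase` (OS/RP/SHP), `fraction_index`,
#' `buoyant_density_g_per_ml` (or `buoyant_density`), `dna_quantity`.
#' Enumerations and ranges are validated; errors name the offending cell.
#'
#' @param path Path to the CSV.
#' @return A tibble with a `buoyant_density` column in g/mL.
#' @export
read_fraction_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("buoyant_density_g_per_ml" %in% names(meta)) {
    names(meta)[names(meta) == "buoyant_density_g_per_ml"] <- "buoyant_density"
  }
  req <- c("sample_id", "isotope", "compartment", "phase", "fraction_index",
           "buoyant_density", "dna_quantity")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    bad <- which(!(meta[[col]] %in% allowed))
    if (length(bad)) {
      stop("invalid ", col, " '", meta[[col]][bad[1L]], "' in metadata row ",
           bad[1L], call. = FALSE)
    }
  }
  check_enum("isotope", c("12C", "13C"))
  check_enum("compartment", c("BSC", "US"))
  check_enum("phase", c("OS", "RP", "SHP"))
  bad_bd <- which(!is.finite(meta$buoyant_density) |
                    meta$buoyant_density <= 1.5 | meta$buoyant_density >= 1.9)
  if (length(bad_bd)) {
    stop("implausible buoyant density '", meta$buoyant_density[bad_bd[1L]],
         "' in metadata row ", bad_bd[1L], call. = FALSE)
  }
  if (any(meta$dna_quantity < 0)) {
    stop("negative dna_quantity in metadata", call. = FALSE)
  }
  dup <- duplicated(meta[, c("isotope", "compartment", "phase",
                             "fraction_index")])
  if (any(dup)) {
    stop("duplicate fraction_index within a treatment (metadata row ",
         which(dup)[1L], ")", call. = FALSE)
  }
  meta
}

#' Run the full SIP identification pipeline from files on disk
#'
#' Reads the fraction count table, fraction metadata and whole-community
#' counts, builds pooled light/heavy profiles, scores REF, calls active
#' taxa, optionally classifies them against a trophic reference, and
#' writes `pooled_profiles.tsv`, `ref_results.tsv` and `summary.json` to
#' `out_dir`. The run is deterministic (no random numbers are drawn) and
#' the thresholds in force are recorded in the summary.
#'
#' @param counts_path TSV of fraction-level counts ([read_otu_table()]).
#' @param metadata_path CSV of fraction metadata
#'   ([read_fraction_metadata()]).
#' @param community_path TSV with columns `taxon_id`, `count` (the
#'   unfractionated whole-community library).
#' @param out_dir Output directory.
#' @param taxonomy_path Optional TSV with `taxon_id`, `lineage`
#'   (semicolon-delimited).
#' @param trophic_path Optional CSV with `lineage`, `class` used to
#'   classify active taxa; without it every active taxon is `"unknown"`.
#' @param bd_threshold,equality_rule,weighting Stratification and pooling
#'   settings (see [build_profiles()]).
#' @param ref_threshold,ra_threshold,detection_floor Activity-calling
#'   settings (see [ref_results()]).
#' @return Invisibly, the [ref_results()] tibble (with `trophic_class`).
#' @export
run_sip_pipeline <- function(counts_path, metadata_path, community_path,
                             out_dir,
                             taxonomy_path = NULL, trophic_path = NULL,
                             bd_threshold = 1.7274,
                             equality_rule = "heavy",
                             weighting = "dna_quantity",
                             ref_threshold = 1.0, ra_threshold = 0.01,
                             detection_floor = 0) {
  counts <- read_otu_table(counts_path)
  meta <- read_fraction_metadata(metadata_path)
  community <- readr::read_tsv(community_path, show_col_types = FALSE,
                               progress = FALSE)
  if (!all(c("taxon_id", "count") %in% names(community))) {
    stop("community table needs `taxon_id` and `count`", call. = FALSE)
  }
  profile <- build_profiles(counts, meta, bd_threshold = bd_threshold,
                            equality_rule = equality_rule,
                            weighting = weighting)
  res <- ref_results(profile,
                     stats::setNames(community$count, community$taxon_id),
                     ref_threshold = ref_threshold,
                     ra_threshold = ra_threshold,
                     detection_floor = detection_floor)
  res$trophic_class <- "unknown"
  if (!is.null(taxonomy_path) && !is.null(trophic_path)) {
    taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                                progress = FALSE)
    reference <- readr::read_csv(trophic_path, show_col_types = FALSE,
                                 progress = FALSE)
    lin <- taxonomy$lineage[match(res$taxon_id, taxonomy$taxon_id)]
    has <- !is.na(lin)
    res$trophic_class[has] <- classify_trophic(lin[has], reference)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(profile, file.path(out_dir, "pooled_profiles.tsv"))
  readr::write_tsv(res, file.path(out_dir, "ref_results.tsv"))
  summary <- list(
    settings = list(bd_threshold = bd_threshold,
                    equality_rule = equality_rule,
                    weighting = weighting,
                    ref_threshold = ref_threshold,
                    ra_threshold = ra_threshold,
                    detection_floor = detection_floor),
    n_taxa = nrow(res),
    n_active = sum(res$active),
    active_taxa = call_active(res),
    fixer_community_pct =
      if (any(res$trophic_class != "unknown")) {
        round2(fixer_community_fraction(res))
      } else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
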