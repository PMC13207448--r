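profile_of <- function(h13, l13, h12, l12, ids = NULL) {
  n <- length(h13)
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(n))
  tibble::tibble(
    taxon_id = ids,
    heavy_13C = h13, light_13C = l13, heavy_12C = h12, light_12C = l12
  )
}

test_that("REF is the ratio of heavy/light ratios with strict zero handling", {
  p <- profile_of(h13 = c(0.01, 0.02, 0.00, 0.02),
                  l13 = c(0.01, 0.01, 0.01, 0.00),
                  h12 = c(0.01, 0.01, 0.01, 0.01),
                  l12 = c(0.01, 0.01, 0.01, 0.01))
  r <- compute_ref(p)
  expect_equal(r$ref_value[1L], 1.0)
  expect_equal(r$ref_value[2L], 2.0)
  expect_equal(r$ref_value[3L], 0.0)       # zero numerator is defined
  expect_true(is.na(r$ref_value[4L]))      # zero 13C-light is undefined
  expect_equal(compute_ref(p, taxon_id = "T02"), 2.0)
  expect_error(compute_ref(p, taxon_id = "nope"), "unknown taxon")
})

test_that("the detection floor substitutes denominator zeros but never the numerator", {
  p <- profile_of(h13 = c(0.10, 0.00),
                  l13 = c(0.00, 0.02),
                  h12 = c(0.00, 0.00),
                  l12 = c(0.02, 0.02))
  r <- compute_ref(p, detection_floor = 1e-4)
  expect_equal(r$ref_value[1L], (0.10 / 1e-4) / (1e-4 / 0.02))
  expect_equal(r$ref_value[2L], 0.0)   # absent from both heavy pools
  r0 <- compute_ref(p)
  expect_true(all(is.na(r0$ref_value)))
})

test_that("swapping isotopes inverts REF for fully observed taxa", {
  ex <- simulate_experiment(sim_community(n_taxa = 40, n_labeled = 3,
                                          afe = 0.3, seed = 9),
                            gradient_config(depth_per_fraction = 20000,
                                            seed = 9))
  prof <- build_profiles_from_experiment(ex)
  swapped <- prof
  swapped$heavy_13C <- prof$heavy_12C
  swapped$light_13C <- prof$light_12C
  swapped$heavy_12C <- prof$heavy_13C
  swapped$light_12C <- prof$light_13C
  r <- compute_ref(prof)$ref_value
  rs <- compute_ref(swapped)$ref_value
  full <- rowSums(as.matrix(prof[, -1L]) > 0) == 4L
  expect_true(any(full))
  expect_equal(rs[full], 1 / r[full], tolerance = 1e-12)
})

test_that("activity needs strict REF and whole-community abundance thresholds", {
  p <- profile_of(h13 = c(0.020, 0.0052, 0.02, 0.03),
                  l13 = c(0.020, 0.0040, 0.01, 0.01),
                  h12 = c(0.010, 0.0010, 0.01, 0.01),
                  l12 = c(0.010, 0.0010, 0.01, 0.01),
                  ids = c("T_refEq1", "T_lowHeavy", "T_rare", "T_clear"))
  ra <- c(T_refEq1 = 0.02, T_lowHeavy = 0.0132, T_rare = 0.005, T_clear = 0.05)
  res <- ref_results(p, ra)
  expect_false(res$active[res$taxon_id == "T_refEq1"])   # REF exactly 1
  expect_false(res$active[res$taxon_id == "T_rare"])     # REF 2, RA 0.5%
  # heavy RA below 1% does not matter: the criterion is whole-community
  expect_true(res$active[res$taxon_id == "T_lowHeavy"])
  expect_true(res$active[res$taxon_id == "T_clear"])
  # deterministic order: descending REF (T_clear 3.0 > T_lowHeavy 1.3)
  expect_equal(call_active(res), c("T_clear", "T_lowHeavy"))
  expect_equal(res$taxon_id[1:2], c("T_clear", "T_rare"))
})

test_that("trophic classification falls back from exact match to neighbors to default", {
  ref <- tibble::tibble(
    lineage = c("Bacteria;Cyanobacteria;Oscillatoriales",
                "Bacteria;Actinobacteria;Geodermatophilales;Blastococcus;Blastococcus mobilis",
                "Bacteria;Proteobacteria;Burkholderiales;Massilia"),
    class = c("fixer", "fixer", "transformer")
  )
  expect_equal(
    classify_trophic("Bacteria;Cyanobacteria;Oscillatoriales", ref), "fixer")
  # nearest annotated lineage: an unlisted species under an annotated genus
  expect_equal(
    classify_trophic("Bacteria;Actinobacteria;Geodermatophilales;Blastococcus;Blastococcus mobilis",
                     ref), "fixer")
  expect_equal(
    classify_trophic("Bacteria;Proteobacteria;Burkholderiales;Massilia;Massilia agri",
                     ref), "transformer")
  # nothing annotated nearby: conservative default
  expect_equal(classify_trophic("Bacteria;Bacteroidetes;Cytophagales", ref),
               "transformer")
  expect_equal(classify_trophic("Bacteria;Bacteroidetes", ref,
                                default_class = "unknown"), "unknown")
  expect_equal(classify_trophic("Bacteria;Bacteroidetes", ref,
                                neighbor_rule = "none"), "transformer")
  expect_error(classify_trophic(";;", ref), "empty lineage")
})

test_that("relative biomass is RA x C and additive over group members", {
  expect_equal(relative_biomass(0, 10), 0)
  expect_equal(relative_biomass(0.10, 10), 1.0)
  expect_error(relative_biomass(-0.1, 10), "0, 1")
  expect_error(relative_biomass(0.1, -1), ">= 0")
  ra <- c(0.02, 0.013, 0.0071, 0.0152)
  C <- 34.3
  expect_equal(relative_biomass(sum(ra), C), sum(relative_biomass(ra, C)))
})

test_that("fixer summaries sum member contributions and deduplicate labeled taxa", {
  res <- tibble::tibble(
    taxon_id = c("a", "b", "c", "d"),
    active = c(TRUE, TRUE, TRUE, FALSE),
    trophic_class = c("fixer", "fixer", "transformer", "fixer"),
    community_ra = c(0.0128, 0.0106, 0.05, 0.9)
  )
  expect_equal(fixer_community_fraction(res), 100 * (0.0128 + 0.0106))
  # order independence
  expect_equal(fixer_community_fraction(res[c(3, 1, 4, 2), ]),
               fixer_community_fraction(res))
  expect_equal(fixer_community_fraction(res[res$active & FALSE, ]), 0)

  lab <- tibble::tibble(taxon_id = c("a", "b", "a", "c"),
                        trophic_class = c("fixer", "transformer", "fixer",
                                          "fixer"))
  expect_equal(fixer_share_of_labeled(lab), 100 * 2 / 3)
  expect_equal(fixer_share_of_labeled(
    tibble::tibble(taxon_id = "x", trophic_class = "fixer")), 100)
  expect_warning(out <- fixer_share_of_labeled(lab[0, ]), "no labeled")
  expect_true(is.na(out))
})

test_that("active counts deduplicate within the requested grouping", {
  res <- tibble::tibble(
    taxon_id = c("a", "b", "a", "c", "c"),
    active = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    phase = c("RP", "RP", "SHP", "SHP", "RP"),
    compartment = c("BSC", "US", "US", "US", "BSC")
  )
  expect_equal(count_active(res)$n_active, 3L)
  byp <- count_active(res, by = "phase")
  expect_equal(byp$n_active[byp$phase == "RP"], 2L)
  expect_equal(byp$n_active[byp$phase == "SHP"], 2L)
  expect_error(count_active(res, by = "planet"), "unknown grouping")
})
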