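# small deterministic fixtures used across test files

mini_community <- function(gc = c(0.45, 0.50, 0.68),
                           ab = c(0.5, 0.3, 0.2),
                           afe = c(0, 0, 0)) {
  tibble::tibble(
    taxon_id = sprintf("T%02d", seq_along(gc)),
    gc_content = gc,
    baseline_abundance = ab,
    atom_fraction_excess = afe,
    trophic_truth = ifelse(afe > 0, "fixer", "inert")
  )
}

# four-fraction paired metadata straddling the 1.7274 threshold
mini_meta <- function() {
  tibble::tibble(
    sample_id = c("12C_F01", "12C_F02", "13C_F01", "13C_F02"),
    isotope = rep(c("12C", "13C"), each = 2L),
    compartment = "BSC",
    phase = "RP",
    fraction_index = rep(1:2, 2L),
    buoyant_density = rep(c(1.7371, 1.7186), 2L),
    dna_quantity = c(1, 4, 2, 3)
  )
}

mini_counts <- function(m = NULL) {
  if (is.null(m)) {
    m <- rbind(A = c(10, 40, 30, 10),
               B = c(30, 40, 50, 60),
               C = c(60, 20, 20, 30))
  }
  colnames(m) <- c("12C_F01", "12C_F02", "13C_F01", "13C_F02")
  m
}

manual_ref <- function(h13, l13, h12, l12) (h13 / l13) / (h12 / l12)
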