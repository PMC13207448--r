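test_that("GC-to-density and labeling shifts follow the linear relations", {
  cfg <- gradient_config()
  expect_equal(unlabeled_bd(0, cfg), 1.660)
  expect_equal(unlabeled_bd(0.5, cfg), 1.709)
  expect_equal(unlabeled_bd(1, cfg), 1.758)
  expect_equal(labeled_bd(1.709, 0, cfg), 1.709)
  expect_equal(labeled_bd(1.709, 1, cfg), 1.745)
  expect_equal(labeled_bd(1.709, 0.5, cfg), 1.727)
  expect_error(unlabeled_bd(1.2, cfg), "0, 1")
  expect_error(labeled_bd(1.709, -0.1, cfg), "0, 1")
})

test_that("fraction bins tile the gradient densest-first", {
  cfg <- gradient_config()
  bins <- fraction_bins(cfg)
  expect_equal(nrow(bins), 12L)
  expect_equal(bins$bd_high[1L], cfg$bd_max)         # fraction 1 = densest
  expect_equal(bins$bd_low[12L], cfg$bd_min)
  expect_true(all(diff(bins$buoyant_density) < 0))
  expect_equal(bins$bd_low[-12L], bins$bd_high[-1L]) # contiguous
})

test_that("per-fraction masses match an independent quadrature oracle and conserve mass", {
  cfg <- gradient_config(seed = 42)
  comm <- sim_community(n_taxa = 50, n_labeled = 5, afe = 0.9, seed = 42)
  m <- taxon_fraction_masses(comm, cfg)

  bins <- fraction_bins(cfg)
  mu <- cfg$schildkraut_intercept + cfg$schildkraut_slope * comm$gc_content +
    cfg$shift_per_afe * comm$atom_fraction_excess
  oracle <- sapply(seq_len(nrow(bins)), function(f) {
    sapply(seq_len(nrow(comm)), function(t) {
      dens <- function(x) stats::dnorm(x, mu[t], cfg$density_sd)
      num <- stats::integrate(dens, bins$bd_low[f], bins$bd_high[f],
                              rel.tol = 1e-12)$value
      z <- stats::integrate(dens, cfg$bd_min, cfg$bd_max,
                            rel.tol = 1e-12)$value
      cfg$dna_total * comm$baseline_abundance[t] * num / z
    })
  })
  expect_lt(max(abs(m - oracle)), 1e-9)
  expect_lt(max(abs(rowSums(m) - cfg$dna_total * comm$baseline_abundance)),
            1e-9)
})

test_that("a band entirely outside the gradient names the offending taxon", {
  comm <- mini_community(gc = c(0.45, 1.0), ab = c(0.5, 0.5), afe = c(0, 1))
  cfg <- gradient_config(density_sd = 0.001)  # 1.794 g/mL sits far beyond bd_max
  expect_error(taxon_fraction_masses(comm, cfg), "T02")
})

test_that("sequencing counts close to the per-fraction depth and are reproducible", {
  cfg <- gradient_config(depth_per_fraction = 2000, seed = 11)
  comm <- mini_community()
  g1 <- simulate_gradient(comm, cfg, seed = 11)
  g2 <- simulate_gradient(comm, cfg, seed = 11)
  expect_identical(g1$counts, g2$counts)
  expect_identical(g1$meta, g2$meta)
  expect_true(all(colSums(g1$counts) %in% c(0L, 2000L)))
  # fractions holding essentially no DNA yield no reads
  expect_true(all(colSums(g1$counts)[g1$meta$dna_quantity < 1e-12] == 0L))
})

test_that("an unlabeled 50% GC taxon peaks in the bin containing 1.709 g/mL", {
  cfg <- gradient_config(depth_per_fraction = 1000, seed = 3)
  comm <- mini_community(gc = 0.5, ab = 1, afe = 0)
  g <- simulate_gradient(comm, cfg, seed = 3)
  peak <- which.max(g$meta$dna_quantity)
  bins <- fraction_bins(cfg)
  expect_true(bins$bd_low[peak] <= 1.709 && 1.709 < bins$bd_high[peak])
})

test_that("paired experiments force the control to zero labeling and record truth", {
  cfg <- gradient_config(depth_per_fraction = 5000, seed = 5)
  comm <- sim_community(n_taxa = 20, n_labeled = 3, afe = 0.9, seed = 5)
  ex <- simulate_experiment(comm, cfg)
  expect_setequal(ex$truth, comm$taxon_id[comm$atom_fraction_excess > 0])
  expect_length(ex$truth, 3L)
  expect_identical(ex$run_12C$meta$isotope, rep("12C", 12L))
  # control masses equal those of the fully unlabeled community
  unl <- comm
  unl$atom_fraction_excess <- 0
  expect_equal(ex$run_12C$masses, taxon_fraction_masses(unl, cfg))
  # rerun with the same config is byte-identical
  ex2 <- simulate_experiment(comm, cfg)
  expect_identical(ex$run_13C$counts, ex2$run_13C$counts)
  expect_identical(ex$community_counts, ex2$community_counts)
})

test_that("an unlabeled experiment has identical expected masses in both runs", {
  cfg <- gradient_config(depth_per_fraction = 2000, seed = 8)
  comm <- sim_community(n_taxa = 15, n_labeled = 0, seed = 8)
  ex <- simulate_experiment(comm, cfg)
  expect_equal(ex$run_12C$masses, ex$run_13C$masses)
})

test_that("a labeled taxon is enriched in the heavy pool of the 13C run", {
  comm <- sim_community(n_taxa = 20, n_labeled = 1, afe = 0.9, seed = 21)
  lab <- comm$taxon_id[comm$atom_fraction_excess > 0]
  wins <- 0L
  for (s in 1:20) {
    ex <- simulate_experiment(comm, gradient_config(depth_per_fraction = 5000,
                                                    seed = 600 + s))
    prof <- build_profiles_from_experiment(ex)
    i <- match(lab, prof$taxon_id)
    if (prof$heavy_13C[i] > prof$heavy_12C[i]) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})
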