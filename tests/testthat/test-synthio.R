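test_that("same config and seed give byte-identical populations", {
  cfg <- tiny_config(seed = 11)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$pa, p2$pa)
  expect_identical(p1$snp, p2$snp)
  expect_identical(p1$Q, p2$Q)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$layouts, p2$layouts)
  expect_identical(p1$homolog, p2$homolog)
})

test_that("a perfectly assorting planted cluster lands in every serpentine strain only", {
  cfg <- sim_config(planted_clusters = list(
    cluster_spec(13, 30000, assortment = 1, leak = 0)),
    core_size = 50, accessory_pool = 200, snp_sites = 20, seed = 3)
  pop <- simulate_population(cfg)
  expect_length(pop$truth$causal_gene_ids, 13)
  serp <- pop$strains$strain[pop$strains$soil == "serpentine"]
  nons <- pop$strains$strain[pop$strains$soil == "nonserpentine"]
  for (g in pop$truth$causal_gene_ids) {
    expect_true(all(pop$pa[serp, g] == 1L))
    expect_true(all(pop$pa[nons, g] == 0L))
  }
})

test_that("configs with more planted genes than the accessory pool are rejected", {
  expect_error(
    sim_config(accessory_pool = 10,
               planted_clusters = list(cluster_spec(11, 2000))),
    "exceed")
})

test_that("Beta(0.3, 0.3) accessory spectrum is U-shaped", {
  # Closed form for the generating Beta: mass below .1 plus above .9 is
  # ~0.54, versus ~0.062 in [.4, .6]; realized per-gene carrier frequencies
  # must echo that ordering.
  extreme_mass <- pbeta(0.1, 0.3, 0.3) + 1 - pbeta(0.9, 0.3, 0.3)
  middle_mass <- pbeta(0.6, 0.3, 0.3) - pbeta(0.4, 0.3, 0.3)
  expect_gt(extreme_mass, 4 * middle_mass)

  cfg <- sim_config(accessory_pool = 2000, core_size = 10, snp_sites = 10,
                    freq_spectrum_shape = c(0.3, 0.3),
                    subgroup_divergence = 0, seed = 5)
  pop <- simulate_population(cfg)
  part <- partition_core_accessory(pop$pa)
  freq <- colMeans(pop$pa[, part$accessory, drop = FALSE])
  frac_extreme <- mean(freq < 0.1 | freq > 0.9)
  frac_middle <- mean(freq >= 0.4 & freq <= 0.6)
  expect_gt(frac_extreme, frac_middle + 0.1)
})

test_that("null phenotypes are i.i.d. Gaussian around baseline", {
  cfg <- sim_config(phenotype_effect = 0, structure_effect = 0,
                    core_size = 20, accessory_pool = 50, snp_sites = 10,
                    phenotype_sd = 0.05, seed = 7)
  pop <- simulate_population(cfg)
  hi <- pop$phenotypes$growth_highNi
  expect_equal(mean(hi), cfg$baseline_od, tolerance = 0.05)
  expect_equal(sd(hi), 0.05, tolerance = 0.5)
  expect_gt(shapiro.test(hi)$p.value, 0.001)
})

test_that("vanishing noise makes high-nickel growth exactly bimodal by carrier status", {
  cfg <- sim_config(planted_clusters = list(cluster_spec(4, 2000)),
                    phenotype_effect = 0.28, phenotype_sd = 1e-9,
                    structure_effect = 0, core_size = 20,
                    accessory_pool = 50, snp_sites = 10, seed = 2)
  pop <- simulate_population(cfg)
  carriers <- pop$strains$strain %in% pop$truth$cluster_carriers[[1]]
  hi <- pop$phenotypes$growth_highNi
  expect_equal(unname(diff(range(hi[carriers]))), 0, tolerance = 1e-6)
  expect_equal(mean(hi[carriers]) - mean(hi[!carriers]), 0.28,
               tolerance = 1e-6)
  # low-nickel growth carries no causal term
  lo <- pop$phenotypes$growth_lowNi
  expect_lt(abs(mean(lo[carriers]) - mean(lo[!carriers])), 1e-6)
})

test_that("genomes collapse to one contig when contigs hold all genes", {
  cfg <- tiny_config(seed = 4, contig_mean_genes = 10000)
  pop <- simulate_population(cfg)
  n_ctg <- tapply(pop$layouts$contig, pop$layouts$strain,
                  function(x) length(unique(x)))
  expect_true(all(n_ctg == 1L))
})

test_that("planted cluster genes sit inside their span on one contig per carrier", {
  cfg <- power_config(seed = 6)
  pop <- simulate_population(cfg)
  cc <- pop$truth$planted_cluster_coords
  expect_equal(nrow(cc), length(pop$truth$cluster_carriers[[1]]))
  expect_true(all(cc$end - cc$start + 1 <= 30000))
  lay <- pop$layouts
  genes <- pop$truth$cluster_genes[[1]]
  for (i in seq_len(nrow(cc))) {
    g <- lay[lay$strain == cc$strain[i] & lay$group_id %in% genes, ]
    expect_equal(length(unique(g$contig)), 1L)
    expect_equal(nrow(g), 13L)
  }
})

test_that("layouts are sorted with non-overlapping genes", {
  pop <- simulate_population(tiny_config(seed = 9))
  lay <- pop$layouts
  for (key in unique(paste(lay$strain, lay$contig))) {
    g <- lay[paste(lay$strain, lay$contig) == key, ]
    expect_false(is.unsorted(g$start))
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("a cluster span too small for its genes is rejected", {
  expect_error(cluster_spec(5, 400), "at least 100")
  cfg <- sim_config(planted_clusters = list(cluster_spec(5, 500)),
                    core_size = 20, accessory_pool = 50, snp_sites = 10,
                    seed = 1)
  expect_error(simulate_population(cfg), "span too small")
})

test_that("homolog distances shift only the candidate genes", {
  cfg <- sim_config(core_size = 20, accessory_pool = 1000, snp_sites = 10,
                    homolog_shift = 0, subgroup_divergence = 0, seed = 8)
  pop <- simulate_population(cfg)
  acc <- colnames(pop$pa)[colSums(pop$pa) < nrow(pop$pa)]
  cand <- sample(acc, 100)
  h0 <- simulate_homolog_distances(pop$pa, cand, cfg)
  d0 <- mean(h0$distance_16S[h0$candidate_flag]) -
    mean(h0$distance_16S[!h0$candidate_flag])
  expect_lt(abs(d0), 0.01)

  cfg$homolog_shift <- 0.033
  h1 <- simulate_homolog_distances(pop$pa, cand, cfg)
  d1 <- mean(h1$distance_16S[h1$candidate_flag]) -
    mean(h1$distance_16S[!h1$candidate_flag])
  expect_equal(d1, 0.033, tolerance = 0.25)
  expect_error(simulate_homolog_distances(pop$pa, acc, cfg),
               "reference distribution")
})

test_that("dropout of zero never misclassifies; dropout of one is degenerate", {
  pop <- simulate_population(tiny_config(seed = 10))
  r0 <- simulate_accessory_identification(pop$pa, 0, n_reps = 3, seed = 1)
  expect_equal(r0$core_misclass_rate, 0)
  expect_equal(r0$mean_freq_distortion, 0)
  expect_error(
    simulate_accessory_identification(pop$pa, 1, n_reps = 1, seed = 1),
    "empty pan-genome")
})

test_that("Q rows sum to one and differentiation grows with the divergence parameter", {
  spread <- vapply(c(0.02, 0.1, 0.3, 0.6), function(f) {
    cfg <- sim_config(core_size = 10, accessory_pool = 800, snp_sites = 10,
                      subgroup_divergence = f, seed = 21)
    pop <- simulate_population(cfg)
    expect_equal(unname(rowSums(pop$Q)), rep(1, nrow(pop$Q)),
                 tolerance = 1e-9)
    set.seed(99)
    p <- runif(2000, 0.05, 0.95)
    mean(abs(serpan:::.balding_nichols(p, f) -
               serpan:::.balding_nichols(p, f)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("presence frequencies track the configured spectrum within binomial bounds", {
  cfg <- sim_config(core_size = 10, accessory_pool = 1500, snp_sites = 10,
                    subgroup_divergence = 0, seed = 31)
  pop <- simulate_population(cfg)
  part <- partition_core_accessory(pop$pa)
  freq <- colMeans(pop$pa[, part$accessory, drop = FALSE])
  # overall mean carrier frequency among surviving (not all-zero, not fixed)
  # genes: compare with the same functional of the generating Beta
  set.seed(42)
  sim_p <- rbeta(2e5, 0.3, 0.3)
  occ <- rbinom(2e5, 38, sim_p)
  keep <- occ > 0 & occ < 38
  expect_equal(mean(freq), mean(occ[keep] / 38), tolerance = 0.05)
})
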