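test_that("structure regression reduces to centering when loadings are uninformative", {
  y <- c(1, 2, 3, 4)
  Q <- matrix(0.5, 4, 2)
  r <- suppressWarnings(regress_out_structure(y, Q))
  expect_equal(unname(r), y - mean(y))
  expect_equal(sum(r), 0, tolerance = 1e-12)
})

test_that("a phenotype exactly linear in loadings leaves zero residuals", {
  set.seed(3)
  Q1 <- runif(10, 0, 1)
  Q <- cbind(Q1, 1 - Q1)
  y <- 2 + 3 * Q1
  r <- regress_out_structure(y, Q)
  expect_equal(unname(r), rep(0, 10), tolerance = 1e-10)
})

test_that("rank-sum statistic and exact p match the textbook cases", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3)
  expect_true(r$exact)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$W, 7)
  expect_equal(wilcoxon_rank_sum(c(5, 5), c(5, 5))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("exact Wilcoxon p equals enumeration over labelings for small groups", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    n1 <- sample(seq_len(n - 1), 1)
    vals <- sample(100, n)  # distinct -> exact path
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcox_exact_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("p-value adjustment reproduces closed forms and stays monotone", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.05, 1.0), "bh"), c(0.10, 1.0))
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- adjust_pvalues(p, "bh")
    expect_equal(q, oracle_bh(p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm], "bh"), q[perm])
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    # q-value never exceeds BH and respects pi0 scaling
    expect_true(all(adjust_pvalues(p, "qvalue") <= q + 1e-12))
  }
})

test_that("gene scan skips fixed and singleton variants with reason codes", {
  set.seed(2)
  res <- rnorm(8)
  m <- cbind(fixed = rep(1L, 8), single = c(1L, rep(0L, 7)),
             ok = rep(c(0L, 1L), 4))
  sc <- gene_content_association(m, res)
  expect_identical(sc$results$variant_id, "ok")
  expect_setequal(sc$skipped$reason, c("fixed", "singleton"))
  expect_equal(sc$skipped$reason[sc$skipped$variant_id == "single"],
               "singleton")
})

test_that("SNP scan rejects non-biallelic codings", {
  set.seed(4)
  res <- rnorm(6)
  m <- cbind(tri = c(0L, 1L, 2L, 0L, 1L, 2L), ok = rep(c(0L, 1L), 3),
             single = c(1L, rep(0L, 5)))
  sc <- snp_association(m, res)
  expect_identical(sc$results$variant_id, "ok")
  expect_equal(sc$skipped$reason[sc$skipped$variant_id == "tri"],
               "not_biallelic")
  expect_equal(sc$skipped$reason[sc$skipped$variant_id == "single"],
               "singleton")
})

test_that("effects and per-soil frequencies follow their definitions", {
  ef <- effect_and_frequencies(c(TRUE, TRUE, FALSE, FALSE),
                               c(0.3, 0.3, 0.1, 0.1),
                               c("serpentine", "serpentine",
                                 "nonserpentine", "nonserpentine"))
  expect_equal(ef$effect, 0.2)
  expect_equal(ef$freq_S, 1)
  expect_equal(ef$freq_N, 0)
  expect_error(effect_and_frequencies(rep(TRUE, 4), 1:4, rep("serpentine", 4)),
               "fixed")
})

test_that("association p-values are shift-invariant and effects scale-equivariant", {
  pop <- simulate_population(power_config(seed = 41))
  ph <- pop$phenotypes
  part <- partition_core_accessory(pop$pa)
  acc <- pop$pa[, part$accessory, drop = FALSE]
  r1 <- regress_out_structure(ph$growth_highNi, pop$Q)
  r2 <- regress_out_structure(ph$growth_highNi + 5, pop$Q)
  s1 <- gene_content_association(acc, r1)
  s2 <- gene_content_association(acc, r2)
  expect_equal(s1$results$p, s2$results$p, tolerance = 1e-12)
  a1 <- annotate_association(s1, acc, ph$growth_highNi, ph$soil)
  a2 <- annotate_association(s1, acc, 2 * ph$growth_highNi, ph$soil)
  expect_equal(a2$effect, 2 * a1$effect, tolerance = 1e-12)
})

test_that("a planted perfectly assorting cluster reaches Bonferroni significance", {
  pop <- simulate_population(power_config(seed = 43))
  ph <- pop$phenotypes
  res <- regress_out_structure(ph$growth_highNi, pop$Q)
  part <- partition_core_accessory(pop$pa)
  acc <- pop$pa[, part$accessory, drop = FALSE]
  ann <- annotate_association(gene_content_association(acc, res), acc,
                              ph$growth_highNi, ph$soil)
  sets <- significant_set(ann, 0.10)
  planted <- pop$truth$cluster_genes[[1]]
  expect_true(all(planted %in% sets$bonferroni))
  # the planted genes assort perfectly in the Table-1 sense
  pl <- ann[ann$variant_id %in% planted, ]
  expect_true(all(pl$freq_S == 1 & pl$freq_N == 0))
})

test_that("the low-nickel phenotype yields no candidates even at a lenient FDR in most replicates", {
  # Under the global null, BH rejects anything with probability <= alpha,
  # so the empty-set rate at 20% FDR is >= 0.80; assert that bound minus
  # Monte-Carlo noise (2.5 binomial sd at 30 replicates ~ 0.18).
  empty <- vapply(1:30, function(r) {
    pop <- simulate_population(power_config(seed = 8100 + r))
    ph <- pop$phenotypes
    res_lo <- regress_out_structure(ph$growth_lowNi, pop$Q)
    part <- partition_core_accessory(pop$pa)
    acc <- pop$pa[, part$accessory, drop = FALSE]
    ann_lo <- annotate_association(gene_content_association(acc, res_lo),
                                   acc, ph$growth_lowNi, ph$soil)
    significant_set(ann_lo, 0.20)$n_fdr == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.7)
})

test_that("candidate sets and FDR tiers are consistent with q-values", {
  expect_equal(significant_set(NULL)$n_fdr, 0L)
  df <- data.frame(variant_id = c("a", "b", "c"), q = c(0.005, 0.04, 0.2),
                   bonferroni_sig = c(TRUE, FALSE, FALSE))
  s <- significant_set(df, 0.10)
  expect_setequal(s$fdr, c("a", "b"))
  expect_identical(s$bonferroni, "a")
  expect_equal(fdr_tiers(df), c(1, 5, Inf))
  allq1 <- data.frame(variant_id = "x", q = 1, bonferroni_sig = FALSE)
  expect_equal(significant_set(allq1, 0.10)$n_fdr, 0L)
})
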