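mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               percent_identity = as.numeric(r[[3]]),
               alignment_length = as.numeric(r[[4]]),
               query_length = as.numeric(r[[5]]),
               evalue = as.numeric(r[[6]]), bitscore = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("hit filtering applies strict thresholds on overlap, E-value and identity", {
  h <- mk_hits(
    list("q1", "s1", 60, 85, 100, 1e-25, 200),   # passes all
    list("q2", "s2", 60, 80, 100, 1e-25, 200),   # overlap exactly 0.80
    list("q3", "s3", 60, 85, 100, 1e-20, 200),   # evalue exactly at bound
    list("q4", "s4", 50, 85, 100, 1e-25, 200),   # identity exactly 50
    list("q5", "s5", 51, 81, 100, 1e-21, 200))   # just inside all three
  out <- filter_hits(h)
  expect_identical(out$query_id, c("q1", "q5"))
  # idempotent
  expect_identical(filter_hits(out), out)
  # empty in, empty out
  expect_equal(nrow(filter_hits(h[0, ])), 0L)
})

test_that("missing query_length is reported with the record index", {
  h <- mk_hits(list("q1", "s1", 60, 85, 100, 1e-25, 200))
  h$query_length[1] <- NA
  expect_error(filter_hits(h), "record\\(s\\): 1")
})

test_that("reciprocal best hits require mutual best status", {
  ab <- mk_hits(list("a1", "b1", 90, 95, 100, 1e-40, 500),
                list("a1", "b2", 90, 95, 100, 1e-30, 300),
                list("a2", "b2", 90, 95, 100, 1e-40, 450))
  ba <- mk_hits(list("b1", "a1", 90, 95, 100, 1e-40, 500),
                list("b2", "a1", 90, 95, 100, 1e-40, 480))
  r <- reciprocal_best_hits(ab, ba)
  # a1<->b1 mutual; a2->b2 best but b2's best is a1, so no pair
  expect_identical(r$gene_a, "a1")
  expect_identical(r$gene_b, "b1")
})

test_that("equal-score best hits break ties lexicographically and are flagged", {
  ab <- mk_hits(list("a1", "b2", 90, 95, 100, 1e-40, 500),
                list("a1", "b1", 90, 95, 100, 1e-40, 500))
  ba <- mk_hits(list("b1", "a1", 90, 95, 100, 1e-40, 500))
  r <- reciprocal_best_hits(ab, ba)
  expect_identical(r$gene_b, "b1")  # lexicographic winner
  expect_true(r$ambiguous)
})

test_that("single-linkage closure groups chained RBH pairs", {
  gs <- setNames(c("s1", "s2", "s3"), c("a", "b", "c"))
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  grp <- build_ortholog_groups(pairs, NULL, gs)
  expect_equal(length(unique(grp$group_id)), 1L)
  # no edges -> singletons
  grp2 <- build_ortholog_groups(pairs[0, ], NULL, gs)
  expect_equal(length(unique(grp2$group_id)), 3L)
})

test_that("ortholog grouping is invariant to strain input order", {
  cfg <- tiny_config(seed = 17)
  pop <- simulate_population(cfg)
  ht <- simulate_hit_tables(pop)
  rbh <- rbh_from_pairwise(ht$pairwise)
  g1 <- suppressMessages(
    build_ortholog_groups(rbh, filter_hits(ht$reference_hits),
                          ht$gene_strains))
  perm <- sample(nrow(rbh))
  g2 <- suppressMessages(
    build_ortholog_groups(rbh[perm, ], filter_hits(ht$reference_hits),
                          rev(ht$gene_strains)))
  m1 <- split(g1$gene_id, g1$group_id)
  m2 <- split(g2$gene_id, g2$group_id)
  expect_setequal(unname(lapply(m1, sort)), unname(lapply(m2, sort)))
})

test_that("core/accessory partition matches the subset definitions", {
  pa <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 1L, 0L),
              c = c(1L, 1L, 1L, 0L))
  colnames(pa) <- paste0("g", 1:4)
  part <- partition_core_accessory(pa, c("a", "b", "c"))
  expect_identical(part$core, "g1")
  expect_setequal(part$accessory, c("g2", "g3"))
  expect_identical(part$absent, "g4")
  # disjoint cover of all columns
  expect_setequal(c(part$core, part$accessory, part$absent), colnames(pa))
  # subset of one strain: every present gene is core
  p1 <- partition_core_accessory(pa, "a")
  expect_setequal(p1$core, c("g1", "g2"))
  expect_length(p1$accessory, 0)
  expect_error(partition_core_accessory(pa, character(0)), "empty")
})

test_that("pan and core counts are monotone along nested strain chains", {
  pa <- rbind(a = c(1L, 1L, 0L), b = c(0L, 1L, 1L))
  colnames(pa) <- paste0("g", 1:3)
  ct <- pan_core_counts(pa, list(ab = c("a", "b"), a = "a"))
  expect_equal(ct$pan, c(3L, 2L))
  expect_equal(ct$core, c(1L, 2L))

  pop <- simulate_population(tiny_config(seed = 23))
  strains <- rownames(pop$pa)
  for (rep in 1:3) {
    set.seed(rep)
    chain <- lapply(seq(2, length(strains), by = 2),
                    function(k) sample(strains)[seq_len(k)])
    chain <- lapply(seq_along(chain), function(i) {
      Reduce(union, chain[seq_len(i)])
    })
    names(chain) <- paste0("s", seq_along(chain))
    ct <- pan_core_counts(pop$pa, chain)
    expect_true(all(diff(ct$pan) >= 0))
    expect_true(all(diff(ct$core) <= 0))
  }
})

test_that("gene frequency spectrum counts occupancy classes", {
  expect_equal(unname(gene_frequency_spectrum(diag(2L))), c(2L, 0L))
  m <- matrix(1L, 3, 4)
  expect_equal(unname(gene_frequency_spectrum(m)), c(0L, 0L, 4L))
})

test_that("SNP calling keeps variable clean columns and skips gapped ones", {
  aln <- c(s1 = "AATAC", s2 = "AATAC", s3 = "AGT-C", s4 = "GGTAA")
  sites <- call_snps_from_alignment(aln)
  # col1 A/A/A/G biallelic; col2 A/G/G/G biallelic; col3 invariant;
  # col4 has a gap -> skipped; col5 C/C/C/A biallelic
  expect_equal(sites$alignment_column, c(1L, 2L, 5L))
  expect_true(all(sites$biallelic))
  expect_equal(attr(sites, "n_skipped"), 1L)

  aln3 <- c(s1 = "A", s2 = "C", s3 = "G", s4 = "G")
  s3 <- call_snps_from_alignment(aln3)
  expect_equal(s3$n_alleles, 3L)
  expect_false(s3$biallelic)

  expect_error(call_snps_from_alignment(c(s1 = "AAA", s2 = "AA")),
               "unequal")
  expect_error(call_snps_from_alignment(aln, strain_subset = c("s1", "zz")),
               "missing")
})

test_that("simulated core alignments round-trip through the SNP caller", {
  pop <- simulate_population(tiny_config(seed = 29))
  alns <- simulate_core_alignments(pop)
  g <- names(alns)[1]
  sites <- call_snps_from_alignment(alns[[g]], gene_id = g)
  truth_cols <- which(sub(":.*", "", colnames(pop$snp)) == g)
  truth_pos <- sort(as.integer(sub(".*:", "", colnames(pop$snp)[truth_cols])))
  # sites that are truly polymorphic in this sample (a drawn site can be
  # monomorphic by chance)
  poly <- vapply(truth_cols, function(k) length(unique(pop$snp[, k])) > 1,
                 logical(1))
  expect_setequal(sites$alignment_column,
                  unique(sort(as.integer(
                    sub(".*:", "", colnames(pop$snp)[truth_cols][poly])))))
  gm <- snp_genotype_matrix(sites)
  # recovered genotypes equal the simulated ones up to 0/1 relabeling
  for (j in seq_len(ncol(gm))) {
    pos <- as.integer(sub(".*:", "", colnames(gm)[j]))
    k <- truth_cols[as.integer(sub(".*:", "", colnames(pop$snp)[truth_cols]))
                    == pos][1]
    a <- gm[rownames(pop$snp), j]
    b <- pop$snp[, k]
    expect_true(all(a == b) || all(a == 1L - b))
  }
})

test_that("reconstruction from dropout-free hit tables equals the truth matrix", {
  pop <- simulate_population(tiny_config(seed = 37))
  ht <- simulate_hit_tables(pop)
  rbh <- rbh_from_pairwise(ht$pairwise)
  grp <- suppressMessages(
    build_ortholog_groups(rbh, filter_hits(ht$reference_hits),
                          ht$gene_strains))
  pa2 <- presence_absence_matrix(grp, strains = rownames(pop$pa))
  recon <- split(grp$gene_id, grp$group_id)
  cn <- vapply(colnames(pa2),
               function(g) unique(ht$truth_groups[recon[[g]]])[1], "")
  expect_false(anyDuplicated(cn) > 0)
  pa2 <- pa2[, order(match(cn, colnames(pop$pa)))]
  expect_identical(unname(pa2), unname(pop$pa))
})
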