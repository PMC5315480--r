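mk_map <- function(starts, len = 500, strain = "s1", contig = "c1",
                   ids = paste0("g", seq_along(starts))) {
  data.frame(strain = strain, contig = contig, group_id = ids,
             start = as.integer(starts), end = as.integer(starts + len - 1),
             strand = "+", stringsAsFactors = FALSE)
}

mirror_map <- function(map) {
  L <- max(map$end) + 997L
  out <- map
  out$start <- L - map$end + 1L
  out$end <- L - map$start + 1L
  out[order(out$contig, out$start), ]
}

test_that("four tandem candidates seed a cluster, three do not", {
  m4 <- mk_map(seq(1, by = 1000, length.out = 6))
  cl <- call_clusters(m4, paste0("g", 2:5))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_candidates, 4L)
  expect_setequal(cl$members[[1]], paste0("g", 2:5))

  cl3 <- call_clusters(m4, paste0("g", 2:4))
  expect_equal(nrow(cl3), 0L)
})

test_that("extension absorbs candidates within 10 kb of the edge and stops beyond", {
  # seed g1..g4 at 1..4000 (500 bp genes, 1 kb apart); g5 non-candidate
  # breaks the seed run; g6 candidate starting 9,900 bp past the seed edge
  # (end of g4 = 3,500); g7 non-candidate; g8 candidate 10,500 bp past the
  # new edge (end of g6 = 13,899).
  starts <- c(1, 1001, 2001, 3001, 6001, 3500 + 9900, 15001,
              13899 + 10501)
  m <- mk_map(starts)
  cand <- paste0("g", c(1:4, 6, 8))
  cl <- call_clusters(m, cand)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$members[[1]], paste0("g", c(1:4, 6)))
  expect_false("g8" %in% cl$members[[1]])
  # span includes the intervening non-candidate g5
  expect_equal(cl$start, 1L)
  expect_equal(cl$end, m$end[m$group_id == "g6"])
})

test_that("cluster calling is invariant under contig mirroring", {
  set.seed(6)
  starts <- cumsum(sample(500:2000, 30, replace = TRUE))
  m <- mk_map(starts)
  cand <- sample(m$group_id, 14)
  cl <- call_clusters(m, cand)
  clm <- call_clusters(mirror_map(m), cand)
  expect_equal(nrow(cl), nrow(clm))
  expect_setequal(lapply(cl$members, sort), lapply(clm$members, sort))
  expect_setequal(cl$span_bp, clm$span_bp)
})

test_that("removing a candidate farther than the gap never changes a cluster", {
  # g5 non-candidate breaks the run; far candidate g6 is never a member
  starts <- c(1, 1001, 2001, 3001, 5001, 40000)
  m <- mk_map(starts)
  cand <- paste0("g", c(1:4, 6))
  cl_with <- call_clusters(m, cand)
  cl_without <- call_clusters(m[-6, ], setdiff(cand, "g6"))
  expect_equal(cl_with$members, cl_without$members)
  expect_equal(cl_with$span_bp, cl_without$span_bp)
})

test_that("clusters brought into contact by extension merge", {
  # two 4-runs separated by 8 kb: extension pulls them together
  starts <- c(seq(1, by = 1000, length.out = 4),
              seq(3500 + 8000, by = 1000, length.out = 4))
  m <- mk_map(starts)
  cl <- call_clusters(m, m$group_id)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_candidates, 8L)
})

test_that("unsorted or overlapping maps are rejected", {
  m <- mk_map(c(1, 1001, 2001, 3001))
  expect_error(call_clusters(m[c(2, 1, 3, 4), ], m$group_id), "not sorted")
  m2 <- m
  m2$end[1] <- 1200  # overlaps gene 2
  expect_error(call_clusters(m2, m$group_id), "overlap")
})

test_that("soil assortment flags perfect and serpentine-only patterns", {
  strains <- c(paste0("S", 1:4), paste0("N", 1:4))
  soil <- rep(c("serpentine", "nonserpentine"), each = 4)
  a <- soil_assortment(paste0("S", 1:4), strains, soil)
  expect_true(a$perfect)
  expect_true(a$serpentine_only)
  b <- soil_assortment(paste0("S", 1:2), strains, soil)
  expect_false(b$perfect)
  expect_true(b$serpentine_only)
  c3 <- soil_assortment(c("S1", "N1"), strains, soil)
  expect_false(c3$perfect)
  expect_false(c3$serpentine_only)
})

test_that("identical clusters across strains form one fully conserved family", {
  m1 <- mk_map(seq(1, by = 1000, length.out = 5), strain = "s1")
  m2 <- mk_map(seq(1, by = 1000, length.out = 5), strain = "s2",
               contig = "c9")
  cl <- call_clusters(rbind(m1, m2), paste0("g", 1:5))
  fam <- match_clusters_across_strains(cl)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$n_clusters, 2L)
  expect_equal(fam$order_conservation, 1)

  # disjoint membership -> separate families
  m3 <- mk_map(seq(1, by = 1000, length.out = 4), strain = "s3",
               ids = paste0("h", 1:4))
  cl2 <- call_clusters(rbind(m1, m3), c(paste0("g", 1:5), paste0("h", 1:4)))
  fam2 <- match_clusters_across_strains(cl2)
  expect_equal(nrow(fam2), 2L)
})

test_that("a planted cluster survives per-strain shuffling of the gene backbone", {
  cfg <- power_config(seed = 51)
  pop <- simulate_population(cfg)
  lay <- fragment_genomes(pop$pa, cfg,
                          cluster_genes = pop$truth$cluster_genes,
                          shuffle = TRUE)
  planted <- pop$truth$cluster_genes[[1]]
  cl <- call_clusters(lay, planted)
  fam <- match_clusters_across_strains(cl)
  expect_equal(nrow(fam), 1L)
  expect_setequal(fam$members[[1]], planted)  # membership recall 1.0
  expect_equal(fam$n_clusters, length(pop$truth$cluster_carriers[[1]]))
})

test_that("family summaries report the planted 13-gene cluster geometry", {
  pop <- simulate_population(power_config(seed = 53))
  ph <- pop$phenotypes
  res <- regress_out_structure(ph$growth_highNi, pop$Q)
  part <- partition_core_accessory(pop$pa)
  acc <- pop$pa[, part$accessory, drop = FALSE]
  ann <- annotate_association(gene_content_association(acc, res), acc,
                              ph$growth_highNi, ph$soil)
  cand <- significant_set(ann, 0.10)$fdr
  cl <- call_clusters(pop$layouts, cand)
  fam <- match_clusters_across_strains(cl)
  summ <- cluster_summary(fam, ann, ph$strain, ph$soil)
  big <- summ[which.max(summ$n_candidates), ]
  expect_gte(big$n_candidates, 13)
  expect_gte(big$n_perfect_assort, 13)
  expect_lte(big$max_span_bp, 30000)
  expect_true(big$perfect)

  empty <- cluster_summary(match_clusters_across_strains(cl[0, ]),
                           ann, ph$strain, ph$soil)
  expect_equal(nrow(empty), 0L)
})
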