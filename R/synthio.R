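#' Specify a planted candidate-gene cluster
#'
#' A planted cluster is a block of accessory genes that co-occur perfectly
#' within carrier strains and sit within a bounded window on a single contig,
#' mimicking a horizontally acquired genomic island.
#'
#' @param n_genes Number of genes in the cluster (>= 1).
#' @param span_bp Maximum genomic span of the cluster in a carrier genome, in
#'   bp. Must be at least `100 * n_genes`.
#' @param assortment Fraction of serpentine-origin strains that carry the
#'   cluster (1 = found in every serpentine strain).
#' @param leak Fraction of non-serpentine strains that carry the cluster
#'   (0 = never found outside serpentine).
#' @param causal Whether carrying the cluster raises growth in high-nickel
#'   medium by `phenotype_effect` OD600 units.
#' @return A `serpan_cluster_spec` list.
#' @export
cluster_spec <- function(n_genes, span_bp, assortment = 1, leak = 0,
                         causal = TRUE) {
  .assert_count(n_genes, "n_genes")
  .assert_count(span_bp, "span_bp")
  .assert_prob(assortment, "assortment")
  .assert_prob(leak, "leak")
  if (span_bp < n_genes * 100) {
    stop("`span_bp` must be at least 100 bp per gene", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), span_bp = as.integer(span_bp),
                 assortment = assortment, leak = leak, causal = isTRUE(causal)),
            class = "serpan_cluster_spec")
}

#' Configuration for the synthetic population generator
#'
#' Defaults describe a two-habitat rhizobial strain collection: 38 focal
#' strains split evenly between serpentine (high-nickel) and non-serpentine
#' soils across three reserves, a U-shaped accessory-gene frequency spectrum
#' (Beta(0.3, 0.3)), two admixture subgroups, a growth effect of 0.28 OD600
#' per causal cluster over residual noise of 0.05, and a 0.033 upward shift
#' in nearest-homolog 16S distance for candidate genes.  Pool sizes are kept
#' at desk scale (see the methods vignette).
#'
#' @param n_serpentine,n_nonserpentine Strains per soil type.
#' @param n_reserves Number of collection reserves (strains are spread
#'   round-robin within each soil type).
#' @param core_size Number of core ortholog groups (present in every strain).
#' @param accessory_pool Number of accessory ortholog groups in the gene pool.
#' @param freq_spectrum_shape Two Beta shape parameters for accessory gene
#'   frequencies; equal shapes < 1 give the rare-or-ubiquitous U shape.
#' @param n_subgroups Number of admixture subpopulations.
#' @param admixture_alpha Symmetric Dirichlet concentration for per-strain
#'   subgroup loadings; small values give near-discrete assignment.
#' @param subgroup_divergence Balding-Nichols F governing how strongly
#'   accessory-gene and SNP frequencies differ between subgroups.
#' @param planted_clusters List of [cluster_spec()] objects.
#' @param phenotype_effect OD600 increment in high-nickel medium per causal
#'   cluster carried.
#' @param phenotype_sd Residual OD600 standard deviation (> 0).
#' @param structure_effect OD600 increment per unit loading on subgroup 1,
#'   applied in both media (the confounding term).
#' @param baseline_od Baseline OD600 common to all strains.
#' @param snp_sites Number of biallelic core-genome SNP sites.
#' @param contig_mean_genes Mean number of genes per contig when fragmenting
#'   simulated genomes.
#' @param intergenic_bp Mean intergenic spacing, bp.
#' @param gene_mean_bp Mean simulated gene length, bp.
#' @param homolog_shift Additive shift in nearest-homolog 16S distance for
#'   candidate genes (the planted horizontal-transfer signal).
#' @param homolog_base_shape Beta shape parameters of the baseline
#'   nearest-homolog 16S distance distribution.
#' @param dropout_rate Probability that a truly present gene is missed in a
#'   draft genome (0 = perfect gene calling).
#' @param seed Master integer seed; stage-specific streams are derived from
#'   it by fixed offsets.
#' @return A validated `serpan_sim_config` list.
#' @seealso [simulate_population()], [default_scenario()]
#' @export
sim_config <- function(n_serpentine = 19, n_nonserpentine = 19, n_reserves = 3,
                       core_size = 500, accessory_pool = 2000,
                       freq_spectrum_shape = c(0.3, 0.3),
                       n_subgroups = 2, admixture_alpha = 0.2,
                       subgroup_divergence = 0.1,
                       planted_clusters = list(),
                       phenotype_effect = 0.28, phenotype_sd = 0.05,
                       structure_effect = 0.1, baseline_od = 0.5,
                       snp_sites = 1000, contig_mean_genes = 30,
                       intergenic_bp = 150, gene_mean_bp = 900,
                       homolog_shift = 0.033, homolog_base_shape = c(2, 38),
                       dropout_rate = 0, seed = 1) {
  .assert_count(n_serpentine, "n_serpentine")
  .assert_count(n_nonserpentine, "n_nonserpentine")
  .assert_count(n_reserves, "n_reserves")
  .assert_count(core_size, "core_size")
  .assert_count(accessory_pool, "accessory_pool")
  .assert_count(n_subgroups, "n_subgroups")
  .assert_count(snp_sites, "snp_sites")
  .assert_count(contig_mean_genes, "contig_mean_genes")
  .assert_count(intergenic_bp, "intergenic_bp")
  .assert_count(gene_mean_bp, "gene_mean_bp", min = 100L)
  stopifnot(length(freq_spectrum_shape) == 2, all(freq_spectrum_shape > 0),
            length(homolog_base_shape) == 2, all(homolog_base_shape > 0),
            admixture_alpha > 0, phenotype_sd > 0, structure_effect >= 0,
            phenotype_effect >= 0, baseline_od >= 0, homolog_shift >= 0)
  .assert_prob(subgroup_divergence, "subgroup_divergence")
  .assert_prob(dropout_rate, "dropout_rate")
  if (!is.list(planted_clusters) ||
      !all(vapply(planted_clusters, inherits, logical(1), "serpan_cluster_spec"))) {
    stop("`planted_clusters` must be a list of cluster_spec() objects",
         call. = FALSE)
  }
  n_planted <- sum(vapply(planted_clusters, `[[`, integer(1), "n_genes"))
  if (n_planted > accessory_pool) {
    stop("planted cluster genes exceed `accessory_pool`", call. = FALSE)
  }
  structure(as.list(environment()), class = "serpan_sim_config")
}

#' Default planted scenario
#'
#' Three serpentine-associated clusters on the Cluster A/B/C pattern: one
#' 13-gene, 30-kbp cluster carried by every serpentine strain and no others,
#' plus a 10-gene/30-kbp and an 11-gene/15-kbp cluster each carried by about
#' a third of serpentine strains.  All three are causal for high-nickel
#' growth.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `serpan_sim_config`.
#' @export
default_scenario <- function(seed = 1, ...) {
  sim_config(
    planted_clusters = list(
      cluster_spec(n_genes = 13, span_bp = 30000, assortment = 1, leak = 0),
      cluster_spec(n_genes = 10, span_bp = 30000, assortment = 6 / 19, leak = 0),
      cluster_spec(n_genes = 11, span_bp = 15000, assortment = 6 / 19, leak = 0)
    ),
    seed = seed, ...
  )
}

.strain_table <- function(config) {
  reserves <- paste0("R", seq_len(config$n_reserves))
  mk <- function(prefix, n) {
    data.frame(
      strain = sprintf("%s%02d", prefix, seq_len(n)),
      soil = if (prefix == "S") "serpentine" else "nonserpentine",
      reserve = reserves[(seq_len(n) - 1L) %% config$n_reserves + 1L],
      stringsAsFactors = FALSE
    )
  }
  rbind(mk("S", config$n_serpentine), mk("N", config$n_nonserpentine))
}

#' Simulate a synthetic pan-genome population
#'
#' Draws a full synthetic dataset with the statistical structure the
#' downstream analyses assume: strain metadata over two soil types and
#' several reserves; a presence/absence matrix whose core genes are present
#' everywhere and whose accessory frequencies follow a Beta frequency
#' spectrum with subgroup-specific differentiation; planted candidate
#' clusters with configured habitat assortment; an admixture Q-matrix; a
#' subgroup-differentiated biallelic SNP matrix; growth phenotypes in high-
#' and low-nickel media; per-strain contig layouts; and a nearest-homolog
#' 16S distance table.  The planted signal is returned separately as the
#' `truth` element so recovery can be scored.
#'
#' @param config A [sim_config()].
#' @return A `serpan_population` list with elements `strains`, `pa`
#'   (observed presence/absence, after dropout if any), `snp`, `Q`,
#'   `phenotypes`, `layouts`, `homolog`, `gene_info` and `truth`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "serpan_sim_config"))
  strains <- .strain_table(config)
  n <- nrow(strains)
  set.seed(.child_seed(config$seed, "population"))

  Q <- .rdirichlet(n, rep(config$admixture_alpha, config$n_subgroups))
  rownames(Q) <- strains$strain
  colnames(Q) <- paste0("K", seq_len(config$n_subgroups))

  core_ids <- sprintf("core%04d", seq_len(config$core_size))
  acc_ids <- sprintf("acc%05d", seq_len(config$accessory_pool))

  # Planted cluster genes are taken from the front of the accessory pool.
  specs <- config$planted_clusters
  cluster_genes <- list()
  cluster_carriers <- list()
  nxt <- 1L
  serp <- strains$strain[strains$soil == "serpentine"]
  nons <- strains$strain[strains$soil == "nonserpentine"]
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ids <- acc_ids[nxt:(nxt + sp$n_genes - 1L)]
    nxt <- nxt + sp$n_genes
    carriers <- c(
      sample(serp, round(sp$assortment * length(serp))),
      sample(nons, round(sp$leak * length(nons)))
    )
    cluster_genes[[i]] <- ids
    cluster_carriers[[i]] <- sort(carriers)
  }
  names(cluster_genes) <- names(cluster_carriers) <-
    if (length(specs)) paste0("cluster", LETTERS[seq_along(specs)]) else character(0)
  planted_ids <- unlist(cluster_genes, use.names = FALSE)

  # Free accessory genes: ancestral frequency from the Beta spectrum, then
  # subgroup-specific frequencies (Balding-Nichols), then admixture-weighted
  # Bernoulli presence per strain.
  free_ids <- setdiff(acc_ids, planted_ids)
  p_anc <- stats::rbeta(length(free_ids), config$freq_spectrum_shape[1],
                        config$freq_spectrum_shape[2])
  p_sub <- vapply(seq_len(config$n_subgroups),
                  function(k) .balding_nichols(p_anc, config$subgroup_divergence),
                  numeric(length(free_ids)))
  p_strain <- pmin(1, pmax(0, tcrossprod(p_sub, Q)))  # genes x strains
  pres_free <- matrix(stats::rbinom(length(p_strain), 1L, p_strain),
                      nrow = length(free_ids))

  pa <- matrix(0L, nrow = n, ncol = config$core_size + config$accessory_pool,
               dimnames = list(strains$strain, c(core_ids, acc_ids)))
  pa[, core_ids] <- 1L
  pa[, free_ids] <- t(pres_free)
  for (i in seq_along(specs)) {
    pa[cluster_carriers[[i]], cluster_genes[[i]]] <- 1L
  }
  keep <- colSums(pa) > 0L
  pa <- pa[, keep, drop = FALSE]

  gene_info <- data.frame(
    group_id = colnames(pa),
    compartment = ifelse(colnames(pa) %in% core_ids, "core", "accessory"),
    origin = ifelse(colnames(pa) %in% core_ids, "reference",
                    ifelse(seq_len(ncol(pa)) %% 2L == 0L, "reference", "de-novo")),
    stringsAsFactors = FALSE
  )

  # SNP matrix: ancestral frequencies uniform, subgroup-differentiated like
  # the accessory genes; sites are anchored to core genes for coordinates.
  set.seed(.child_seed(config$seed, "snp"))
  q_anc <- stats::runif(config$snp_sites, 0.1, 0.9)
  q_sub <- vapply(seq_len(config$n_subgroups),
                  function(k) .balding_nichols(q_anc, config$subgroup_divergence),
                  numeric(config$snp_sites))
  q_strain <- pmin(1, pmax(0, tcrossprod(q_sub, Q)))
  snp <- t(matrix(stats::rbinom(length(q_strain), 1L, q_strain),
                  nrow = config$snp_sites))
  site_gene <- sample(core_ids, config$snp_sites, replace = TRUE)
  site_pos <- sample.int(config$gene_mean_bp, config$snp_sites, replace = TRUE)
  dimnames(snp) <- list(strains$strain, paste0(site_gene, ":", site_pos))

  truth <- list(
    causal_gene_ids = unlist(
      cluster_genes[vapply(specs, `[[`, logical(1), "causal")],
      use.names = FALSE),
    strain_subgroup_loadings = Q,
    true_effects = NULL,
    cluster_genes = cluster_genes,
    cluster_carriers = cluster_carriers,
    cluster_specs = specs,
    pa_truth = pa
  )
  effs <- rep(config$phenotype_effect, length(truth$causal_gene_ids))
  names(effs) <- truth$causal_gene_ids
  truth$true_effects <- effs

  phenotypes <- simulate_phenotypes(truth, config)
  layouts <- fragment_genomes(pa, config, cluster_genes = cluster_genes)
  truth$planted_cluster_coords <- attr(layouts, "cluster_coords")
  homolog <- simulate_homolog_distances(pa, planted_ids, config)

  if (config$dropout_rate > 0) {
    set.seed(.child_seed(config$seed, "dropout"))
    mask <- matrix(stats::rbinom(length(pa), 1L, 1 - config$dropout_rate),
                   nrow = nrow(pa))
    pa_obs <- pa * mask
    # A causal gene must remain observable somewhere; restore one carrier if
    # dropout wiped it out entirely.
    for (g in truth$causal_gene_ids) {
      if (sum(pa_obs[, g]) == 0L) {
        pa_obs[which(pa[, g] == 1L)[1L], g] <- 1L
      }
    }
    pa_obs <- pa_obs[, colSums(pa_obs) > 0L, drop = FALSE]
  } else {
    pa_obs <- pa
  }

  structure(list(
    strains = strains, pa = pa_obs, snp = snp, Q = Q,
    phenotypes = phenotypes, layouts = layouts, homolog = homolog,
    gene_info = gene_info, truth = truth, config = config
  ), class = "serpan_population")
}

#' @export
print.serpan_population <- function(x, ...) {
  cat(sprintf(
    "serpan synthetic population: %d strains (%d serpentine / %d non-serpentine),\n  %d genes (%d core), %d SNP sites, %d planted cluster(s)\n",
    nrow(x$strains), sum(x$strains$soil == "serpentine"),
    sum(x$strains$soil == "nonserpentine"), ncol(x$pa),
    sum(x$gene_info$compartment == "core" &
          x$gene_info$group_id %in% colnames(x$pa)),
    ncol(x$snp), length(x$truth$cluster_genes)))
  invisible(x)
}

#' Simulate growth phenotypes from planted truth
#'
#' High-nickel growth is additive: baseline, plus one `phenotype_effect`
#' per causal cluster carried, plus `structure_effect` times the loading on
#' subgroup 1, plus Gaussian noise.  Low-nickel growth has the same
#' structure and noise terms but no causal term (planted adaptation is
#' nickel-specific).
#'
#' @param truth Truth object from [simulate_population()].
#' @param config The matching [sim_config()].
#' @return Data frame with `strain`, `growth_highNi`, `growth_lowNi`,
#'   `soil`, `reserve`.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(config, "serpan_sim_config"))
  Q <- truth$strain_subgroup_loadings
  strains <- .strain_table(config)
  stopifnot(identical(rownames(Q), strains$strain))
  set.seed(.child_seed(config$seed, "phenotype"))
  n <- nrow(strains)

  causal_load <- numeric(n)
  specs <- truth$cluster_specs
  for (i in seq_along(specs)) {
    if (specs[[i]]$causal) {
      carried <- strains$strain %in% truth$cluster_carriers[[i]]
      causal_load <- causal_load + as.numeric(carried)
    }
  }
  struct <- config$structure_effect * Q[, 1L]
  hi <- config$baseline_od + config$phenotype_effect * causal_load + struct +
    stats::rnorm(n, 0, config$phenotype_sd)
  lo <- config$baseline_od + struct + stats::rnorm(n, 0, config$phenotype_sd)
  data.frame(strain = strains$strain, growth_highNi = hi, growth_lowNi = lo,
             soil = strains$soil, reserve = strains$reserve,
             stringsAsFactors = FALSE)
}

#' Fragment simulated genomes into draft contigs
#'
#' Lays the genes present in each strain along a shared backbone order,
#' keeps each planted cluster contiguous within its configured span, and
#' splits the sequence into contigs whose sizes are geometric around
#' `contig_mean_genes`.  Coordinates are 1-based inclusive on the forward
#' strand, with no overlapping genes.
#'
#' @param pa Binary presence/absence matrix (strains x genes).
#' @param config A [sim_config()].
#' @param cluster_genes Named list of gene-id vectors, one per planted
#'   cluster, as produced by [simulate_population()].
#' @param shuffle If `TRUE`, permute the order of non-cluster genes
#'   independently per strain (cluster blocks stay intact).
#' @return Data frame (`strain`, `contig`, `group_id`, `start`, `end`,
#'   `strand`) sorted by strain, contig and start; the per-strain cluster
#'   coordinates are attached as attribute `cluster_coords`.
#' @export
fragment_genomes <- function(pa, config, cluster_genes = list(),
                             shuffle = FALSE) {
  .assert_binary_matrix(pa, "pa")
  stopifnot(inherits(config, "serpan_sim_config"))
  set.seed(.child_seed(config$seed, "layout"))
  genes <- colnames(pa)
  specs <- config$planted_clusters
  stopifnot(length(cluster_genes) == length(specs))

  # Per-cluster geometry: gene length and gap chosen so the whole block fits
  # inside span_bp.
  geom <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    gap <- min(config$intergenic_bp, 50L)
    len <- floor(sp$span_bp / sp$n_genes) - gap
    if (len < 100L) stop("cluster span too small for its gene count", call. = FALSE)
    list(len = len, gap = gap)
  })

  gene_len <- pmax(150L, stats::rpois(length(genes), config$gene_mean_bp))
  names(gene_len) <- genes
  in_cluster <- unlist(cluster_genes, use.names = FALSE)

  # Shared backbone: random order of all genes with each cluster inserted as
  # one intact block at a random position.
  backbone <- sample(setdiff(genes, in_cluster))
  blocks <- as.list(backbone)
  for (i in seq_along(cluster_genes)) {
    pos <- sample.int(length(blocks) + 1L, 1L)
    blocks <- append(blocks, list(cluster_genes[[i]]), after = pos - 1L)
  }

  cluster_index <- integer(0)  # gene -> cluster number
  for (i in seq_along(cluster_genes)) {
    ci <- rep(i, length(cluster_genes[[i]]))
    names(ci) <- cluster_genes[[i]]
    cluster_index <- c(cluster_index, ci)
  }

  strain_ids <- rownames(pa)
  out <- vector("list", length(strain_ids))
  coords <- list()
  for (si in seq_along(strain_ids)) {
    s <- strain_ids[si]
    present <- colnames(pa)[pa[s, ] == 1L]
    sblocks <- lapply(blocks, function(b) b[b %in% present])
    sblocks <- sblocks[lengths(sblocks) > 0L]
    if (shuffle) sblocks <- sblocks[sample(seq_along(sblocks))]
    nb <- length(sblocks)
    block_is_cluster <- vapply(
      sblocks, function(b) b[1L] %in% in_cluster, logical(1))

    ngene_total <- sum(lengths(sblocks))
    # Contig breaks land between blocks only, so a break never splits a
    # planted cluster; per-gene break probability 1/contig_mean_genes.
    if (config$contig_mean_genes >= ngene_total || nb == 1L) {
      brk <- rep(FALSE, max(0L, nb - 1L))
    } else {
      brk <- stats::runif(nb - 1L) <
        lengths(sblocks)[-nb] / config$contig_mean_genes
    }
    contig_of_block <- cumsum(c(1L, as.integer(brk)))

    genes_v <- unlist(sblocks, use.names = FALSE)
    bidx <- rep(seq_len(nb), lengths(sblocks))
    is_cl <- block_is_cluster[bidx]
    cl_i <- rep(NA_integer_, length(genes_v))
    cl_i[is_cl] <- cluster_index[genes_v[is_cl]]
    lens <- unname(gene_len[genes_v])
    gaps <- pmax(1L, stats::rpois(length(genes_v), config$intergenic_bp))
    if (any(is_cl)) {
      lens[is_cl] <- vapply(cl_i[is_cl], function(i) geom[[i]]$len, numeric(1))
      gaps[is_cl] <- vapply(cl_i[is_cl], function(i) geom[[i]]$gap, numeric(1))
    }
    contig_v <- contig_of_block[bidx]
    # per-contig 1-based coordinates
    step <- lens + gaps
    starts <- integer(length(genes_v))
    for (ctg in unique(contig_v)) {
      k <- which(contig_v == ctg)
      starts[k] <- 1L + cumsum(c(0L, step[k][-length(k)]))
    }
    ends <- starts + as.integer(lens) - 1L
    df <- data.frame(
      strain = s, contig = sprintf("%s_ctg%03d", s, contig_v),
      group_id = genes_v, start = as.integer(starts), end = ends,
      strand = "+", stringsAsFactors = FALSE)
    out[[si]] <- df
    for (i in unique(cl_i[!is.na(cl_i)])) {
      k <- which(!is.na(cl_i) & cl_i == i)
      cl <- names(cluster_genes)[i]
      coords[[paste(cl, s, sep = ":")]] <- data.frame(
        cluster = cl, strain = s, contig = df$contig[k[1L]],
        start = min(df$start[k]), end = max(df$end[k]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cluster_coords") <-
    if (length(coords)) {
      cc <- do.call(rbind, coords); rownames(cc) <- NULL; cc
    } else NULL
  res
}

#' Simulate nearest-homolog 16S distances
#'
#' Every accessory gene is assigned a 16S distance between the focal clade
#' and the lineage carrying its closest homolog.  Non-candidates draw from a
#' Beta baseline; candidate genes get the same draw plus `homolog_shift`,
#' emulating acquisition from more distant donors.
#'
#' @param pa Presence/absence matrix (used to identify accessory genes).
#' @param candidate_ids Accessory gene ids to shift.
#' @param config A [sim_config()].
#' @return Data frame (`group_id`, `closest_lineage`, `distance_16S`,
#'   `candidate_flag`).
#' @export
simulate_homolog_distances <- function(pa, candidate_ids, config) {
  .assert_binary_matrix(pa, "pa")
  stopifnot(inherits(config, "serpan_sim_config"))
  acc <- colnames(pa)[colSums(pa) < nrow(pa)]
  candidate_ids <- intersect(candidate_ids, acc)
  if (length(setdiff(acc, candidate_ids)) == 0L) {
    stop("all accessory genes are candidates: no reference distribution",
         call. = FALSE)
  }
  set.seed(.child_seed(config$seed, "homolog"))
  d <- stats::rbeta(length(acc), config$homolog_base_shape[1],
                    config$homolog_base_shape[2])
  is_cand <- acc %in% candidate_ids
  d[is_cand] <- pmin(1, d[is_cand] + config$homolog_shift)
  data.frame(
    group_id = acc,
    closest_lineage = sprintf("taxon_%04d",
                              sample.int(9999L, length(acc), replace = TRUE)),
    distance_16S = d,
    candidate_flag = is_cand,
    stringsAsFactors = FALSE
  )
}

#' Gene-dropout efficacy simulation for core/accessory identification
#'
#' Applies independent per-gene-per-strain dropout to a known presence/
#' absence matrix, re-runs the core/accessory partition, and reports how
#' often true core genes are misclassified and how much accessory gene
#' frequencies are distorted.  For a core gene over `S` strains the
#' probability of losing core status is exactly `1 - (1 - d)^S`.
#'
#' @param pa True binary presence/absence matrix.
#' @param dropout_rate Per-cell probability of missing a present gene, in
#'   `[0, 1]`.
#' @param n_reps Number of dropout replicates.
#' @param seed Integer seed.
#' @return List with `core_misclass_rate` (fraction of true-core gene
#'   replicates no longer called core), `expected_core_misclass`,
#'   `mean_freq_distortion` (mean observed-minus-true frequency over
#'   accessory genes), `n_core`, `n_reps` and the per-replicate rates.
#' @export
simulate_accessory_identification <- function(pa, dropout_rate, n_reps = 20,
                                              seed = 1) {
  .assert_binary_matrix(pa, "pa")
  .assert_prob(dropout_rate, "dropout_rate")
  .assert_count(n_reps, "n_reps")
  set.seed(as.integer(seed))
  S <- nrow(pa)
  true_core <- colnames(pa)[colSums(pa) == S]
  true_freq <- colMeans(pa)
  acc <- setdiff(colnames(pa), true_core)

  per_rep <- numeric(n_reps)
  distort <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    mask <- matrix(stats::rbinom(length(pa), 1L, 1 - dropout_rate),
                   nrow = S)
    obs <- pa * mask
    if (all(colSums(obs) == 0L)) {
      stop("dropout removed every gene call: empty pan-genome", call. = FALSE)
    }
    still_core <- colSums(obs[, true_core, drop = FALSE]) == S
    per_rep[r] <- if (length(true_core)) mean(!still_core) else NA_real_
    distort[r] <- if (length(acc)) {
      mean(colMeans(obs[, acc, drop = FALSE]) - true_freq[acc])
    } else NA_real_
  }
  list(
    core_misclass_rate = mean(per_rep),
    expected_core_misclass = 1 - (1 - dropout_rate)^S,
    mean_freq_distortion = mean(distort),
    per_rep_misclass = per_rep,
    n_core = length(true_core), n_strains = S, n_reps = n_reps
  )
}

#' Simulate tabular homology hit tables for a population
#'
#' Emits the two hit-table layers the ortholog-grouping step consumes:
#' per-strain hits of gene calls against a reference proteome (core genes
#' and reference-origin accessory genes), and pairwise between-strain hits
#' for de-novo genes, from which reciprocal best hits are derived.  True
#' orthologs receive dominant bitscores; a sprinkling of weaker decoy hits
#' exercises best-hit selection.  All emitted hits pass the default
#' homology filters.
#'
#' @param pop A `serpan_population`.
#' @param decoy_rate Expected number of decoy hits per true pairwise hit.
#' @return List with `reference_hits` (data frame), `pairwise` (named list
#'   of data frames, one per ordered strain pair `"A->B"`), and
#'   `gene_strains` (named vector mapping gene instance id to strain).
#' @export
simulate_hit_tables <- function(pop, decoy_rate = 0.02) {
  stopifnot(inherits(pop, "serpan_population"))
  set.seed(.child_seed(pop$config$seed, "hits"))
  pa <- pop$pa
  origin <- setNames(pop$gene_info$origin, pop$gene_info$group_id)
  strains <- rownames(pa)

  # Stable per-strain instance ids in layout order so ids do not encode the
  # ortholog group.
  inst <- list(); gene_strains <- character(0)
  inst_of <- function(s) inst[[s]]
  for (s in strains) {
    present <- colnames(pa)[pa[s, ] == 1L]
    lay <- pop$layouts[pop$layouts$strain == s, ]
    ord <- lay$group_id[lay$group_id %in% present]
    ord <- c(ord, setdiff(present, ord))
    ids <- sprintf("%s_g%05d", s, seq_along(ord))
    names(ids) <- ord
    inst[[s]] <- ids
    gs <- rep(s, length(ids)); names(gs) <- ids
    gene_strains <- c(gene_strains, gs)
  }

  mk_hit <- function(query, subject, qlen, bit) {
    n <- length(query)
    alen <- ceiling(qlen * stats::runif(n, 0.85, 1.0))
    data.frame(
      query_id = query, subject_id = subject,
      percent_identity = round(stats::runif(n, 60, 99), 1),
      alignment_length = alen,
      mismatches = pmax(0L, round(alen * stats::runif(n, 0, 0.2))),
      gap_opens = 0L, q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
      evalue = 10^-stats::runif(n, 25, 60), bitscore = round(bit, 1),
      query_length = qlen, stringsAsFactors = FALSE
    )
  }

  ref_rows <- list()
  for (s in strains) {
    ids <- inst[[s]]
    grp <- names(ids)
    is_ref <- origin[grp] == "reference"
    if (!any(is_ref)) next
    qlen <- rep(300L, sum(is_ref))
    ref_rows[[s]] <- mk_hit(unname(ids[is_ref]), paste0("REFP_", grp[is_ref]),
                            qlen, stats::runif(sum(is_ref), 400, 900))
  }
  reference_hits <- do.call(rbind, ref_rows)
  rownames(reference_hits) <- NULL

  denovo_groups <- names(origin)[origin == "de-novo"]
  pairwise <- list()
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (i == j) next
      a <- strains[i]; b <- strains[j]
      shared <- denovo_groups[pa[a, denovo_groups] == 1L &
                                pa[b, denovo_groups] == 1L]
      if (!length(shared)) next
      qa <- unname(inst[[a]][shared]); sb <- unname(inst[[b]][shared])
      h <- mk_hit(qa, sb, rep(300L, length(shared)),
                  stats::runif(length(shared), 500, 900))
      n_decoy <- stats::rpois(1L, decoy_rate * length(shared))
      if (n_decoy > 0L && length(shared) > 1L) {
        qi <- sample(shared, n_decoy, replace = TRUE)
        si <- vapply(qi, function(g) sample(setdiff(shared, g), 1L), "")
        h <- rbind(h, mk_hit(unname(inst[[a]][qi]), unname(inst[[b]][si]),
                             rep(300L, n_decoy),
                             stats::runif(n_decoy, 60, 150)))
      }
      pairwise[[paste0(a, "->", b)]] <- h
    }
  }
  list(reference_hits = reference_hits, pairwise = pairwise,
       gene_strains = gene_strains,
       instance_map = setNames(
         rep(names(inst), lengths(inst)),
         unlist(lapply(inst, unname), use.names = FALSE)),
       truth_groups = setNames(
         unlist(lapply(inst, names), use.names = FALSE),
         unlist(lapply(inst, unname), use.names = FALSE)))
}

#' Write aligned FASTA files for simulated core genes
#'
#' Builds one gapless alignment per requested core gene: an invariant
#' random backbone with the gene's simulated SNP sites overwritten from the
#' SNP matrix (allele 0 = one base, allele 1 = another).  Useful for
#' exercising the alignment-based SNP caller against known truth.
#'
#' @param pop A `serpan_population`.
#' @param genes Core gene ids; defaults to all genes carrying SNP sites.
#' @param width Alignment width in bp.
#' @return Named list of character matrices (strains x positions); use
#'   [write_alignments()] to serialize as FASTA.
#' @export
simulate_core_alignments <- function(pop, genes = NULL, width = NULL) {
  stopifnot(inherits(pop, "serpan_population"))
  site_gene <- sub(":.*$", "", colnames(pop$snp))
  site_pos <- as.integer(sub("^.*:", "", colnames(pop$snp)))
  if (is.null(genes)) genes <- unique(site_gene)
  if (is.null(width)) width <- pop$config$gene_mean_bp
  set.seed(.child_seed(pop$config$seed, "snp") + 1L)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (g in genes) {
    idx <- which(site_gene == g & site_pos <= width)
    backbone <- sample(bases, width, replace = TRUE)
    m <- matrix(rep(backbone, each = nrow(pop$snp)), nrow = nrow(pop$snp),
                dimnames = list(rownames(pop$snp), NULL))
    for (k in idx) {
      p <- site_pos[k]
      ref <- backbone[p]
      alt <- setdiff(bases, ref)[1L]
      m[, p] <- ifelse(pop$snp[, k] == 1L, alt, ref)
    }
    out[[g]] <- m
  }
  out
}
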