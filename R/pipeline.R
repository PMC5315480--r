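#' Pipeline run configuration
#'
#' Bundles all stage parameters.  In `"synthetic"` mode the input is drawn
#' from [simulate_population()]; in `"files"` mode the exchange files are
#' read from `paths` (required: `presence_absence`, `phenotypes`,
#' `qmatrix`; optional: `snp_matrix`, `gff3_dir`, `homolog_distances`).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim A [sim_config()] (synthetic mode).
#' @param paths Named list of input paths (file mode).
#' @param fdr_level FDR threshold for the candidate set.
#' @param bonferroni_alpha Family-wise level for the Bonferroni flag.
#' @param no_hit_fdr_level FDR level at which the low-nickel phenotype is
#'   expected to return no candidates.
#' @param min_tandem,gap_bp Cluster-calling parameters.
#' @param hgt_tiers Percent FDR tiers for the donor-distance test.
#' @param n_perm Permutations for PERMANOVA.
#' @param n_boot Bootstrap replicates for R-squared intervals.
#' @param seed Master seed (synthetic mode uses `sim$seed` for data).
#' @return A `serpan_run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"), sim = default_scenario(),
                       paths = list(), fdr_level = 0.10,
                       bonferroni_alpha = 0.05, no_hit_fdr_level = 0.20,
                       min_tandem = 4, gap_bp = 10000,
                       hgt_tiers = c(1, 5, 10), n_perm = 999, n_boot = 200,
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(fdr_level > 0, fdr_level < 1, bonferroni_alpha > 0,
            bonferroni_alpha < 1)
  if (mode == "files") {
    req <- c("presence_absence", "phenotypes", "qmatrix")
    miss <- setdiff(req, names(paths))
    if (length(miss)) {
      stop("file mode is missing required input(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (nm in names(paths)) {
      if (!file.exists(paths[[nm]]) && !dir.exists(paths[[nm]])) {
        stop("input path for `", nm, "` does not exist: ", paths[[nm]],
             call. = FALSE)
      }
    }
  } else {
    stopifnot(inherits(sim, "serpan_sim_config"))
  }
  structure(as.list(environment()), class = "serpan_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` block
#' mirrors [sim_config()] with `planted_clusters` as a list of
#' [cluster_spec()] argument maps.
#'
#' @param path YAML file.
#' @return A `serpan_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    pcs <- lapply(y$sim$planted_clusters, function(p) do.call(cluster_spec, p))
    y$sim$planted_clusters <- pcs %||% list()
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full association pipeline
#'
#' Executes the stages in dependency order: input (simulate or read),
#' pan-genome summaries, structure-corrected association mapping of gene
#' content and SNPs against high-nickel growth (and the no-hit check on
#' low-nickel growth), positional cluster calling and cross-strain
#' matching, the donor-distance shift test, and PERMANOVA variance
#' partitioning with bootstrap intervals.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage outputs and a
#'   manifest are written there.
#' @return A `serpan_run` list with per-stage results and a `summary`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "serpan_run_config"))

  inp <- .stage("input", {
    if (config$mode == "synthetic") {
      pop <- simulate_population(config$sim)
      list(pa = pop$pa, snp = pop$snp, Q = pop$Q,
           phenotypes = pop$phenotypes, layouts = pop$layouts,
           homolog = pop$homolog, pop = pop)
    } else {
      p <- config$paths
      list(
        pa = read_presence_absence(p$presence_absence),
        snp = if (!is.null(p$snp_matrix)) {
          read_presence_absence(p$snp_matrix)
        },
        Q = read_qmatrix(p$qmatrix),
        phenotypes = read_phenotypes(p$phenotypes),
        layouts = if (!is.null(p$gff3_dir)) {
          files <- list.files(p$gff3_dir, "\\.gff3$", full.names = TRUE)
          do.call(rbind, lapply(files, function(f) {
            read_gff3(f, sub("\\.gff3$", "", basename(f)))
          }))
        },
        homolog = if (!is.null(p$homolog_distances)) {
          read_homolog_distances(p$homolog_distances)
        },
        pop = NULL)
    }
  })

  pangen <- .stage("pangenome", {
    strains <- inp$phenotypes$strain
    stopifnot(all(strains %in% rownames(inp$pa)))
    pa <- inp$pa[strains, , drop = FALSE]
    part <- partition_core_accessory(pa)
    list(pa = pa, partition = part,
         spectrum = gene_frequency_spectrum(pa),
         counts = pan_core_counts(pa, list(focal = strains)))
  })

  assoc <- .stage("association", {
    ph <- inp$phenotypes
    Q <- inp$Q[ph$strain, , drop = FALSE]
    resid_hi <- regress_out_structure(ph$growth_highNi, Q)
    resid_lo <- regress_out_structure(ph$growth_lowNi, Q)
    acc <- pangen$pa[, pangen$partition$accessory, drop = FALSE]
    scan_hi <- gene_content_association(acc, resid_hi)
    genes_hi <- annotate_association(scan_hi, acc, ph$growth_highNi, ph$soil,
                                     bonferroni_alpha = config$bonferroni_alpha)
    scan_lo <- gene_content_association(acc, resid_lo)
    genes_lo <- annotate_association(scan_lo, acc, ph$growth_lowNi, ph$soil,
                                     bonferroni_alpha = config$bonferroni_alpha)
    snps_hi <- NULL
    if (!is.null(inp$snp)) {
      snp <- inp$snp[ph$strain, , drop = FALSE]
      scan_snp <- snp_association(snp, resid_hi)
      snps_hi <- annotate_association(scan_snp, snp, ph$growth_highNi,
                                      ph$soil,
                                      bonferroni_alpha = config$bonferroni_alpha)
    }
    list(genes_highNi = genes_hi, genes_lowNi = genes_lo,
         snps_highNi = snps_hi,
         skipped_genes = scan_hi$skipped,
         sets = significant_set(genes_hi, config$fdr_level),
         sets_snp = if (!is.null(snps_hi)) {
           significant_set(snps_hi, config$fdr_level)
         },
         sets_lowNi_lenient = significant_set(genes_lo,
                                              config$no_hit_fdr_level))
  })

  clus <- .stage("clusters", {
    if (is.null(inp$layouts)) {
      NULL
    } else {
      cand <- assoc$sets$fdr
      cl <- call_clusters(inp$layouts, cand, min_tandem = config$min_tandem,
                          gap_bp = config$gap_bp)
      fam <- match_clusters_across_strains(cl)
      summ <- cluster_summary(fam, assoc$genes_highNi,
                              inp$phenotypes$strain, inp$phenotypes$soil)
      list(clusters = cl, families = fam, summary = summ)
    }
  })

  hgt <- .stage("hgt", {
    if (is.null(inp$homolog)) {
      NULL
    } else {
      rec <- inp$homolog
      tier <- rep(Inf, nrow(rec))
      hit <- match(rec$group_id, assoc$genes_highNi$variant_id)
      ok <- !is.na(hit)
      tier[ok] <- fdr_tiers(assoc$genes_highNi,
                            config$hgt_tiers)[hit[ok]]
      rec$fdr_tier <- tier
      tryCatch(distance_shift_test(rec, tiers = config$hgt_tiers),
               error = function(e) {
                 message("hgt stage skipped: ", conditionMessage(e))
                 NULL
               })
    }
  })

  biog <- .stage("biogeo", {
    fac <- inp$phenotypes[, c("soil", "reserve"), drop = FALSE]
    acc <- pangen$pa[, pangen$partition$accessory, drop = FALSE]
    Dg <- gene_content_distance(acc)
    out <- list(
      gene = list(D = Dg,
                  permanova = permanova(Dg, fac, n_perm = config$n_perm,
                                        seed = config$seed),
                  ci = bootstrap_r2_ci(Dg, fac, n_boot = config$n_boot,
                                       seed = config$seed)))
    if (!is.null(inp$snp)) {
      Ds <- snp_distance(inp$snp[inp$phenotypes$strain, , drop = FALSE])
      out$snp <- list(D = Ds,
                      permanova = permanova(Ds, fac, n_perm = config$n_perm,
                                            seed = config$seed + 1L),
                      ci = bootstrap_r2_ci(Ds, fac, n_boot = config$n_boot,
                                           seed = config$seed + 1L))
    }
    out
  })

  summary <- list(
    n_strains = nrow(pangen$pa),
    n_genes = ncol(pangen$pa),
    n_core = length(pangen$partition$core),
    n_accessory = length(pangen$partition$accessory),
    n_gene_candidates_fdr = assoc$sets$n_fdr,
    n_gene_candidates_bonferroni = assoc$sets$n_bonferroni,
    n_snp_candidates_fdr = if (!is.null(assoc$sets_snp)) {
      assoc$sets_snp$n_fdr
    } else NA_integer_,
    n_lowNi_candidates_lenient = assoc$sets_lowNi_lenient$n_fdr,
    n_cluster_families = if (!is.null(clus)) nrow(clus$summary) else NA,
    n_families_ge4 = if (!is.null(clus)) {
      sum(clus$summary$n_candidates >= 4)
    } else NA,
    n_families_ge10 = if (!is.null(clus)) {
      sum(clus$summary$n_candidates >= 10)
    } else NA,
    n_perfect_assorting_genes = if (!is.null(clus) && nrow(clus$summary)) {
      max(clus$summary$n_perfect_assort)
    } else 0L,
    largest_family_span_bp = if (!is.null(clus) && nrow(clus$summary)) {
      max(clus$summary$max_span_bp)
    } else NA,
    hgt_mean_shift = if (!is.null(hgt)) {
      hgt$mean_diff[hgt$tier == max(hgt$tier)]
    } else NA,
    permanova_soil_R2_accessory =
      biog$gene$permanova$table$R2[biog$gene$permanova$table$factor == "soil"]
  )

  run <- structure(list(
    config = config, input = inp, pangenome = pangen, association = assoc,
    clusters = clus, hgt = hgt, biogeo = biog, summary = summary,
    manifest = list(
      package_version = as.character(utils::packageVersion("serpan")),
      seed = config$seed,
      mode = config$mode,
      fdr_level = config$fdr_level,
      bonferroni_alpha = config$bonferroni_alpha,
      min_tandem = config$min_tandem, gap_bp = config$gap_bp,
      n_perm = config$n_perm, n_boot = config$n_boot)
  ), class = "serpan_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    make_report(run, out_dir)
  }
  run
}

#' @export
print.serpan_run <- function(x, ...) {
  s <- x$summary
  cat("serpan pipeline run\n")
  cat(sprintf("  strains: %d, genes: %d (core %d / accessory %d)\n",
              s$n_strains, s$n_genes, s$n_core, s$n_accessory))
  cat(sprintf("  gene candidates: %d at %d%% FDR, %d after Bonferroni\n",
              s$n_gene_candidates_fdr,
              round(100 * x$config$fdr_level),
              s$n_gene_candidates_bonferroni))
  if (!is.na(s$n_snp_candidates_fdr)) {
    cat(sprintf("  SNP candidates: %d at %d%% FDR\n", s$n_snp_candidates_fdr,
                round(100 * x$config$fdr_level)))
  }
  if (!is.na(s$n_cluster_families)) {
    cat(sprintf("  cluster families: %d (>=10 candidates: %d), max span %s bp\n",
                s$n_cluster_families, s$n_families_ge10,
                format(s$largest_family_span_bp, big.mark = ",")))
  }
  invisible(x)
}

#' Write a human-readable report for a pipeline run
#'
#' Deterministic markdown summary plus the candidate table (q-value,
#' effect, per-soil frequencies), cluster-family table, donor-distance
#' table and PERMANOVA tables as TSVs.
#'
#' @param run A `serpan_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
make_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- run$summary

  fmt_tbl <- function(df, digits = 4) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
    }
    df
  }

  genes <- run$association$genes_highNi
  cand <- genes[genes$q < run$config$fdr_level, , drop = FALSE]
  cand_out <- data.frame(
    variant = cand$variant_id, kind = cand$variant_kind,
    q_value = signif(cand$q, 3),
    bonferroni = cand$bonferroni_sig,
    effect = round(cand$effect, 2),
    freq_S = sprintf("%.2f", cand$freq_S),
    freq_N = sprintf("%.2f", cand$freq_N),
    stringsAsFactors = FALSE)
  .write_tsv(cand_out, file.path(out_dir, "candidates.tsv"))
  .write_tsv(fmt_tbl(genes), file.path(out_dir, "association_genes.tsv"))
  if (!is.null(run$association$snps_highNi)) {
    .write_tsv(fmt_tbl(run$association$snps_highNi),
               file.path(out_dir, "association_snps.tsv"))
  }
  if (!is.null(run$clusters)) {
    .write_tsv(fmt_tbl(run$clusters$summary),
               file.path(out_dir, "cluster_families.tsv"))
  }
  if (!is.null(run$hgt)) {
    .write_tsv(fmt_tbl(run$hgt), file.path(out_dir, "hgt_shift.tsv"))
  }
  pmv <- run$biogeo$gene$permanova$table
  pmv$dataset <- "accessory_gene_content"
  if (!is.null(run$biogeo$snp)) {
    p2 <- run$biogeo$snp$permanova$table
    p2$dataset <- "core_snps"
    pmv <- rbind(pmv, p2)
  }
  .write_tsv(fmt_tbl(pmv), file.path(out_dir, "permanova.tsv"))

  lines <- c(
    "# Pipeline run summary", "",
    sprintf("- strains: %d", s$n_strains),
    sprintf("- genes: %d (core %d, accessory %d)", s$n_genes, s$n_core,
            s$n_accessory),
    sprintf("- gene candidates at %d%% FDR: %d",
            round(100 * run$config$fdr_level), s$n_gene_candidates_fdr),
    sprintf("- gene candidates after Bonferroni: %d",
            s$n_gene_candidates_bonferroni),
    sprintf("- SNP candidates at %d%% FDR: %s",
            round(100 * run$config$fdr_level), s$n_snp_candidates_fdr),
    sprintf("- low-nickel candidates at %d%% FDR: %d",
            round(100 * run$config$no_hit_fdr_level),
            s$n_lowNi_candidates_lenient),
    sprintf("- cluster families: %s (with >= 4 candidates: %s, >= 10: %s)",
            s$n_cluster_families, s$n_families_ge4, s$n_families_ge10),
    sprintf("- perfectly assorting genes in largest family: %s",
            s$n_perfect_assorting_genes),
    sprintf("- largest family span: %s bp", s$largest_family_span_bp),
    sprintf("- donor-distance shift (least stringent tier): %s",
            signif(s$hgt_mean_shift, 3)),
    sprintf("- PERMANOVA soil R2 (accessory content): %s",
            signif(s$permanova_soil_R2_accessory, 3)))
  writeLines(lines, file.path(out_dir, "report.md"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
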