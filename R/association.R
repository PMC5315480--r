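#' Residualize a phenotype on admixture structure
#'
#' Ordinary least squares of the phenotype on an intercept plus the first
#' `K - 1` Q-matrix columns (the last is dropped because loadings sum to 1);
#' any further collinear columns are dropped with a warning.  The residuals
#' are what association tests operate on.
#'
#' @param phenotype Numeric vector, one value per strain, no missing values.
#' @param Q Numeric strains x K admixture matrix, rows aligned to
#'   `phenotype` and summing to 1.
#' @return Numeric residual vector (sums to zero), named like `phenotype`.
#' @export
regress_out_structure <- function(phenotype, Q) {
  Q <- as.matrix(Q)
  if (length(phenotype) != nrow(Q)) {
    stop("phenotype and Q have different numbers of strains", call. = FALSE)
  }
  if (anyNA(phenotype) || anyNA(Q)) stop("missing values", call. = FALSE)
  if (any(abs(rowSums(Q) - 1) > 1e-6)) {
    stop("Q rows must sum to 1", call. = FALSE)
  }
  X <- Q[, -ncol(Q), drop = FALSE]
  if (ncol(X) == 0L) return(setNames(phenotype - mean(phenotype),
                                     names(phenotype)))
  fit <- stats::lm.fit(cbind(1, X), phenotype)
  if (any(is.na(fit$coefficients[-1]))) {
    warning("collinear structure columns dropped from the regression")
  }
  setNames(unname(fit$residuals), names(phenotype))
}

#' Wilcoxon rank-sum test
#'
#' Reports the rank sum of the first group (midranks for ties) and a
#' two-sided p-value: exact by enumeration when the smaller group has at
#' most `exact_max_n` observations and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_max_n Largest smaller-group size for which the exact null
#'   distribution is used.
#' @return List with `W` (rank sum of `x`), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max_n
  if (ties && length(unique(c(x, y))) == 1L) {
    return(list(W = W, p = 1, exact = FALSE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  list(W = W, p = p, exact = exact)
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"bh"` (Benjamini-Hochberg step-up), or
#'   `"qvalue"` (Storey: BH scaled by an estimate of the null proportion
#'   `pi0 = min(1, mean(p > 0.5) / 0.5)`).
#' @return Adjusted values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "qvalue")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  switch(method,
    bonferroni = stats::p.adjust(p, "bonferroni"),
    bh = stats::p.adjust(p, "BH"),
    qvalue = {
      pi0 <- min(1, mean(p > 0.5) / 0.5)
      if (pi0 <= 0) pi0 <- 1 / length(p)  # degenerate: all p tiny
      pmin(1, pi0 * stats::p.adjust(p, "BH"))
    })
}

#' Effect size and per-soil carrier frequencies for a variant
#'
#' Effect is the difference in mean raw high-nickel growth between carriers
#' and non-carriers (raw, not residualized, so it is in OD600 units);
#' frequencies are carrier fractions among serpentine and non-serpentine
#' strains.
#'
#' @param carrier Logical/0-1 vector of carrier status per strain.
#' @param phenotype Raw phenotype vector aligned to `carrier`.
#' @param soil Character vector (`"serpentine"`/`"nonserpentine"`) aligned
#'   to `carrier`.
#' @return List with `effect`, `freq_S`, `freq_N`.
#' @export
effect_and_frequencies <- function(carrier, phenotype, soil) {
  carrier <- as.logical(carrier)
  if (!any(carrier) || all(carrier)) {
    stop("effect undefined: variant absent or fixed", call. = FALSE)
  }
  list(effect = mean(phenotype[carrier]) - mean(phenotype[!carrier]),
       freq_S = mean(carrier[soil == "serpentine"]),
       freq_N = mean(carrier[soil == "nonserpentine"]))
}

# Shared machinery for the two variant kinds: Wilcoxon of residuals between
# carrier classes, with fixed/singleton/minor-class skips.
.class_association <- function(m, residuals, kind, min_minor, exact_max_n) {
  stopifnot(nrow(m) == length(residuals))
  res_rows <- vector("list", ncol(m))
  skip_rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    id <- colnames(m)[j]
    if (kind == "snp" && !all(v %in% c(0L, 1L))) {
      skip_rows[[j]] <- data.frame(variant_id = id, reason = "not_biallelic",
                                   stringsAsFactors = FALSE)
      next
    }
    n1 <- sum(v == 1L); n0 <- sum(v == 0L)
    minor <- min(n1, n0)
    if (minor == 0L) {
      skip_rows[[j]] <- data.frame(variant_id = id, reason = "fixed",
                                   stringsAsFactors = FALSE)
      next
    }
    if (minor < min_minor) {
      reason <- if (minor == 1L) "singleton" else "minor_class_too_small"
      skip_rows[[j]] <- data.frame(variant_id = id, reason = reason,
                                   stringsAsFactors = FALSE)
      next
    }
    wt <- wilcoxon_rank_sum(residuals[v == 1L], residuals[v == 0L],
                            exact_max_n = exact_max_n)
    res_rows[[j]] <- data.frame(
      variant_id = id, variant_kind = kind, W = wt$W, p = wt$p,
      n_with = n1, n_without = n0, stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, Filter(Negate(is.null), res_rows)),
       skipped = do.call(rbind, Filter(Negate(is.null), skip_rows)))
}

#' Gene-content association scan
#'
#' For every accessory gene with carrier and non-carrier classes of at
#' least `min_minor` strains, a Wilcoxon rank-sum test of the
#' structure-corrected phenotype residuals between classes.  Fixed genes
#' and singletons are skipped with reason codes.
#'
#' @param pa Binary presence/absence matrix restricted to the focal strains
#'   (rows aligned with `residuals`).
#' @param residuals From [regress_out_structure()].
#' @param min_minor Minimum size of the smaller carrier class.
#' @param exact_max_n Passed to [wilcoxon_rank_sum()].
#' @return List with `results` (data frame: `variant_id`, `variant_kind`,
#'   `W`, `p`, `n_with`, `n_without`) and `skipped` (`variant_id`,
#'   `reason`).
#' @export
gene_content_association <- function(pa, residuals, min_minor = 2,
                                     exact_max_n = 25) {
  .assert_binary_matrix(pa, "pa")
  .class_association(pa, residuals, "gene", min_minor, exact_max_n)
}

#' Core-genome SNP association scan
#'
#' Identical test to [gene_content_association()] with allele classes;
#' non-biallelic columns are skipped with reason `"not_biallelic"`.
#'
#' @param snp Strains x sites genotype matrix coded 0/1 for biallelic
#'   sites (other codings mark a site non-biallelic).
#' @inheritParams gene_content_association
#' @return Same shape as [gene_content_association()].
#' @export
snp_association <- function(snp, residuals, min_minor = 2,
                            exact_max_n = 25) {
  .class_association(snp, residuals, "snp", min_minor, exact_max_n)
}

#' Annotate an association scan with adjusted p-values, effects and
#' frequencies
#'
#' Adds `q` (FDR-adjusted), `bonferroni_sig`, raw-phenotype `effect` and
#' per-soil carrier frequencies to a scan result.
#'
#' @param scan Output of [gene_content_association()] or
#'   [snp_association()].
#' @param m The matrix the scan was run on.
#' @param phenotype Raw (unresidualized) phenotype vector.
#' @param soil Soil labels aligned with the matrix rows.
#' @param fdr_method Method for [adjust_pvalues()].
#' @param bonferroni_alpha Family-wise level for the Bonferroni flag.
#' @return Data frame of `AssociationResult` rows ordered by `q` then `p`.
#' @export
annotate_association <- function(scan, m, phenotype, soil,
                                 fdr_method = "bh", bonferroni_alpha = 0.05) {
  res <- scan$results
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(variant_id = character(0), variant_kind = character(0),
                      W = numeric(0), p = numeric(0), q = numeric(0),
                      bonferroni_sig = logical(0), effect = numeric(0),
                      freq_S = numeric(0), freq_N = numeric(0),
                      n_with = integer(0), n_without = integer(0)))
  }
  res$q <- adjust_pvalues(res$p, fdr_method)
  res$bonferroni_sig <- adjust_pvalues(res$p, "bonferroni") < bonferroni_alpha
  ef <- lapply(res$variant_id, function(id) {
    effect_and_frequencies(m[, id] == 1L, phenotype, soil)
  })
  res$effect <- vapply(ef, `[[`, numeric(1), "effect")
  res$freq_S <- vapply(ef, `[[`, numeric(1), "freq_S")
  res$freq_N <- vapply(ef, `[[`, numeric(1), "freq_N")
  res[order(res$q, res$p, res$variant_id), ]
}

#' Candidate sets at FDR and Bonferroni thresholds
#'
#' @param results Annotated association table (needs `variant_id`, `q`,
#'   `bonferroni_sig`).
#' @param fdr_level FDR threshold; candidates have `q < fdr_level`.
#' @return List with `fdr` and `bonferroni` id vectors plus the counts.
#' @export
significant_set <- function(results, fdr_level = 0.10) {
  if (is.null(results) || nrow(results) == 0L) {
    return(list(fdr = character(0), bonferroni = character(0),
                n_fdr = 0L, n_bonferroni = 0L, fdr_level = fdr_level))
  }
  fdr_ids <- results$variant_id[results$q < fdr_level]
  bon_ids <- results$variant_id[results$bonferroni_sig]
  list(fdr = fdr_ids, bonferroni = bon_ids,
       n_fdr = length(fdr_ids), n_bonferroni = length(bon_ids),
       fdr_level = fdr_level)
}

#' FDR tier of each variant
#'
#' Smallest of the given FDR levels (in percent) at which the variant is
#' significant; `Inf` when none.
#'
#' @param results Annotated association table.
#' @param tiers Percent FDR levels, ascending.
#' @return Numeric vector aligned with `results` rows.
#' @export
fdr_tiers <- function(results, tiers = c(1, 5, 10)) {
  tiers <- sort(tiers)
  out <- rep(Inf, nrow(results))
  for (t in rev(tiers)) out[results$q < t / 100] <- t
  out
}
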