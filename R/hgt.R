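#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' is exact when `n * m <= 10000` and there are no ties, otherwise
#' asymptotic (the behaviour of [stats::ks.test()]).
#'
#' @param x,y Numeric samples (nonempty).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Donor-distance shift test for candidate accessory genes
#'
#' Compares the nearest-homolog 16S distance distribution of candidate
#' accessory genes against non-candidate accessory genes, per candidate
#' FDR tier: two-sample KS test, Wilcoxon rank-sum test, and the mean
#' difference (candidates minus non-candidates).  A positive shift says
#' candidates tend to trace to more phylogenetically distant donors,
#' consistent with horizontal acquisition.
#'
#' @param records Data frame with `distance_16S` and either `fdr_tier`
#'   (numeric; `Inf` or `NA` for non-candidates) or a logical
#'   `candidate_flag`.
#' @param tiers Percent FDR tiers to evaluate (a gene is a candidate at
#'   tier `t` when `fdr_tier <= t`).  Ignored when only `candidate_flag`
#'   is present (a single tier `"all"` is reported).
#' @return Data frame, one row per tier: `tier`, `n_candidate`,
#'   `n_noncandidate`, `mean_diff`, `ks_D`, `ks_p`, `wilcox_W`,
#'   `wilcox_p`.
#' @export
distance_shift_test <- function(records, tiers = c(1, 5, 10)) {
  stopifnot("distance_16S" %in% names(records))
  if ("fdr_tier" %in% names(records)) {
    tier_of <- records$fdr_tier
    tier_of[is.na(tier_of)] <- Inf
    noncand <- tier_of > max(tiers)
    tier_list <- tiers
    cand_sets <- lapply(tiers, function(t) tier_of <= t)
  } else if ("candidate_flag" %in% names(records)) {
    noncand <- !records$candidate_flag
    tier_list <- "all"
    cand_sets <- list(records$candidate_flag)
  } else {
    stop("records need `fdr_tier` or `candidate_flag`", call. = FALSE)
  }
  ref <- records$distance_16S[noncand]
  rows <- lapply(seq_along(tier_list), function(i) {
    cand <- records$distance_16S[cand_sets[[i]]]
    if (length(cand) < 2L || length(ref) < 2L) {
      stop("fewer than 2 records in a class at tier ", tier_list[i],
           call. = FALSE)
    }
    ks <- ks_two_sample(cand, ref)
    wt <- wilcoxon_rank_sum(cand, ref)
    data.frame(tier = tier_list[i], n_candidate = length(cand),
               n_noncandidate = length(ref),
               mean_diff = mean(cand) - mean(ref),
               ks_D = ks$D, ks_p = ks$p,
               wilcox_W = wt$W, wilcox_p = wt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
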