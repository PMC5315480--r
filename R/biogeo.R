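#' Pairwise SNP distance between strains
#'
#' Proportion of differing sites over the sites called (non-missing) in
#' both strains.
#'
#' @param snp Strains x sites genotype matrix coded 0/1 with `NA` for
#'   uncalled sites.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
snp_distance <- function(snp) {
  snp <- as.matrix(snp)
  n <- nrow(snp)
  D <- matrix(0, n, n, dimnames = list(rownames(snp), rownames(snp)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !is.na(snp[i, ]) & !is.na(snp[j, ])
      if (!any(ok)) {
        stop("strains ", rownames(snp)[i], " and ", rownames(snp)[j],
             " share no called sites", call. = FALSE)
      }
      D[i, j] <- D[j, i] <- mean(snp[i, ok] != snp[j, ok])
    }
  }
  D
}

#' Jaccard distance on accessory gene content
#'
#' `1 - |A intersect B| / |A union B|` on per-strain gene sets; two strains
#' with empty gene sets are assigned distance 0 by convention.
#'
#' @param pa Binary presence/absence matrix (pass the accessory columns).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
gene_content_distance <- function(pa) {
  .assert_binary_matrix(pa, "pa")
  inter <- tcrossprod(pa)
  sizes <- rowSums(pa)
  un <- outer(sizes, sizes, `+`) - inter
  D <- 1 - inter / un
  if (any(un == 0)) {
    message("strain pair(s) with empty gene sets assigned distance 0")
    D[un == 0] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(pa), rownames(pa))
  D
}

# Gower-centred inner-product matrix from a distance matrix.
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# Hat matrix of the column space of cbind(1, model matrix of the first
# `upto` factors).
.hat_matrix <- function(factors, upto) {
  n <- nrow(factors)
  X <- matrix(1, n, 1)
  if (upto > 0L) {
    for (j in seq_len(upto)) {
      X <- cbind(X, stats::model.matrix(~f, data.frame(f = factors[[j]]))[, -1,
                                                                          drop = FALSE])
    }
  }
  qrX <- qr(X)
  Qm <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  tcrossprod(Qm)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[r + seq_len(nrow(sub)), 1L] <- i
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

# Sequential (Type-I) sums of squares for each factor, McArdle-Anderson
# trace form.  Returns SS per factor, residual SS, total SS, df per factor.
.permanova_ss <- function(G, factors) {
  nf <- length(factors)
  hats <- lapply(0:nf, function(k) .hat_matrix(factors, k))
  tr_seq <- vapply(hats, function(H) sum(diag(H %*% G)), numeric(1))
  SS <- diff(tr_seq)
  total <- sum(diag(G))
  df <- vapply(seq_len(nf), function(j) {
    qr(cbind(1, stats::model.matrix(~f, data.frame(f = factors[[j]]))[, -1,
                                                                      drop = FALSE]))$rank - 1L
  }, integer(1))
  list(SS = SS, resid = total - tr_seq[nf + 1L], total = total, df = df)
}

#' Distance-based variance partitioning (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among
#' categorical factors with sequential (Type-I) entry, reporting per-factor
#' R-squared, pseudo-F and permutation p-values obtained by free
#' permutation of strain labels.  All `n!` permutations are enumerated when
#' `n! <= max_exact` (p is then exact); otherwise `n_perm` random
#' permutations are drawn and the observed statistic is included in the
#' reference set.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @param factors Data frame of factors, rows aligned with `D`; each must
#'   have at least 2 levels.
#' @param n_perm Number of random permutations when enumeration is not
#'   feasible.
#' @param seed Integer seed for the random permutations.
#' @param max_exact Enumeration threshold on `n!`.
#' @return List with `table` (data frame: `factor`, `df`, `SS`, `R2`,
#'   `pseudo_F`, `p`, `p_method`), `residual` row values, `total_SS`, `n`.
#' @export
permanova <- function(D, factors, n_perm = 999, seed = NULL,
                      max_exact = 10000) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(isSymmetric(unname(D)), all(abs(diag(D)) < 1e-12))
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  stopifnot(nrow(factors) == n)
  for (nm in names(factors)) {
    if (length(unique(factors[[nm]])) < 2L) {
      stop("factor `", nm, "` has fewer than 2 levels", call. = FALSE)
    }
  }
  G <- .gower_center(D)
  obs <- .permanova_ss(G, factors)
  nf <- length(factors)
  df_resid <- n - 1L - sum(obs$df)
  Fobs <- (obs$SS / obs$df) / (obs$resid / df_resid)

  exact <- factorial(n) <= max_exact
  if (exact) {
    perms <- .all_permutations(n)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  }
  count_ge <- numeric(nf)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    ssp <- .permanova_ss(G[p, p, drop = FALSE], factors)
    Fp <- (ssp$SS / ssp$df) / (ssp$resid / (n - 1L - sum(ssp$df)))
    count_ge <- count_ge + as.numeric(Fp >= Fobs - 1e-12)
  }
  pval <- if (exact) count_ge / nrow(perms) else (count_ge + 1) / (n_perm + 1)

  tab <- data.frame(
    factor = names(factors), df = obs$df, SS = obs$SS,
    R2 = obs$SS / obs$total, pseudo_F = Fobs, p = pval,
    p_method = if (exact) "exact" else "sampled",
    stringsAsFactors = FALSE)
  list(table = tab,
       residual = list(df = df_resid, SS = obs$resid,
                       R2 = obs$resid / obs$total),
       total_SS = obs$total, n = n,
       n_perm = nrow(perms), exact = exact)
}

#' Bootstrap confidence intervals for PERMANOVA R-squared
#'
#' Strains are resampled with replacement (duplicated strains have zero
#' mutual distance, which the distance submatrix provides automatically)
#' and the per-factor R-squared recomputed; percentile intervals are
#' returned.  Replicates in which a factor collapses to a single level are
#' discarded and counted.
#'
#' @param D Symmetric distance matrix.
#' @param factors Data frame of factors aligned with `D`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `ci` (data frame: `factor`, `estimate`, `lower`,
#'   `upper`), `n_discarded`, `n_used`.
#' @export
bootstrap_r2_ci <- function(D, factors, n_boot = 1000, seed = NULL,
                            conf = 0.95) {
  D <- as.matrix(D)
  n <- nrow(D)
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  point <- {
    G <- .gower_center(D)
    ss <- .permanova_ss(G, factors)
    ss$SS / ss$total
  }
  keep <- matrix(NA_real_, n_boot, length(factors))
  discarded <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    fb <- droplevels(as.data.frame(lapply(factors, function(f) factor(f)[idx])))
    if (any(vapply(fb, nlevels, integer(1)) < 2L)) {
      discarded <- discarded + 1L
      next
    }
    Gb <- .gower_center(D[idx, idx, drop = FALSE])
    ssb <- .permanova_ss(Gb, fb)
    keep[b, ] <- ssb$SS / ssb$total
  }
  used <- stats::complete.cases(keep)
  a <- (1 - conf) / 2
  qs <- apply(keep[used, , drop = FALSE], 2L, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  list(ci = data.frame(factor = names(factors), estimate = point,
                       lower = qs[1L, ], upper = qs[2L, ],
                       stringsAsFactors = FALSE),
       n_discarded = discarded, n_used = sum(used))
}
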