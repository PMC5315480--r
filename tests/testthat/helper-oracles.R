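# Independent oracles used by the property and acceptance tests.  These are
# deliberately written from first principles (enumeration / direct sweeps)
# and share no code with the package implementations they check.

# Exact two-sided Wilcoxon p by enumerating all C(n, n1) group labelings of
# the pooled values; two-sided p = min(1, 2 * min(lower tail, upper tail)).
oracle_wilcox_exact_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  n1 <- length(x)
  r <- rank(vals)
  combs <- utils::combn(n, n1)
  Ws <- colSums(matrix(r[combs], nrow = n1))
  wobs <- sum(r[seq_len(n1)])
  pl <- mean(Ws <= wobs + 1e-9)
  pg <- mean(Ws >= wobs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# Benjamini-Hochberg step-up from the definition:
# q_i = min over j with p_(j) >= p_i of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, m * ranked / seq_len(m))
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# NG86 per-codon quantities by explicit enumeration.
oracle_codon_syn_sites <- function(codon, gc) {
  bases <- c("A", "C", "G", "T")
  sp <- strsplit(codon, "")[[1]]
  if (gc[[codon]] == "*") return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, sp[pos])) {
      mut <- sp
      mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] != "*" && gc[[mc]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# Average (syn, nonsyn) difference counts over all orderings of the
# differing positions; pathways through stop codons excluded when possible.
oracle_codon_diffs <- function(c1, c2, gc) {
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  pos <- which(p1 != p2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, steps) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- steps
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- p2[p]
      walk(nxt, setdiff(remaining, p),
           c(steps, list(c(paste(cur, collapse = ""),
                           paste(nxt, collapse = "")))))
    }
  }
  walk(p1, pos, list())
  score <- vapply(paths, function(st) {
    sd <- 0; nd <- 0; blocked <- FALSE
    for (s in st) {
      a1 <- gc[[s[1]]]; a2 <- gc[[s[2]]]
      if (a1 == "*" || a2 == "*") blocked <- TRUE
      if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, as.numeric(blocked))
  }, numeric(3))
  ok <- score[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(score))
  c(sd = mean(score[1, ok]), nd = mean(score[2, ok]))
}

# KS statistic by a direct ECDF sweep over the pooled support.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

# Small default simulation configs used across tests.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_serpentine = 5, n_nonserpentine = 5, core_size = 40,
             accessory_pool = 120, snp_sites = 50,
             planted_clusters = list(cluster_spec(5, 5000)), seed = seed, ...)
}

power_config <- function(seed = 1, ...) {
  sim_config(accessory_pool = 300, core_size = 50, snp_sites = 10,
             planted_clusters = list(cluster_spec(13, 30000)),
             phenotype_effect = 0.28, phenotype_sd = 0.05, seed = seed, ...)
}
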