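# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Conventions (documented in the methods vignette):
#  * genetic code: bacterial/plastid table 11 by default;
#  * site counting: for each codon position the synonymous fraction is the
#    share of the three possible single-base changes that preserve the amino
#    acid; changes creating a stop codon count as nonsynonymous;
#  * multi-step codon differences: synonymous/nonsynonymous difference
#    counts are averaged over all shortest mutational pathways, excluding
#    pathways that pass through a stop codon (all pathways are used if every
#    one is blocked);
#  * distance correction: Jukes-Cantor, d = -(3/4) log(1 - (4/3) p),
#    undefined (NA, flagged) when p >= 3/4.

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function(code = "11") {
  key <- paste0("code", code)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  gc <- Biostrings::getGeneticCode(code)
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  aa <- gc
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (aa[[cd]] == "*") next  # stop codons carry no countable sites here
    s <- 0
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, sp[pos])) {
        mut <- sp; mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (aa[[mutc]] != "*" && aa[[mutc]] == aa[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }
  .codon_env[[key]] <- list(aa = aa, syn_sites = syn_sites, bases = bases)
  .codon_env[[key]]
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all shortest mutational pathways (k! orderings of the k differing
# positions), excluding pathways through stop codons when possible.
.codon_path_diffs <- function(c1, c2, tab) {
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- if (k == 1L) list(diff_pos) else {
    perms <- .permutations(diff_pos)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  }
  eval_path <- function(ord) {
    cur <- p1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- p2[pos]
      a1 <- tab$aa[[paste(cur, collapse = "")]]
      a2 <- tab$aa[[paste(nxt, collapse = "")]]
      if (a2 == "*" || a1 == "*") blocked <- TRUE
      if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(orders, eval_path, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", ok]), nd = mean(res["nd", ok]))
}

.permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

.split_codons <- function(seq) {
  seq <- toupper(seq)
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Counts fractional synonymous and nonsynonymous sites (averaged over the
#' two sequences), averages difference counts over all shortest mutational
#' pathways for multi-step codons, and applies the Jukes-Cantor correction
#' to the proportions of differences per site.
#'
#' @param seq_a,seq_b DNA strings of equal length, a multiple of 3, with no
#'   gaps, ambiguity characters or internal stop codons.
#' @param code Genetic code id for [Biostrings::getGeneticCode()]
#'   (default `"11"`, bacterial).
#' @return A `serpan_kaks` list: `Ka`, `Ks` (NA when the corrected distance
#'   is undefined), `ratio`, `pN`, `pS`, `n_sites_syn`, `n_sites_nonsyn`,
#'   `n_diff_syn`, `n_diff_nonsyn`, `flags`.
#' @export
ng86_ka_ks <- function(seq_a, seq_b, code = "11") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  if (nchar(seq_a) == 0L || nchar(seq_a) %% 3L != 0L) {
    stop("sequence length must be a nonzero multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b)) {
    stop("sequences contain gaps or ambiguity characters", call. = FALSE)
  }
  tab <- .codon_tables(code)
  ca <- .split_codons(seq_a); cb <- .split_codons(seq_b)
  aa_a <- unname(unlist(tab$aa[ca])); aa_b <- unname(unlist(tab$aa[cb]))
  n_codon <- length(ca)
  internal_stop <- c(which(aa_a == "*"), which(aa_b == "*"))
  internal_stop <- internal_stop[internal_stop < n_codon]
  if (length(internal_stop)) stop("internal stop codon", call. = FALSE)
  # trailing stop codons (if both end in one) are dropped from the counts
  if (aa_a[n_codon] == "*" || aa_b[n_codon] == "*") {
    if (!(aa_a[n_codon] == "*" && aa_b[n_codon] == "*")) {
      stop("internal stop codon", call. = FALSE)
    }
    ca <- ca[-n_codon]; cb <- cb[-n_codon]
    if (!length(ca)) stop("no codons left after removing stop", call. = FALSE)
  }

  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(a, b) .codon_path_diffs(a, b, tab), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])

  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  flags <- character(0)
  if (S <= 0) flags <- c(flags, "no_synonymous_sites")
  if (!is.na(pS) && pS >= 3 / 4) flags <- c(flags, "Ks_saturated")
  if (!is.na(pN) && pN >= 3 / 4) flags <- c(flags, "Ka_saturated")
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(ratio)) flags <- c(flags, "ratio_undefined")
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio, pN = pN, pS = pS,
                 n_sites_syn = S, n_sites_nonsyn = N,
                 n_diff_syn = Sd, n_diff_nonsyn = Nd, flags = flags),
            class = "serpan_kaks")
}

#' Ka/Ks table for a set of gene pairs
#'
#' Applies [ng86_ka_ks()] to each gene's pair of sequences, skipping genes
#' whose sequences violate the preconditions and recording the reason.
#'
#' @param pairs Named list; each element is a character vector of two
#'   sequences.
#' @param code Genetic code id.
#' @return Data frame (`gene_id`, `Ka`, `Ks`, `ratio`, `skipped`, `reason`).
#' @export
ka_ks_table <- function(pairs, code = "11") {
  rows <- lapply(names(pairs), function(g) {
    res <- tryCatch(ng86_ka_ks(pairs[[g]][1], pairs[[g]][2], code = code),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(gene_id = g, Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                 skipped = TRUE, reason = res, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g, Ka = res$Ka, Ks = res$Ks, ratio = res$ratio,
                 skipped = FALSE,
                 reason = paste(res$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Compare Ka/Ks between genome compartments
#'
#' Two-sided Wilcoxon rank-sum test on log10(Ka/Ks), accessory versus core.
#' By default genes with Ka = 0 or Ks = 0 (undefined or zero log ratio) are
#' excluded; a pseudocount can instead be added to both rates.
#'
#' @param core_results,accessory_results Data frames from [ka_ks_table()]
#'   (need columns `Ka`, `Ks`).
#' @param pseudocount Added to Ka and Ks before forming the ratio; 0 means
#'   exclude non-finite log ratios.
#' @return List with `W` (rank sum of the accessory group), `p`,
#'   `median_core`, `median_accessory`, `n_core`, `n_accessory`,
#'   `n_filtered`.
#' @export
compare_compartments <- function(core_results, accessory_results,
                                 pseudocount = 0) {
  lr <- function(df) {
    ka <- df$Ka + pseudocount; ks <- df$Ks + pseudocount
    v <- log10(ka / ks)
    v[is.finite(v)]
  }
  core <- lr(core_results); acc <- lr(accessory_results)
  n_filtered <- (nrow(core_results) - length(core)) +
    (nrow(accessory_results) - length(acc))
  if (length(core) < 2L || length(acc) < 2L) {
    stop("fewer than 2 finite log10 ratios in a compartment", call. = FALSE)
  }
  wt <- wilcoxon_rank_sum(acc, core)
  list(W = wt$W, p = wt$p,
       median_core = stats::median(core),
       median_accessory = stats::median(acc),
       n_core = length(core), n_accessory = length(acc),
       n_filtered = n_filtered)
}
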