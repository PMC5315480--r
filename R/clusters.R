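#' Call positional clusters of candidate genes on draft contigs
#'
#' A cluster is seeded by a run of at least `min_tandem` consecutive
#' candidate genes (consecutive in gene order on one contig; a
#' non-candidate gene breaks a seed run).  Each seed is then extended
#' outward, absorbing any further candidate gene whose proximal boundary
#' lies within `gap_bp` of the current cluster edge; intervening
#' non-candidates are allowed (they contribute to span, not membership).
#' Extension iterates to a fixed point and overlapping clusters are
#' merged.  The rule is symmetric in orientation: on the right the
#' candidate's start is compared with the cluster's right edge, on the
#' left its end with the left edge, so mirroring a contig mirrors the
#' clusters.
#'
#' @param map Contig gene map: data frame (`strain`, `contig`, `group_id`,
#'   `start`, `end`) sorted by start within each strain/contig, 1-based
#'   inclusive coordinates, no overlapping genes.
#' @param candidate_ids Gene (group) ids considered candidates.
#' @param min_tandem Minimum seed-run length.
#' @param gap_bp Maximum candidate-free extension gap in bp.
#' @return Data frame, one row per cluster: `strain`, `contig`, `start`,
#'   `end`, `span_bp`, `n_candidates`, and `members` (list column of
#'   candidate group ids in positional order).
#' @export
call_clusters <- function(map, candidate_ids, min_tandem = 4,
                          gap_bp = 10000) {
  req <- c("strain", "contig", "group_id", "start", "end")
  stopifnot(all(req %in% names(map)))
  out <- list()
  for (key in unique(paste(map$strain, map$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- map[map$strain == parts[1] & map$contig == parts[2], , drop = FALSE]
    if (is.unsorted(g$start, strictly = FALSE)) {
      stop("contig gene map is not sorted by start (", parts[1], " ",
           parts[2], ")", call. = FALSE)
    }
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)])) {
      stop("overlapping genes on ", parts[2], call. = FALSE)
    }
    cand <- g$group_id %in% candidate_ids
    if (sum(cand) < min_tandem) next

    # seed runs of consecutive candidates
    r <- rle(cand)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    seeds <- which(r$values & r$lengths >= min_tandem)
    if (!length(seeds)) next

    clusters <- lapply(seeds, function(k) run_start[k]:run_end[k])
    cand_idx <- which(cand)

    extend <- function(memb) {
      repeat {
        left <- min(g$start[memb]); right <- max(g$end[memb])
        outside <- setdiff(cand_idx, memb)
        if (!length(outside)) return(memb)
        near <- outside[
          (g$start[outside] >= left & g$end[outside] <= right) |         # inside
            (g$start[outside] > right & g$start[outside] - right <= gap_bp) |
            (g$end[outside] < left & left - g$end[outside] <= gap_bp)]
        if (!length(near)) return(memb)
        memb <- sort(unique(c(memb, near)))
      }
    }
    clusters <- lapply(clusters, extend)

    # merge clusters sharing members or overlapping spans
    if (length(clusters) > 1L) {
      repeat {
        merged <- FALSE
        for (i in seq_along(clusters)) {
          for (j in seq_along(clusters)) {
            if (j <= i) next
            si <- range(c(g$start[clusters[[i]]], g$end[clusters[[i]]]))
            sj <- range(c(g$start[clusters[[j]]], g$end[clusters[[j]]]))
            if (si[1] <= sj[2] && sj[1] <= si[2]) {
              clusters[[i]] <- sort(unique(c(clusters[[i]], clusters[[j]])))
              clusters[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
      clusters <- unique(clusters)
    }

    for (memb in clusters) {
      memb <- intersect(memb, cand_idx)
      out[[length(out) + 1L]] <- data.frame(
        strain = parts[1], contig = parts[2],
        start = min(g$start[memb]), end = max(g$end[memb]),
        span_bp = max(g$end[memb]) - min(g$start[memb]) + 1L,
        n_candidates = length(memb), stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(g$group_id[memb])
    }
  }
  if (!length(out)) {
    res <- data.frame(strain = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      span_bp = integer(0), n_candidates = integer(0))
    res$members <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Habitat assortment of a cluster across strains
#'
#' @param carriers Strain ids carrying the cluster.
#' @param strains All strain ids.
#' @param soil Soil labels aligned with `strains`
#'   (`"serpentine"`/`"nonserpentine"`).
#' @return List with carrier counts per soil and the flags `perfect`
#'   (carriers are exactly the serpentine strains) and `serpentine_only`
#'   (carriers are a subset of serpentine strains).
#' @export
soil_assortment <- function(carriers, strains, soil) {
  stopifnot(length(strains) == length(soil))
  serp <- strains[soil == "serpentine"]
  nons <- strains[soil == "nonserpentine"]
  n_s <- sum(carriers %in% serp)
  n_n <- sum(carriers %in% nons)
  list(n_serpentine = n_s, n_nonserpentine = n_n,
       n_serpentine_total = length(serp),
       n_nonserpentine_total = length(nons),
       perfect = setequal(carriers, serp) && length(serp) > 0L,
       serpentine_only = n_n == 0L && n_s > 0L)
}

# Longest common subsequence length of two character vectors.
.lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Match clusters across strains into families
#'
#' Single-linkage grouping of per-strain clusters whose candidate
#' membership Jaccard similarity reaches `min_jaccard`.  For each family,
#' gene-order conservation is the mean over strain pairs of the longest
#' common subsequence of member order divided by the shorter member list.
#'
#' @param clusters Output of [call_clusters()].
#' @param min_jaccard Minimum Jaccard similarity to link two clusters.
#' @return Data frame, one row per family: `family`, `n_clusters`,
#'   `strains` (list), `members` (list, union in stable order),
#'   `n_candidates`, `max_span_bp`, `order_conservation`.
#' @export
match_clusters_across_strains <- function(clusters, min_jaccard = 0.5) {
  n <- nrow(clusters)
  if (n == 0L) {
    res <- data.frame(family = character(0), n_clusters = integer(0),
                      n_candidates = integer(0), max_span_bp = integer(0),
                      order_conservation = numeric(0))
    res$strains <- list(); res$members <- list()
    return(res)
  }
  sets <- clusters$members
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      adj[i, j] <- adj[j, i] <- jac >= min_jaccard
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  fams <- sort(unique(comp))
  rows <- lapply(seq_along(fams), function(fi) {
    idx <- which(comp == fams[fi])
    union_members <- Reduce(union, sets[idx])
    oc <- if (length(idx) < 2L) 1 else {
      pairs <- utils::combn(idx, 2L)
      mean(apply(pairs, 2L, function(pr) {
        a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
        .lcs_length(a, b) / min(length(a), length(b))
      }))
    }
    d <- data.frame(
      family = sprintf("family%02d", fi), n_clusters = length(idx),
      n_candidates = length(union_members),
      max_span_bp = max(clusters$span_bp[idx]),
      order_conservation = oc, stringsAsFactors = FALSE)
    d$strains <- list(sort(unique(clusters$strain[idx])))
    d$members <- list(union_members)
    d
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize cluster families against association results
#'
#' @param families Output of [match_clusters_across_strains()].
#' @param results Annotated association table (for `bonferroni_sig`,
#'   `freq_S`, `freq_N`).
#' @param strains,soil Strain ids and soil labels (for assortment flags).
#' @return Data frame, one row per family, with candidate counts,
#'   Bonferroni counts, perfectly assorting member counts, span and
#'   carrier-soil assortment flags.
#' @export
cluster_summary <- function(families, results, strains, soil) {
  if (nrow(families) == 0L) {
    return(data.frame(family = character(0), n_strains = integer(0),
                      n_candidates = integer(0), n_bonferroni = integer(0),
                      n_perfect_assort = integer(0), max_span_bp = integer(0),
                      perfect = logical(0), serpentine_only = logical(0)))
  }
  bon <- results$variant_id[results$bonferroni_sig]
  perf <- results$variant_id[results$freq_S == 1 & results$freq_N == 0]
  rows <- lapply(seq_len(nrow(families)), function(i) {
    memb <- families$members[[i]]
    carriers <- families$strains[[i]]
    assort <- soil_assortment(carriers, strains, soil)
    data.frame(
      family = families$family[i], n_strains = length(carriers),
      n_candidates = length(memb),
      n_bonferroni = sum(memb %in% bon),
      n_perfect_assort = sum(memb %in% perf),
      max_span_bp = families$max_span_bp[i],
      order_conservation = families$order_conservation[i],
      perfect = assort$perfect, serpentine_only = assort$serpentine_only,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
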