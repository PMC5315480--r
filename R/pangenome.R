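#' Filter tabular homology hits
#'
#' Retains hits passing all three homology thresholds with strict
#' inequalities: overlap (alignment length over query length) above
#' `min_overlap`, E-value below `max_evalue`, and percent identity above
#' `min_identity`.  The defaults mirror the usual BLASTX gene-calling
#' thresholds for draft bacterial genomes (>80% overlap, E < 1e-20,
#' identity > 50%).
#'
#' @param hits Data frame with at least `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `query_length`, `evalue`,
#'   `bitscore`.
#' @param min_overlap Minimum fractional overlap (exclusive).
#' @param max_evalue Maximum E-value (exclusive).
#' @param min_identity Minimum percent identity (exclusive).
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, min_overlap = 0.80, max_evalue = 1e-20,
                        min_identity = 50) {
  req <- c("query_id", "subject_id", "percent_identity", "alignment_length",
           "query_length", "evalue", "bitscore")
  miss <- setdiff(req, names(hits))
  if (length(miss)) {
    stop("hit table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(hits) == 0L) return(hits)
  bad <- which(is.na(hits$query_length) | hits$query_length <= 0)
  if (length(bad)) {
    stop("missing or invalid query_length at record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  overlap <- hits$alignment_length / hits$query_length
  keep <- overlap > min_overlap & hits$evalue < max_evalue &
    hits$percent_identity > min_identity
  hits[keep, , drop = FALSE]
}

# Best hit per query: max bitscore, ties by min evalue, then lexicographic
# minimum subject id.  Returns per-query best subject plus an ambiguity flag
# (a tie that had to be broken lexicographically).
.best_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  best <- h[first, , drop = FALSE]
  # ambiguous: the runner-up ties on both bitscore and evalue
  idx_first <- which(first)
  idx_second <- idx_first + 1L
  amb <- idx_second <= nrow(h) &
    h$query_id[pmin(idx_second, nrow(h))] == best$query_id &
    h$bitscore[pmin(idx_second, nrow(h))] == best$bitscore &
    h$evalue[pmin(idx_second, nrow(h))] == best$evalue
  data.frame(query_id = best$query_id, subject_id = best$subject_id,
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' Reciprocal best hits between two strains
#'
#' A pair `(a, b)` is reported when `b` is `a`'s best hit in the forward
#' table and `a` is `b`'s best hit in the reverse table.  Best = maximum
#' bitscore, ties broken by minimum E-value and then lexicographically
#' smallest subject id; lexicographic breaks are flagged ambiguous.
#'
#' @param hits_ab,hits_ba Filtered hit tables in the two directions.
#' @return Data frame (`gene_a`, `gene_b`, `ambiguous`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  fa <- .best_hits(hits_ab)
  fb <- .best_hits(hits_ba)
  fwd <- setNames(fa$subject_id, fa$query_id)
  rev <- setNames(fb$subject_id, fb$query_id)
  keep <- !is.na(rev[fa$subject_id]) & rev[fa$subject_id] == fa$query_id
  keep[is.na(keep)] <- FALSE
  amb_b <- setNames(fb$ambiguous, fb$query_id)
  data.frame(gene_a = fa$query_id[keep], gene_b = fa$subject_id[keep],
             ambiguous = fa$ambiguous[keep] |
               unname(amb_b[fa$subject_id[keep]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pool reciprocal best hits over all strain pairs
#'
#' Applies [filter_hits()] and [reciprocal_best_hits()] to every unordered
#' strain pair present in both directions of a pairwise hit-table list.
#'
#' @param pairwise Named list of hit tables, names `"A->B"`.
#' @param ... Passed to [filter_hits()].
#' @return Data frame of pooled RBH pairs (`gene_a`, `gene_b`,
#'   `ambiguous`).
#' @export
rbh_from_pairwise <- function(pairwise, ...) {
  nm <- names(pairwise)
  ab <- do.call(rbind, strsplit(nm, "->", fixed = TRUE))
  done <- character(0)
  out <- list()
  for (k in seq_along(nm)) {
    a <- ab[k, 1]; b <- ab[k, 2]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% done) next
    rev_nm <- paste0(b, "->", a)
    if (!rev_nm %in% nm) next
    done <- c(done, key)
    out[[key]] <- reciprocal_best_hits(
      filter_hits(pairwise[[k]], ...),
      filter_hits(pairwise[[rev_nm]], ...))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build ortholog groups from reference hits and RBH pairs
#'
#' Genes whose (filtered) best reference hit is the same reference protein
#' share that protein's group; the remaining genes are grouped by
#' single-linkage closure over reciprocal-best-hit pairs.  RBH edges
#' touching a reference-assigned gene are dropped (reference assignment
#' wins, with a message).  Within a group, extra same-strain members
#' (in-paralogs) are split off into singleton groups, keeping the member
#' with the highest supporting bitscore.
#'
#' @param rbh_pairs Data frame (`gene_a`, `gene_b`) pooled over strain
#'   pairs, e.g. from [reciprocal_best_hits()].
#' @param reference_hits Filtered hit table of genes against the reference
#'   proteome (best hit per gene is used), or `NULL`.
#' @param gene_strains Named character vector mapping every gene id to its
#'   strain.
#' @return Data frame (`gene_id`, `strain`, `group_id`, `origin`).
#' @export
build_ortholog_groups <- function(rbh_pairs, reference_hits, gene_strains) {
  stopifnot(!is.null(names(gene_strains)))
  all_genes <- names(gene_strains)
  group <- setNames(rep(NA_character_, length(all_genes)), all_genes)
  support <- setNames(rep(0, length(all_genes)), all_genes)

  if (!is.null(reference_hits) && nrow(reference_hits) > 0L) {
    best <- .best_hits(reference_hits)
    bs <- reference_hits[order(reference_hits$query_id,
                               -reference_hits$bitscore), ]
    bs <- bs[!duplicated(bs$query_id), ]
    group[best$query_id] <- best$subject_id
    support[bs$query_id] <- bs$bitscore
  }
  ref_assigned <- names(group)[!is.na(group)]

  if (!is.null(rbh_pairs) && nrow(rbh_pairs) > 0L) {
    drop <- rbh_pairs$gene_a %in% ref_assigned |
      rbh_pairs$gene_b %in% ref_assigned
    if (any(drop)) {
      message(sum(drop),
              " RBH edge(s) touched reference-assigned genes; reference wins")
    }
    edges <- rbh_pairs[!drop, c("gene_a", "gene_b"), drop = FALSE]
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0))
  }

  denovo_genes <- setdiff(all_genes, ref_assigned)
  if (length(denovo_genes)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = denovo_genes, stringsAsFactors = FALSE))
    comp <- igraph::components(g)$membership
    # deterministic group ids: ordered by lexicographic minimum member
    min_member <- tapply(names(comp), comp, min)
    rank_id <- rank(min_member, ties.method = "first")
    ids <- sprintf("denovo%05d", rank_id[as.character(comp)])
    group[names(comp)] <- ids
  }

  out <- data.frame(
    gene_id = all_genes, strain = unname(gene_strains[all_genes]),
    group_id = unname(group[all_genes]),
    origin = ifelse(all_genes %in% ref_assigned, "reference", "de-novo"),
    stringsAsFactors = FALSE
  )

  # one gene per strain per group: keep best-supported, split the rest
  key <- paste(out$group_id, out$strain)
  if (anyDuplicated(key)) {
    o <- order(key, -support[out$gene_id], out$gene_id)
    dup <- o[duplicated(key[o])]
    message(length(dup), " in-paralog(s) split into singleton groups")
    out$group_id[dup] <- paste0("paralog_", out$gene_id[dup])
  }
  out
}

#' Presence/absence matrix from ortholog group assignments
#'
#' @param groups Data frame from [build_ortholog_groups()].
#' @param strains Strain order for the rows; defaults to sorted unique
#'   strains in `groups`.
#' @return Binary strains x groups integer matrix (no all-zero columns by
#'   construction).
#' @export
presence_absence_matrix <- function(groups, strains = NULL) {
  if (is.null(strains)) strains <- sort(unique(groups$strain))
  gids <- sort(unique(groups$group_id))
  m <- matrix(0L, length(strains), length(gids),
              dimnames = list(strains, gids))
  m[cbind(match(groups$strain, strains), match(groups$group_id, gids))] <- 1L
  m
}

#' Partition a pan-genome into core and accessory genes
#'
#' Relative to a strain subset: core genes are present in every subset
#' strain, accessory genes are present in at least one and absent from at
#' least one; genes absent from the whole subset fall outside its
#' pan-genome and are reported separately.
#'
#' @param pa Binary presence/absence matrix.
#' @param strain_subset Strains defining the subset; defaults to all rows.
#' @return List with `core`, `accessory`, `absent` (character vectors of
#'   gene ids).
#' @export
partition_core_accessory <- function(pa, strain_subset = rownames(pa)) {
  .assert_binary_matrix(pa, "pa")
  if (length(strain_subset) == 0L) stop("empty strain subset", call. = FALSE)
  if (!all(strain_subset %in% rownames(pa))) {
    stop("strain_subset contains strains absent from the matrix", call. = FALSE)
  }
  sub <- pa[strain_subset, , drop = FALSE]
  cs <- colSums(sub)
  if (all(cs == 0L)) {
    stop("empty pan-genome: no gene is present in the given subset",
         call. = FALSE)
  }
  list(core = colnames(sub)[cs == length(strain_subset)],
       accessory = colnames(sub)[cs > 0L & cs < length(strain_subset)],
       absent = colnames(sub)[cs == 0L])
}

#' Pan- and core-genome sizes for named strain subsets
#'
#' @param pa Binary presence/absence matrix.
#' @param subsets Named list of strain-id vectors.
#' @return Data frame (`subset`, `n_strains`, `pan`, `core`).
#' @export
pan_core_counts <- function(pa, subsets) {
  stopifnot(is.list(subsets), length(names(subsets)) == length(subsets))
  rows <- lapply(names(subsets), function(nm) {
    part <- partition_core_accessory(pa, subsets[[nm]])
    data.frame(subset = nm, n_strains = length(subsets[[nm]]),
               pan = length(part$core) + length(part$accessory),
               core = length(part$core), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene frequency spectrum
#'
#' Histogram of per-gene occupancy (number of strains carrying each gene).
#'
#' @param pa Binary presence/absence matrix.
#' @return Named integer vector of counts over occupancy classes `1..S`.
#' @export
gene_frequency_spectrum <- function(pa) {
  .assert_binary_matrix(pa, "pa")
  occ <- colSums(pa)
  tab <- tabulate(occ, nbins = nrow(pa))
  names(tab) <- seq_len(nrow(pa))
  tab
}

#' Call SNP sites from a core-gene multiple alignment
#'
#' Scans alignment columns over a strain subset and reports those with two
#' or more distinct bases.  Columns containing a gap or ambiguity character
#' in any subset row are skipped entirely (complete-column deletion keeps
#' one consistent site set across strains); the number skipped is attached
#' as attribute `n_skipped`.
#'
#' @param aln Alignment: a character matrix (strains x positions), a named
#'   character vector of equal-length sequences, a `Biostrings::DNAStringSet`,
#'   or a path to an aligned FASTA file.
#' @param strain_subset Row names to restrict to; defaults to all.
#' @param gene_id Label recorded in the output.
#' @return Data frame (`gene_id`, `alignment_column`, `n_alleles`,
#'   `biallelic`) with the per-strain allele matrix attached as attribute
#'   `alleles` (strains x sites).
#' @export
call_snps_from_alignment <- function(aln, strain_subset = NULL,
                                     gene_id = "gene") {
  m <- .alignment_matrix(aln)
  if (is.null(strain_subset)) strain_subset <- rownames(m)
  miss <- setdiff(strain_subset, rownames(m))
  if (length(miss)) {
    stop("strains missing from alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- toupper(m[strain_subset, , drop = FALSE])
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  col_ok <- colSums(valid) == nrow(m)
  n_all <- apply(m, 2L, function(col) length(unique(col)))
  is_site <- col_ok & n_all >= 2L
  out <- data.frame(
    gene_id = gene_id,
    alignment_column = which(is_site),
    n_alleles = n_all[is_site],
    biallelic = n_all[is_site] == 2L,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "alleles") <- m[, is_site, drop = FALSE]
  attr(out, "n_skipped") <- sum(!col_ok)
  out
}

# Coerce the accepted alignment representations to a character matrix with
# strain rownames; errors on ragged rows.
.alignment_matrix <- function(aln) {
  if (is.character(aln) && length(aln) == 1L && file.exists(aln)) {
    aln <- Biostrings::readDNAStringSet(aln)
  }
  if (inherits(aln, "XStringSet")) {
    if (length(unique(Biostrings::width(aln))) != 1L) {
      stop("alignment rows have unequal lengths", call. = FALSE)
    }
    m <- as.matrix(aln)
    return(m)
  }
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop("alignment matrix needs rownames")
    return(aln)
  }
  if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L) {
      stop("alignment rows have unequal lengths", call. = FALSE)
    }
    if (is.null(names(aln))) stop("alignment sequences need names")
    return(matrix(unlist(strsplit(aln, "")), nrow = length(aln), byrow = TRUE,
                  dimnames = list(names(aln), NULL)))
  }
  stop("unsupported alignment representation", call. = FALSE)
}

#' Encode biallelic SNP sites as a 0/1 genotype matrix
#'
#' Multi-allelic sites are dropped.  At each site the major allele is coded
#' 0 and the minor allele 1 (frequency ties broken alphabetically).
#'
#' @param sites Output of [call_snps_from_alignment()] (one gene) or a list
#'   of such outputs.
#' @return Binary strains x sites matrix with `gene:column` column names.
#' @export
snp_genotype_matrix <- function(sites) {
  if (is.data.frame(sites)) sites <- list(sites)
  mats <- lapply(sites, function(s) {
    al <- attr(s, "alleles")
    keep <- which(s$biallelic)
    if (!length(keep)) return(NULL)
    cols <- vapply(keep, function(k) {
      col <- al[, k]
      tab <- sort(table(col), decreasing = TRUE)
      major <- names(tab)[order(-tab, names(tab))][1L]
      as.integer(col != major)
    }, integer(nrow(al)))
    colnames(cols) <- paste0(s$gene_id[keep], ":", s$alignment_column[keep])
    rownames(cols) <- rownames(al)
    cols
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) stop("no biallelic sites", call. = FALSE)
  do.call(cbind, mats)
}
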