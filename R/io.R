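# Readers and writers for the plain-text exchange formats the pipeline
# uses: TSV matrices and tables, minimal GFF3, aligned FASTA, truth JSON,
# NEXUS distance blocks, and a VCF-like SNP export.

.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Write / read a binary presence-absence matrix as TSV
#'
#' Strains in rows (first column `strain`), ortholog groups in columns.
#' @param pa Binary matrix.
#' @param path File path.
#' @return `path` (writer) or an integer matrix (reader).
#' @export
write_presence_absence <- function(pa, path) {
  df <- data.frame(strain = rownames(pa), pa, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_presence_absence
#' @export
read_presence_absence <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$strain
  m
}

#' Write / read a phenotype table as TSV
#' @param phenotypes Data frame with `strain`, `growth_highNi`,
#'   `growth_lowNi`, `soil`, `reserve`.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) .write_tsv(phenotypes, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an admixture Q-matrix as TSV
#' @param Q Numeric matrix (strains x subgroups), strain rownames.
#' @param path File path.
#' @export
write_qmatrix <- function(Q, path) {
  .write_tsv(data.frame(strain = rownames(Q), Q, check.names = FALSE), path)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$strain
  m
}

#' Write / read a nearest-homolog 16S distance table as TSV
#' @param homolog Data frame from [simulate_homolog_distances()] or of the
#'   same shape.
#' @param path File path.
#' @export
write_homolog_distances <- function(homolog, path) .write_tsv(homolog, path)

#' @rdname write_homolog_distances
#' @export
read_homolog_distances <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-strain contig layouts as GFF3
#'
#' One GFF3 file per strain under `dir`, gene features only, with
#' `ID=<group_id>` attributes; 1-based inclusive coordinates.
#'
#' @param layouts Data frame (`strain`, `contig`, `group_id`, `start`,
#'   `end`, `strand`).
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_gff3 <- function(layouts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strains <- unique(layouts$strain)
  paths <- setNames(file.path(dir, paste0(strains, ".gff3")), strains)
  for (s in strains) {
    g <- layouts[layouts$strain == s, , drop = FALSE]
    lines <- c("##gff-version 3",
               sprintf("%s\tserpan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start, g$end, g$strand, g$group_id))
    writeLines(lines, paths[[s]])
  }
  paths
}

#' Read gene features from a GFF3 file into a contig gene map
#'
#' Minimal reader for the layouts written by [write_gff3()]: keeps `gene`
#' features, takes the `ID` attribute as the group id.
#'
#' @param path GFF3 file path.
#' @param strain Strain label to attach.
#' @return Data frame (`strain`, `contig`, `group_id`, `start`, `end`,
#'   `strand`) sorted by contig and start.
#' @export
read_gff3 <- function(path, strain) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9L]
  typ <- vapply(f, `[[`, "", 3L)
  f <- f[typ == "gene"]
  id <- sub("^.*ID=([^;]+).*$", "\\1", vapply(f, `[[`, "", 9L))
  out <- data.frame(
    strain = strain,
    contig = vapply(f, `[[`, "", 1L),
    group_id = id,
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    stringsAsFactors = FALSE)
  out[order(out$contig, out$start), ]
}

#' Write alignments as aligned FASTA files
#'
#' @param alignments Named list of character matrices (strains x columns),
#'   e.g. from [simulate_core_alignments()].
#' @param dir Output directory.
#' @return Vector of file paths.
#' @export
write_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(alignments)) {
    m <- alignments[[g]]
    seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
    p <- file.path(dir, paste0(g, ".aln.fasta"))
    Biostrings::writeXStringSet(seqs, p)
    paths <- c(paths, p)
  }
  paths
}

#' Export a SNP matrix as a minimal VCF-like table
#'
#' `CHROM` is the anchoring gene, `POS` the within-gene position parsed
#' from the `gene:pos` column names; genotypes are the 0/1 codes.
#'
#' @param snp Strains x sites 0/1 matrix with `gene:pos` column names.
#' @param path Output path.
#' @export
write_snp_vcf <- function(snp, path) {
  gene <- sub(":.*$", "", colnames(snp))
  pos <- sub("^.*:", "", colnames(snp))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=serpan",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(snp)), collapse = "\t"))
  body <- vapply(seq_len(ncol(snp)), function(j) {
    paste(c(gene[j], pos[j], colnames(snp)[j], "A", "G", ".", "PASS", ".",
            "GT", as.character(snp[, j])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a distance matrix as a NEXUS Distances block
#'
#' For use with phylogenetic-network tools that consume NEXUS distance
#' input.
#'
#' @param D Symmetric distance matrix with strain dimnames.
#' @param path Output path.
#' @export
write_nexus_distances <- function(D, path) {
  D <- as.matrix(D)
  n <- nrow(D)
  taxa <- rownames(D)
  lines <- c(
    "#NEXUS",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "TAXLABELS",
    sprintf("  [%d] '%s'", seq_len(n), taxa),
    ";",
    "END;",
    "BEGIN Distances;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "FORMAT labels=left diagonal triangle=both;",
    "MATRIX")
  for (i in seq_len(n)) {
    lines <- c(lines, paste0("  '", taxa[i], "' ",
                             paste(formatC(D[i, ], format = "g", digits = 8),
                                   collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Write a full synthetic population to a directory
#'
#' Emits the standard exchange files: presence/absence TSV, phenotype TSV,
#' Q-matrix TSV, per-strain GFF3 layouts, homolog-distance TSV, SNP matrix
#' TSV and a truth JSON.
#'
#' @param pop A `serpan_population`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_presence_absence(pop$pa, file.path(dir, "presence_absence.tsv"))
  write_phenotypes(pop$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_qmatrix(pop$Q, file.path(dir, "qmatrix.tsv"))
  write_homolog_distances(pop$homolog, file.path(dir, "homolog_distances.tsv"))
  .write_tsv(data.frame(strain = rownames(pop$snp), pop$snp,
                        check.names = FALSE),
             file.path(dir, "snp_matrix.tsv"))
  write_gff3(pop$layouts, file.path(dir, "gff3"))
  truth <- pop$truth
  truth$pa_truth <- NULL  # matrix lives in its own TSV
  truth$cluster_specs <- lapply(truth$cluster_specs, unclass)
  write_presence_absence(pop$truth$pa_truth,
                         file.path(dir, "presence_absence_truth.tsv"))
  truth$strain_subgroup_loadings <-
    as.data.frame(truth$strain_subgroup_loadings)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
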