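#!/usr/bin/env Rscript
# Positional clustering of association candidates on draft contigs: seed
# runs of >= 4 tandem candidates, 10-kb gap extension, cross-strain family
# matching, and habitat-assortment summaries.

suppressPackageStartupMessages(library(serpan))
dir.create("results/clusters", showWarnings = FALSE, recursive = TRUE)

cand <- readLines("results/association/candidates_fdr10.txt")
ph <- read_phenotypes("results/sim/phenotypes.tsv")
genes <- read.delim("results/association/genes_highNi.tsv")

gff <- list.files("results/sim/gff3", "\\.gff3$", full.names = TRUE)
lay <- do.call(rbind, lapply(gff, function(f) {
  read_gff3(f, sub("\\.gff3$", "", basename(f)))
}))

cl <- call_clusters(lay, cand, min_tandem = 4, gap_bp = 10000)
fam <- match_clusters_across_strains(cl)
summ <- cluster_summary(fam, genes, ph$strain, ph$soil)
summ <- summ[order(-summ$n_candidates), ]
print(summ, row.names = FALSE)

cat(sprintf("%d per-strain clusters collapse into %d families; %d families carry >= 10 candidates\n",
            nrow(cl), nrow(fam), sum(summ$n_candidates >= 10)))
big <- summ[1, ]
cat(sprintf("largest family: %d candidates over <= %.1f kbp, %d perfectly assorting, perfect assortment: %s\n",
            big$n_candidates, big$max_span_bp / 1000, big$n_perfect_assort,
            big$perfect))

flat <- cl
flat$members <- vapply(cl$members, paste, "", collapse = ",")
write.table(flat, "results/clusters/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ, "results/clusters/families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# BED export of cluster spans (0-based half-open)
bed <- data.frame(chrom = cl$contig, start = cl$start - 1L, end = cl$end,
                  name = sprintf("%s_cluster%02d", cl$strain, seq_len(nrow(cl))))
write.table(bed, "results/clusters/cluster_spans.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
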