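#!/usr/bin/env Rscript
# Structure-corrected association mapping of accessory gene content and
# core-genome SNPs against growth in high-nickel medium, with the low-nickel
# phenotype as the negative control.  Writes Table-1-style candidate tables
# under results/association/.

suppressPackageStartupMessages(library(serpan))
seed <- as.integer(Sys.getenv("SERPAN_SEED", "1"))
dir.create("results/association", showWarnings = FALSE, recursive = TRUE)

pa <- read_presence_absence("results/sim/presence_absence.tsv")
snp <- read_presence_absence("results/sim/snp_matrix.tsv")
ph <- read_phenotypes("results/sim/phenotypes.tsv")
Q <- read_qmatrix("results/sim/qmatrix.tsv")

pa <- pa[ph$strain, ]; snp <- snp[ph$strain, ]; Q <- Q[ph$strain, ]
part <- partition_core_accessory(pa)
acc <- pa[, part$accessory, drop = FALSE]

resid_hi <- regress_out_structure(ph$growth_highNi, Q)
genes <- annotate_association(gene_content_association(acc, resid_hi), acc,
                              ph$growth_highNi, ph$soil)
snps <- annotate_association(snp_association(snp, resid_hi), snp,
                             ph$growth_highNi, ph$soil)
resid_lo <- regress_out_structure(ph$growth_lowNi, Q)
genes_lo <- annotate_association(gene_content_association(acc, resid_lo),
                                 acc, ph$growth_lowNi, ph$soil)

sets <- significant_set(genes, 0.10)
sets_snp <- significant_set(snps, 0.10)
sets_lo <- significant_set(genes_lo, 0.20)

cat(sprintf("accessory genes: %d candidates at 10%% FDR, %d after Bonferroni\n",
            sets$n_fdr, sets$n_bonferroni))
cat(sprintf("core SNPs: %d candidates at 10%% FDR\n", sets_snp$n_fdr))
cat(sprintf("low-nickel control: %d candidates even at 20%% FDR\n",
            sets_lo$n_fdr))

top <- head(genes[genes$q < 0.10,
                  c("variant_id", "q", "effect", "freq_S", "freq_N")], 15)
top$q <- signif(top$q, 3); top$effect <- round(top$effect, 2)
print(top, row.names = FALSE)

write.table(genes, "results/association/genes_highNi.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(snps, "results/association/snps_highNi.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sets$fdr, "results/association/candidates_fdr10.txt")
writeLines(sets$bonferroni, "results/association/candidates_bonferroni.txt")
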