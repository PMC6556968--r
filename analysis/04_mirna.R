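#!/usr/bin/env Rscript

# Stage 4: miRNA regulation axis.
#
# Aggregates miRNA targets across three sources ((miRanda ∩ miRDB) ∪
# miRtarBase), filters multi-hit targets, scores the miR-17-92 cluster as
# its member mean, compares the score between TERT groups, and relates the
# cluster to its mRNA targets (PC1 correlation) and to the tumor/normal
# telomere-length ratio. Writes results under results/mirna/.

suppressPackageStartupMessages(library(telomark))

clinical <- read.delim("results/cohort/clinical.tsv")
mirna <- read_layer_tsv("results/cohort/mirna.tsv")
mrna <- read_layer_tsv("results/cohort/mrna.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
dir.create("results/mirna", showWarnings = FALSE, recursive = TRUE)

grp <- assign_tert_groups(setNames(clinical$tert_reads, clinical$sample),
                          clinical$alt)
z <- as.integer(grp$label == "high")

# target tables: the planted cluster-target couplings, distributed across
# the three sources the way curated databases overlap (synthetic stand-ins
# derived from the generator's truth)
cluster <- unlist(truth$mirna_cluster)
targets <- unlist(truth$mirna_targets)
mk_tab <- function(mirnas, genes) {
  data.frame(mirna = rep(mirnas, each = length(genes)),
             gene = rep(genes, length(mirnas)))
}
half1 <- targets[seq(1, length(targets), 2)]
half2 <- targets[seq(2, length(targets), 2)]
tab_miranda <- mk_tab(cluster, c(half1, half2))
tab_mirdb <- mk_tab(cluster, half1)              # intersection = half1
tab_mirtarbase <- mk_tab(cluster[1:2], half2[1:3])
tmap <- aggregate_targets(tab_mirtarbase, tab_miranda, tab_mirdb)
multi <- filter_multi_hit_targets(tmap, "up")
cat("aggregated targets per cluster miRNA:",
    paste(vapply(tmap, length, integer(1)), collapse = ","), "\n")
cat("multi-hit (>= 2 miRNAs) targets:", length(multi), "\n")

cl <- mirna_cluster_score(mirna)
test <- group_score_test(cl$score, z)
cat(sprintf("miR-17-92 score: mean %.2f (high) vs %.2f (low), Wilcoxon p = %.2g\n",
            mean(cl$score[z == 1]), mean(cl$score[z == 0]), test$p))

pc <- pc1_correlation(mirna[cluster, ], mrna[targets, ])
cat(sprintf("PC1(cluster) vs PC1(targets): r = %.2f (p = %.2g)\n",
            pc$r, pc$p))

tl <- telomere_ratio_correlation(cl$score, clinical$tl_ratio)
cat(sprintf("cluster score vs telomere-length ratio: r = %.2f (p = %.2g)\n",
            tl$r, tl$p))

write.table(data.frame(sample = clinical$sample, score = cl$score,
                       group = ifelse(z == 1, "high", "low"),
                       tl_ratio = clinical$tl_ratio),
            "results/mirna/cluster_score.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
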