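#!/usr/bin/env Rscript

# Stage 3: weighted co-expression network.
#
# Builds the unsigned network on the expression-filtered mRNA layer,
# detects modules on the topological overlap, summarizes them by
# eigengenes, computes intramodular connectivity and hubs, tests module
# preservation against a replicate cohort, and relates connectivity in the
# activity-linked module to the telomerase activity score. Writes module
# tables under results/network/.

suppressPackageStartupMessages(library(telomark))

clinical <- read.delim("results/cohort/clinical.tsv")
mrna <- read_layer_tsv("results/cohort/mrna.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

grp <- assign_tert_groups(setNames(clinical$tert_reads, clinical$sample),
                          clinical$alt)
z <- as.integer(grp$label == "high")
expr <- mrna[filter_expressed_mrna(mrna, z), ]

beta <- tryCatch(pick_soft_power(expr, 1:10),
                 warning = function(w) {
                   cat("note:", conditionMessage(w), "\n"); 6
                 })
cat("soft power:", as.numeric(beta), "\n")
adj <- adjacency_matrix(expr, as.numeric(beta))
tom <- topological_overlap(adj)
labels <- detect_modules(tom, min_module_size = 30, expr = expr)
cat("modules detected:", max(labels), " (", sum(labels == 0),
    "genes unassigned )\n")

merged <- merge_modules(expr, labels)
labels <- merged$labels
me <- merged$eigengenes
conn <- intramodular_connectivity(adj, labels)
k_me <- kme(expr, me)
write.table(cbind(conn, round(k_me[conn$gene, , drop = FALSE], 4)),
            "results/network/modules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_layer_tsv(me, "results/network/eigengenes.tsv")
cat("hub genes per module:\n")
print(table(conn$module[conn$hub]))

# preservation against an independent replicate of the same design
rep_coh <- generate_cohort(cohort_config(seed = 542))
pres <- module_preservation_z(expr, rep_coh$layers$mrna[rownames(expr), ],
                              labels, n_perm = 200, seed = 3)
write.table(pres, "results/network/preservation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("module preservation in a replicate cohort:\n")
print(pres, digits = 3)

# connectivity vs telomerase activity in the activity-linked module
act <- telomerase_activity_score(mrna, unlist(truth$signature_genes))
mod_lab <- unlist(truth$module_labels)
mod1 <- intersect(names(mod_lab)[mod_lab == 1], rownames(expr))
adj1 <- adjacency_matrix(mrna[mod1, ], as.numeric(beta))
conn1 <- intramodular_connectivity(adj1, rep(1, length(mod1)))
per_gene_r <- apply(mrna[mod1, ], 1, cor, y = act)
ca <- connectivity_activity_correlation(conn1$K, per_gene_r)
cat(sprintf("intramodular K vs activity correlation: R = %.2f (p = %.2g)\n",
            ca$r, ca$p))
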