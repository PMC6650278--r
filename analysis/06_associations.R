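#!/usr/bin/env Rscript
# Differential abundance and the cross-measurement-type association network:
# per-feature random-intercept mixed models with the nested
# diagnosis/dysbiosis design, residualization (with and without the
# dysbiosis covariate), and all-against-all Spearman networks on 2-week
# matched residuals with per-pair BH tiers, top-300 truncation, and hub
# annotation.

suppressPackageStartupMessages(library(dysbiome))

cohort_dir <- "results/cohort"
out <- "results/associations"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

taxa <- read_profile_tsv(file.path(cohort_dir, "taxa_profiles.tsv"), "MGX-taxa")
coupled <- read_profile_tsv(file.path(cohort_dir, "coupled_profiles.tsv"), "MBX")
md <- validate_metadata(read.csv(file.path(cohort_dir, "metadata.csv")))
md_c <- validate_metadata(read.csv(file.path(cohort_dir, "metadata_coupled.csv")))
scores <- read.delim("results/dysbiosis/scores.tsv")
md$dysbiotic <- scores$dysbiotic[match(md$sample_id, scores$sample_id)]
md_c$dysbiotic <- scores$dysbiotic[match(md_c$sample_id, scores$sample_id)]
planted <- readLines(file.path(cohort_dir, "responsive_taxa.txt"))

tab <- prevalence_variance_filter(taxa)
da <- differential_abundance(tab, md)
write.table(da, file.path(out, "differential_abundance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
dys_terms <- grep(":dysbioticTRUE", unique(da$term), value = TRUE)
sub <- da[da$term %in% dys_terms, ]
minq <- tapply(sub$q, sub$feature, min)
hits <- names(minq)[minq < 0.05]
message(sprintf("differential abundance: %d/%d features dysbiosis-associated at q<0.05",
                length(hits), nrow(tab)))
message(sprintf("  planted taxa recovered: %d/%d",
                sum(planted %in% hits), length(planted)))

res_taxa_adj <- residualize(tab, md)
res_coup_adj <- residualize(prevalence_variance_filter(coupled), md_c,
                            transform = "log1p")
res_taxa_un <- residualize(tab, md, adjust_for_dysbiosis = FALSE)
res_coup_un <- residualize(prevalence_variance_filter(coupled), md_c,
                           adjust_for_dysbiosis = FALSE, transform = "log1p")

matches <- match_cohort(list(taxa = md, coupled = md_c), 2)
align <- function(res_a, res_b) {
  keep <- matches$taxa_sample %in% colnames(res_a) &
    matches$coupled_sample %in% colnames(res_b)
  b <- res_b[, matches$coupled_sample[keep], drop = FALSE]
  colnames(b) <- matches$taxa_sample[keep]
  list(taxa = res_a, coupled = b)
}

for (variant in c("adjusted", "unadjusted")) {
  inputs <- if (variant == "adjusted") align(res_taxa_adj, res_coup_adj)
            else align(res_taxa_un, res_coup_un)
  net <- spearman_network(inputs, dysbiosis_features = hits)
  write.table(net$edges, file.path(out, sprintf("network_%s_edges.tsv", variant)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$nodes, file.path(out, sprintf("network_%s_nodes.tsv", variant)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s network: %d edges, %d nodes, %d hubs", variant,
                  nrow(net$edges), nrow(net$nodes), sum(net$nodes$hub)))
}
message("wrote ", out)
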