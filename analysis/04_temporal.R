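#!/usr/bin/env Rscript
# Temporal statistics: power-law divergence of within-subject Bray-Curtis
# dissimilarity over time (with flat-line and between-group F-tests),
# repeated-measures PERMANOVA of diagnosis and dysbiosis, and inter-/intra-
# individual Mantel coupling between the two measurement types.

suppressPackageStartupMessages(library(dysbiome))

cohort_dir <- "results/cohort"
out <- "results/temporal"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 4

taxa <- relative_normalize(
  read_profile_tsv(file.path(cohort_dir, "taxa_profiles.tsv"), "MGX-taxa"))
coupled <- relative_normalize(
  read_profile_tsv(file.path(cohort_dir, "coupled_profiles.tsv"), "MBX"))
md <- validate_metadata(read.csv(file.path(cohort_dir, "metadata.csv")))
md_c <- validate_metadata(read.csv(file.path(cohort_dir, "metadata_coupled.csv")))
scores <- read.delim("results/dysbiosis/scores.tsv")
md$dysbiotic <- scores$dysbiotic[match(md$sample_id, scores$sample_id)]

D <- bray_curtis(taxa)
pairs <- build_pair_sets(D, md, include_inter = FALSE)
pairs$diagnosis <- md$diagnosis[match(pairs$subject_id, md$subject_id)]
pairs <- pairs[pairs$dt > 0, ]

rows <- list()
by_group <- split(pairs[, c("dt", "dissimilarity")], pairs$diagnosis)
for (dx in names(by_group)) {
  fit <- fit_powerlaw(by_group[[dx]]$dt, by_group[[dx]]$dissimilarity)
  ft <- powerlaw_vs_flat_test(fit)
  rows[[dx]] <- data.frame(test = "powerlaw_vs_flat", group = dx,
                           statistic = ft$F, p = ft$p, n = fit$n,
                           a = fit$a, b = fit$b, c = fit$c,
                           scheme = "F", seed = seed)
  message(sprintf("power law %-6s d = %.3f*dt^%.3f + %.3f  (F p = %.3g)",
                  dx, fit$a, fit$b, fit$c, ft$p))
}
cmp <- powerlaw_group_compare(by_group[c("UC", "CD")])
message(sprintf("UC vs CD power-law difference: F p = %.3g", cmp$p))
cmp2 <- powerlaw_group_compare(by_group[c("nonIBD", "CD")])
message(sprintf("nonIBD vs CD power-law difference: F p = %.3g", cmp2$p))
rows$cmp <- data.frame(test = "powerlaw_group_compare", group = "UC/CD",
                       statistic = cmp$F, p = cmp$p, n = NA,
                       a = NA, b = NA, c = NA, scheme = "F", seed = seed)

pv_dx <- blocked_permanova(D, "diagnosis", md, scheme = "subject-relabel",
                           n_perm = 999, seed = seed)
pv_dys <- blocked_permanova(D, md$dysbiotic, md, scheme = "within-subject",
                            n_perm = 999, seed = seed)
message(sprintf("PERMANOVA diagnosis:  R2 = %.3f, p = %.3g (subject-relabel)",
                pv_dx$r2, pv_dx$p))
message(sprintf("PERMANOVA dysbiosis:  R2 = %.3f, p = %.3g (within-subject)",
                pv_dys$r2, pv_dys$p))
rows$pdx <- data.frame(test = "permanova_diagnosis", group = "all",
                       statistic = pv_dx$r2, p = pv_dx$p, n = ncol(D),
                       a = NA, b = NA, c = NA, scheme = pv_dx$scheme, seed = seed)
rows$pdys <- data.frame(test = "permanova_dysbiosis", group = "all",
                        statistic = pv_dys$r2, p = pv_dys$p, n = ncol(D),
                        a = NA, b = NA, c = NA, scheme = pv_dys$scheme, seed = seed)

# Mantel coupling between measurement types on matched samples/subjects
matches <- match_cohort(list(taxa = md, coupled = md_c), 2)
ta <- unclass(taxa)[, matches$taxa_sample, drop = FALSE]
tb <- unclass(coupled)[, matches$coupled_sample, drop = FALSE]
colnames(tb) <- colnames(ta)
md_m <- md[match(matches$taxa_sample, md$sample_id), ]
DA <- bray_curtis(abundance_table(ta, type = "MGX-taxa"))
DB <- bray_curtis(abundance_table(tb, type = "MBX"))

subj_a <- subject_mean_profiles(abundance_table(ta, type = "MGX-taxa"), md_m)
subj_b <- subject_mean_profiles(abundance_table(tb, type = "MBX"), md_m)
mi <- mantel_inter(bray_curtis(subj_a), bray_curtis(subj_b),
                   n_perm = 999, seed = seed)
mw <- mantel_intra(DA, DB, md_m, n_perm = 999, seed = seed)
message(sprintf("Mantel inter-individual: r2 = %.3f, p = %.3g", mi$r2, mi$p))
message(sprintf("Mantel intra-individual: r2 = %.3f, p = %.3g", mw$r2, mw$p))
rows$mi <- data.frame(test = "mantel_inter", group = "taxa~coupled",
                      statistic = mi$r2, p = mi$p, n = ncol(subj_a),
                      a = NA, b = NA, c = NA, scheme = mi$scheme, seed = seed)
rows$mw <- data.frame(test = "mantel_intra", group = "taxa~coupled",
                      statistic = mw$r2, p = mw$p, n = nrow(matches),
                      a = NA, b = NA, c = NA, scheme = mw$scheme, seed = seed)

write.table(do.call(rbind, rows), file.path(out, "temporal_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
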