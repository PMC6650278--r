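#!/usr/bin/env Rscript
# Dysbiosis scoring and episode statistics: score each sample by its median
# Bray-Curtis dissimilarity to the week->20 non-IBD reference set (own
# subject excluded), threshold at the 90th percentile of non-IBD scores,
# extract dysbiotic episodes/intervals with end-of-series censoring, and
# estimate their exponential means with the censored MLE. Also: Kaplan-Meier
# curves and cross-measurement-type dysbiosis concordance.

suppressPackageStartupMessages(library(dysbiome))

cohort_dir <- "results/cohort"
out <- "results/dysbiosis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

taxa <- read_profile_tsv(file.path(cohort_dir, "taxa_profiles.tsv"), "MGX-taxa")
coupled <- read_profile_tsv(file.path(cohort_dir, "coupled_profiles.tsv"), "MBX")
md <- validate_metadata(read.csv(file.path(cohort_dir, "metadata.csv")))
md_c <- validate_metadata(read.csv(file.path(cohort_dir, "metadata_coupled.csv")))

res <- dysbiosis_classify(taxa, md)
md$dysbiotic <- unname(res$dysbiotic[md$sample_id])
message(sprintf("threshold %.4f; %d/%d samples (%.1f%%) dysbiotic",
                res$threshold, sum(md$dysbiotic), nrow(md),
                100 * mean(md$dysbiotic)))
for (dx in c("nonIBD", "UC", "CD")) {
  message(sprintf("  %-6s %5.1f%% dysbiotic", dx,
                  100 * mean(md$dysbiotic[md$diagnosis == dx])))
}
write.table(data.frame(sample_id = names(res$scores), score = res$scores,
                       dysbiotic = res$dysbiotic, threshold = res$threshold),
            file.path(out, "scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

episodes <- extract_episodes(md)
episodes$diagnosis <- md$diagnosis[match(episodes$subject_id, md$subject_id)]
write.table(episodes, file.path(out, "episodes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

rows <- list()
for (dx in c("UC", "CD")) {
  for (kind in c("duration", "interval")) {
    ep <- episodes[episodes$diagnosis == dx & episodes$kind == kind, ]
    if (sum(!ep$censored) == 0) next
    est <- censored_exponential_mean(ep)
    rows[[paste(dx, kind)]] <- data.frame(
      diagnosis = dx, kind = kind, mean_weeks = est$mean, se = est$se,
      n_episodes = est$n, n_censored = est$n - est$n_uncensored)
    km <- kaplan_meier(ep)
    write.table(km, file.path(out, sprintf("km_%s_%s.tsv", dx, kind)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
est_tab <- do.call(rbind, rows)
write.table(est_tab, file.path(out, "episode_estimates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("censored-MLE episode means (weeks):")
for (k in seq_len(nrow(est_tab))) {
  message(sprintf("  %-3s %-9s %5.2f +/- %.2f (n=%d, %d censored)",
                  est_tab$diagnosis[k], est_tab$kind[k], est_tab$mean_weeks[k],
                  est_tab$se[k], est_tab$n_episodes[k], est_tab$n_censored[k]))
}

# concordance of metagenomic vs metabolite-like dysbiosis calls on 2-week
# matched samples
res_c <- dysbiosis_classify(coupled, md_c)
matches <- match_cohort(list(taxa = md, coupled = md_c), 2)
a <- res$dysbiotic[matches$taxa_sample]
b <- res_c$dysbiotic[matches$coupled_sample]
conc <- cross_type_concordance(a, b)
message(sprintf(
  "cross-type concordance on %d matched pairs: OR %.2f, Fisher p %.3g",
  nrow(matches), conc$odds_ratio, conc$p))
write.table(data.frame(odds_ratio = conc$odds_ratio, p = conc$p,
                       n_pairs = nrow(matches)),
            file.path(out, "cross_type_concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out)
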