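#!/usr/bin/env Rscript
# Simulate the synthetic longitudinal multi-omic cohort that every later
# analysis step consumes: three diagnosis groups followed for a year with
# 2-weekly stool sampling, a latent eubiotic/dysbiotic semi-Markov process
# per subject (sojourn means: CD 7.8/12.8 wk, UC 4.1/17.2 wk, non-IBD 4/36
# wk), a 100-taxon metagenomic table with 10 depleted + 10 enriched
# dysbiosis-responsive taxa, and a coupled metabolite-like table.

suppressPackageStartupMessages(library(dysbiome))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

config <- cohort_config(seed = 20260928)
cohort <- simulate_cohort(config)

write_profile_tsv(cohort$taxa$table, file.path(out, "taxa_profiles.tsv"))
write_profile_tsv(cohort$coupled$table, file.path(out, "coupled_profiles.tsv"))
write.csv(cohort$taxa$metadata, file.path(out, "metadata.csv"), row.names = FALSE)
write.csv(cohort$coupled$metadata, file.path(out, "metadata_coupled.csv"),
          row.names = FALSE)
writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, pretty = TRUE),
           file.path(out, "config.json"))
writeLines(c(cohort$taxa$truth$depleted, cohort$taxa$truth$enriched),
           file.path(out, "responsive_taxa.txt"))

md <- cohort$taxa$metadata
message(sprintf("cohort: %d subjects, %d metagenomic samples, %d coupled samples",
                length(unique(md$subject_id)), nrow(md),
                nrow(cohort$coupled$metadata)))
for (dx in c("nonIBD", "UC", "CD")) {
  sel <- md$diagnosis == dx
  message(sprintf("  %-6s %4d samples, %5.1f%% in the latent dysbiotic state",
                  dx, sum(sel), 100 * mean(md$dysbiotic_true[sel])))
}
message("wrote ", out)
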