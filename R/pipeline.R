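#' @noRd
.config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(js), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Run the full longitudinal dysbiosis pipeline on a synthetic cohort
#'
#' Executes, in dependency order: cohort simulation, dysbiosis
#' scoring/classification and episode extraction, shift detection, temporal
#' statistics (power-law fits, Mantel, PERMANOVA), cross-measurement-type
#' matching, and the residual Spearman network. Every stage writes its
#' outputs under `out_dir` and is recorded in a machine-readable manifest
#' (`manifest.json`) with the full configuration, seeds, parameter values,
#' and output file hashes. When a stage is disabled its previously written
#' outputs are reused from disk; a missing upstream output is an explicit
#' dependency error. Reruns with an identical configuration reuse stage
#' outputs whose files are present (keyed by the configuration hash).
#'
#' @param config a [cohort_config()]; its `seed` drives every stage through
#'   named substreams.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to execute.
#' @param n_perm permutation count for the temporal statistics stage.
#' @param match_window matching window width in weeks.
#' @param force rerun stages even when cached outputs match.
#' @return The manifest, invisibly; stage results as a list.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = "pipeline_out",
                         stages = c("simulate", "dysbiosis", "shifts",
                                    "temporal", "match", "network"),
                         n_perm = 199, match_window = 2, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL) else NULL
  cached_ok <- !force && !is.null(prev) && identical(prev$config_hash, hash)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dysbiome")),
    r_version = R.version.string,
    config = unclass(config),
    config_hash = hash,
    n_perm = n_perm, match_window = match_window,
    stages = list()
  )
  results <- list()
  paths <- list(
    taxa = file.path(out_dir, "taxa_profiles.tsv"),
    coupled = file.path(out_dir, "coupled_profiles.tsv"),
    metadata = file.path(out_dir, "metadata.csv"),
    metadata_coupled = file.path(out_dir, "metadata_coupled.csv"),
    dysbiosis = file.path(out_dir, "dysbiosis_scores.tsv"),
    episodes = file.path(out_dir, "episodes.tsv"),
    shifts = file.path(out_dir, "shift_calls.tsv"),
    curve = file.path(out_dir, "shift_thresholds.tsv"),
    temporal = file.path(out_dir, "temporal_stats.tsv"),
    matches = file.path(out_dir, "matched_sets.tsv"),
    edges = file.path(out_dir, "network_edges.tsv"),
    nodes = file.path(out_dir, "network_nodes.tsv")
  )
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  need <- function(ps) {
    missing <- ps[!file.exists(unlist(ps))]
    if (length(missing) > 0) {
      stop(sprintf("missing upstream output(s): %s (enable the producing stage)",
                   paste(unlist(missing), collapse = ", ")), call. = FALSE)
    }
  }
  stage_done <- function(name, outputs) {
    manifest$stages[[name]] <<- list(
      outputs = unlist(outputs),
      md5 = unname(tools::md5sum(unlist(outputs))))
  }

  ## -- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    sim_paths <- paths[c("taxa", "coupled", "metadata", "metadata_coupled")]
    if (cached_ok && all(file.exists(unlist(sim_paths)))) {
      cohort <- NULL
    } else {
      cohort <- simulate_cohort(config)
      write_profile_tsv(cohort$taxa$table, paths$taxa)
      write_profile_tsv(cohort$coupled$table, paths$coupled)
      utils::write.csv(cohort$taxa$metadata, paths$metadata, row.names = FALSE)
      utils::write.csv(cohort$coupled$metadata, paths$metadata_coupled,
                       row.names = FALSE)
    }
    stage_done("simulate", sim_paths)
    results$cohort <- cohort
  }

  load_primary <- function() {
    need(paths[c("taxa", "metadata")])
    list(table = read_profile_tsv(paths$taxa, type = "MGX-taxa"),
         metadata = validate_metadata(utils::read.csv(paths$metadata)))
  }

  ## -- dysbiosis -----------------------------------------------------------
  if ("dysbiosis" %in% stages) {
    prim <- load_primary()
    dres <- dysbiosis_classify(prim$table, prim$metadata)
    md <- prim$metadata
    md$dysbiotic <- unname(dres$dysbiotic[md$sample_id])
    episodes <- extract_episodes(md)
    write_tsv(data.frame(sample_id = names(dres$scores),
                         score = unname(dres$scores),
                         dysbiotic = unname(dres$dysbiotic),
                         threshold = dres$threshold), paths$dysbiosis)
    write_tsv(as.data.frame(episodes), paths$episodes)
    stage_done("dysbiosis", paths[c("dysbiosis", "episodes")])
    results$dysbiosis <- dres
    results$episodes <- episodes
    results$episode_means <- lapply(
      split(as.data.frame(episodes), episodes$kind),
      censored_exponential_mean)
  }

  ## -- shifts --------------------------------------------------------------
  if ("shifts" %in% stages) {
    prim <- load_primary()
    tab <- relative_normalize(prim$table)
    D <- bray_curtis(tab)
    nonibd <- prim$metadata$sample_id[prim$metadata$diagnosis == "nonIBD"]
    pairs_ref <- build_pair_sets(D[nonibd, nonibd], prim$metadata)
    curve <- fit_threshold_curve(pairs_ref,
                                 sampling_interval = config$sampling_interval)
    pairs_all <- build_pair_sets(D, prim$metadata, consecutive_only = TRUE,
                                 include_inter = FALSE)
    calls <- call_shifts(pairs_all, curve)
    calls <- attribute_shifts(calls, tab, prim$metadata)
    rates <- shift_rate(calls, pairs_all, prim$metadata)
    write_tsv(calls, paths$shifts)
    write_tsv(curve$windows, paths$curve)
    stage_done("shifts", paths[c("shifts", "curve")])
    results$shift_curve <- curve
    results$shift_calls <- calls
    results$shift_rates <- rates
  }

  ## -- temporal ------------------------------------------------------------
  if ("temporal" %in% stages) {
    prim <- load_primary()
    tab <- relative_normalize(prim$table)
    D <- bray_curtis(tab)
    pairs <- build_pair_sets(D, prim$metadata, include_inter = FALSE)
    md <- prim$metadata
    rows <- list()
    for (dx in unique(md$diagnosis)) {
      sel <- pairs$subject_id %in% md$subject_id[md$diagnosis == dx]
      pp <- pairs[sel & pairs$dt > 0, ]
      fit <- fit_powerlaw(pp$dt, pp$dissimilarity)
      ft <- powerlaw_vs_flat_test(fit)
      rows[[dx]] <- data.frame(test = "powerlaw_vs_flat", group = dx,
                               statistic = ft$F, p = ft$p, n = fit$n,
                               scheme = "F-test", seed = config$seed)
    }
    pv <- blocked_permanova(D, "diagnosis", md, scheme = "subject-relabel",
                            n_perm = n_perm, seed = config$seed)
    rows$permanova <- data.frame(test = "permanova_diagnosis", group = "all",
                                 statistic = pv$r2, p = pv$p, n = ncol(D),
                                 scheme = pv$scheme, seed = config$seed)
    write_tsv(do.call(rbind, rows), paths$temporal)
    stage_done("temporal", paths["temporal"])
    results$temporal <- do.call(rbind, rows)
  }

  ## -- match ---------------------------------------------------------------
  if ("match" %in% stages) {
    need(paths[c("metadata", "metadata_coupled")])
    md_a <- validate_metadata(utils::read.csv(paths$metadata))
    md_b <- validate_metadata(utils::read.csv(paths$metadata_coupled))
    matches <- match_cohort(list(taxa = md_a, coupled = md_b), match_window)
    write_tsv(matches, paths$matches)
    stage_done("match", paths["matches"])
    results$matches <- matches
  }

  ## -- network -------------------------------------------------------------
  if ("network" %in% stages) {
    need(paths[c("taxa", "coupled", "metadata", "metadata_coupled", "dysbiosis",
                 "matches")])
    prim <- load_primary()
    coup <- read_profile_tsv(paths$coupled, type = "MBX")
    md_a <- prim$metadata
    md_b <- validate_metadata(utils::read.csv(paths$metadata_coupled))
    dys <- utils::read.delim(paths$dysbiosis)
    md_a$dysbiotic <- dys$dysbiotic[match(md_a$sample_id, dys$sample_id)]
    md_b$dysbiotic <- dys$dysbiotic[match(md_b$sample_id, dys$sample_id)]
    taxa_f <- prevalence_variance_filter(relative_normalize(prim$table))
    res_a <- residualize(taxa_f, md_a)
    res_b <- residualize(prevalence_variance_filter(coup), md_b,
                         transform = "log1p")
    matches <- utils::read.delim(paths$matches)
    # align coupled residual columns to their matched taxa samples
    keep <- matches$taxa_sample %in% colnames(res_a) &
      matches$coupled_sample %in% colnames(res_b)
    mb <- res_b[, matches$coupled_sample[keep], drop = FALSE]
    colnames(mb) <- matches$taxa_sample[keep]
    net <- spearman_network(list(taxa = res_a, coupled = mb))
    write_tsv(net$edges, paths$edges)
    write_tsv(net$nodes, paths$nodes)
    stage_done("network", paths[c("edges", "nodes")])
    results$network <- net
  }

  manifest$completed <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
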