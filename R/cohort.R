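#' Configuration for a synthetic longitudinal multi-omic cohort
#'
#' The generator emulates the design of a year-long IBD cohort: subjects in
#' three diagnosis groups (nonIBD/UC/CD) sampled every two weeks, each
#' carrying a latent two-state (eubiotic/dysbiotic) continuous-time
#' semi-Markov process with exponential sojourn times. Dysbiotic state shifts
#' a designated set of taxa (depleted obligate-anaerobe-like taxa, enriched
#' facultative-anaerobe-like taxa) on the log scale. A coupled secondary
#' measurement type (metabolite-like) responds to the same latent state,
#' attenuated by `coupling_strength`.
#'
#' Episode sojourn means default to 7.8/12.8 weeks (duration/interval) for
#' CD and 4.1/17.2 for UC; non-IBD subjects share the process with a long
#' interval mean (36 weeks) so that roughly 10% of their samples fall in the
#' dysbiotic state.
#'
#' @param n_subjects_per_group named integer vector over
#'   `c("nonIBD","UC","CD")`.
#' @param study_length study span in weeks (default 52).
#' @param sampling_interval weeks between scheduled samples (default 2; must
#'   divide `study_length`).
#' @param mean_episode_duration,mean_episode_interval named numeric vectors
#'   of exponential sojourn means (weeks) per diagnosis; `Inf` interval means
#'   a group never enters dysbiosis.
#' @param n_taxa number of taxa in the primary (taxonomic) table.
#' @param n_depleted,n_enriched dysbiosis-responsive taxa counts
#'   (depleted/enriched; sum must not exceed `n_taxa`).
#' @param effect_size log-scale shift magnitude applied to responsive taxa
#'   while dysbiotic (default 3, i.e. about 20-fold).
#' @param subject_sd log-scale SD of per-subject taxon baselines.
#' @param temporal_sd log-scale SD of AR(1) innovations.
#' @param ar_coefficient AR(1) coefficient per sampling step, in `[0, 1)`.
#' @param missingness_prob independent drop probability per scheduled sample.
#' @param coupling_strength attenuation of the dysbiosis effect in the
#'   coupled measurement type, in `[0, 1]`.
#' @param detection_limit relative abundances below this are recorded as 0
#'   (zero inflation as produced by finite sequencing depth).
#' @param n_features_coupled,n_responsive_coupled coupled-table feature
#'   counts.
#' @param seed master seed; all stage randomness is derived from it via
#'   named substreams.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = c(nonIBD = 40, UC = 40, CD = 40),
                          study_length = 52,
                          sampling_interval = 2,
                          mean_episode_duration = c(nonIBD = 4, UC = 4.1, CD = 7.8),
                          mean_episode_interval = c(nonIBD = 36, UC = 17.2, CD = 12.8),
                          n_taxa = 100,
                          n_depleted = 10,
                          n_enriched = 10,
                          effect_size = 3,
                          subject_sd = 1,
                          temporal_sd = 0.35,
                          ar_coefficient = 0.5,
                          missingness_prob = 0.1,
                          coupling_strength = 0.7,
                          detection_limit = 1e-4,
                          n_features_coupled = 200,
                          n_responsive_coupled = 20,
                          seed = 1) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group,
              study_length = study_length,
              sampling_interval = sampling_interval,
              mean_episode_duration = mean_episode_duration,
              mean_episode_interval = mean_episode_interval,
              n_taxa = n_taxa, n_depleted = n_depleted, n_enriched = n_enriched,
              effect_size = effect_size, subject_sd = subject_sd,
              temporal_sd = temporal_sd, ar_coefficient = ar_coefficient,
              missingness_prob = missingness_prob,
              coupling_strength = coupling_strength,
              detection_limit = detection_limit,
              n_features_coupled = n_features_coupled,
              n_responsive_coupled = n_responsive_coupled,
              seed = seed)
  .assert(all(cfg$mean_episode_duration > 0), "episode duration means must be positive")
  .assert(all(cfg$mean_episode_interval > 0), "episode interval means must be positive")
  .assert(cfg$subject_sd >= 0 && cfg$temporal_sd >= 0, "SDs must be nonnegative")
  .assert(cfg$study_length %% cfg$sampling_interval == 0,
          "sampling_interval must divide study_length")
  .assert(cfg$missingness_prob >= 0 && cfg$missingness_prob < 1,
          "missingness_prob must be in [0, 1)")
  .assert(cfg$n_depleted + cfg$n_enriched <= cfg$n_taxa,
          "depleted + enriched must not exceed n_taxa")
  .assert(cfg$ar_coefficient >= 0 && cfg$ar_coefficient < 1,
          "ar_coefficient must be in [0, 1)")
  .assert(cfg$coupling_strength >= 0 && cfg$coupling_strength <= 1,
          "coupling_strength must be in [0, 1]")
  .assert(cfg$effect_size >= 0, "effect_size must be nonnegative")
  structure(cfg, class = "cohort_config")
}

#' @noRd
.rexp_mean <- function(n, mean) {
  if (!is.finite(mean)) rep(Inf, n) else stats::rexp(n, rate = 1 / mean)
}

#' Simulate one subject's latent dysbiosis state process
#'
#' Continuous-time alternation of eubiotic and dysbiotic states with
#' independent exponential sojourns (initial state eubiotic), discretized by
#' the state holding at each scheduled sampling time.
#'
#' @param config a [cohort_config()].
#' @param diagnosis diagnosis group with configured sojourn means.
#' @param subject_id subject identifier; also names the RNG substream, so
#'   adding subjects never perturbs existing ones.
#' @return List of class `state_series`: `subject_id`, `weeks` (sampling
#'   grid), `dysbiotic` (logical state at each grid point), `transitions`
#'   (continuous transition times within the study window).
#' @export
simulate_state_process <- function(config, diagnosis, subject_id = diagnosis) {
  .assert(diagnosis %in% names(config$mean_episode_duration) &&
            diagnosis %in% names(config$mean_episode_interval),
          sprintf("no sojourn means configured for diagnosis '%s'", diagnosis))
  m_dur <- config$mean_episode_duration[[diagnosis]]
  m_int <- config$mean_episode_interval[[diagnosis]]
  weeks <- seq(0, config$study_length, by = config$sampling_interval)
  transitions <- with_stream(config$seed, paste0("state:", subject_id), {
    t <- 0
    dysbiotic <- FALSE
    trans <- numeric(0)
    repeat {
      sojourn <- .rexp_mean(1, if (dysbiotic) m_dur else m_int)
      t <- t + sojourn
      if (t > config$study_length) break
      trans <- c(trans, t)
      dysbiotic <- !dysbiotic
    }
    trans
  })
  # state at a grid point = parity of the number of transitions before it
  state <- (findInterval(weeks, transitions) %% 2) == 1
  structure(list(subject_id = subject_id, weeks = weeks, dysbiotic = state,
                 transitions = transitions, diagnosis = diagnosis),
            class = "state_series")
}

#' @noRd
.taxon_baselines <- function(config) {
  with_stream(config$seed, "taxa-baselines",
              stats::rnorm(config$n_taxa, mean = 0, sd = 1.5))
}

#' Simulate taxonomic profiles for a set of subjects
#'
#' Per-subject log-normal baselines (SD `subject_sd`) around cohort-level
#' taxon means, AR(1) temporal noise on the sampling grid (coefficient
#' `ar_coefficient`, innovation SD `temporal_sd`), and an additive log-scale
#' shift of `+/- effect_size` on the responsive taxa while the latent state
#' is dysbiotic. Profiles are closed to relative abundances, values below
#' the detection limit are zeroed (then re-closed), and scheduled samples
#' are dropped independently with `missingness_prob` (weeks are then re-zeroed
#' to the subject's first retained sample).
#'
#' @param config a [cohort_config()].
#' @param states list of `state_series`, one per subject (see
#'   [simulate_state_process()]).
#' @return List: `table` (an [abundance_table()], type `MGX-taxa`),
#'   `metadata` (with latent truth in `dysbiotic_true`), `truth` (responsive
#'   taxon IDs).
#' @export
simulate_profiles <- function(config, states) {
  .assert(length(states) > 0, "empty subject list")
  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  depleted <- taxa[seq_len(config$n_depleted)]
  enriched <- taxa[config$n_depleted + seq_len(config$n_enriched)]
  mu <- .taxon_baselines(config)
  ar <- config$ar_coefficient

  cols <- list(); meta <- list()
  for (st in states) {
    sid <- st$subject_id
    n_t <- length(st$weeks)
    sim <- with_stream(config$seed, paste0("subject:", sid), {
      b <- stats::rnorm(config$n_taxa, 0, config$subject_sd)
      e <- matrix(0, n_t, config$n_taxa)
      sd0 <- if (ar > 0) config$temporal_sd / sqrt(1 - ar^2) else config$temporal_sd
      e[1, ] <- stats::rnorm(config$n_taxa, 0, sd0)
      if (n_t > 1) {
        for (t in 2:n_t) {
          e[t, ] <- ar * e[t - 1, ] + stats::rnorm(config$n_taxa, 0, config$temporal_sd)
        }
      }
      keep <- stats::runif(n_t) >= config$missingness_prob
      age <- round(stats::runif(1, 18, 75))
      sex <- sample(c("F", "M"), 1)
      site <- sample(sprintf("site%d", 1:5), 1)
      abx <- stats::runif(n_t) < 0.05
      list(b = b, e = e, keep = keep, age = age, sex = sex, site = site, abx = abx)
    })
    loga <- sweep(sim$e, 2, mu + sim$b, "+")
    eff <- rep(0, config$n_taxa)
    eff[match(depleted, taxa)] <- -config$effect_size
    eff[match(enriched, taxa)] <- config$effect_size
    loga[st$dysbiotic, ] <- sweep(loga[st$dysbiotic, , drop = FALSE], 2, eff, "+")
    x <- exp(loga)
    rel <- x / rowSums(x)
    rel[rel < config$detection_limit] <- 0
    rel <- rel / rowSums(rel)

    keep <- sim$keep
    if (!any(keep)) keep[1] <- TRUE
    wk <- st$weeks[keep] - min(st$weeks[keep])
    ids <- sprintf("%s_wk%02d", sid, wk)
    m <- t(rel[keep, , drop = FALSE])
    dimnames(m) <- list(taxa, ids)
    cols[[sid]] <- m
    meta[[sid]] <- data.frame(
      sample_id = ids, subject_id = sid, week = wk,
      diagnosis = st$diagnosis,
      dysbiotic_true = st$dysbiotic[keep],
      consent_age = sim$age, sex = sim$sex, site = sim$site,
      antibiotics = sim$abx[keep],
      stringsAsFactors = FALSE
    )
  }
  table <- abundance_table(do.call(cbind, cols), type = "MGX-taxa")
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(table = table, metadata = validate_metadata(metadata),
       truth = list(depleted = depleted, enriched = enriched))
}

#' Simulate a coupled secondary measurement type
#'
#' A metabolite-like feature space responding to the same latent dysbiosis
#' state as the primary table, with the log-scale effect attenuated by
#' `coupling_strength`, independent per-subject baselines, and independent
#' (serially uncorrelated) temporal noise: the coupled features vary rapidly
#' rather than drifting. Samples are dropped independently with their own
#' missingness draw, so the coupled table covers a different subset of weeks
#' than the primary table (exercising temporal matching).
#'
#' @param primary_metadata metadata from [simulate_profiles()] (provides the
#'   latent state per retained specimen).
#' @param config a [cohort_config()].
#' @param coupling_strength override of `config$coupling_strength`.
#' @param missingness_prob override of `config$missingness_prob`.
#' @return List: `table` (type `MBX`, sample IDs shared with the primary
#'   table for co-collected specimens), `metadata` (rows of
#'   `primary_metadata` retained), `truth` (responsive coupled feature IDs).
#' @export
simulate_coupled_measurement <- function(primary_metadata, config,
                                         coupling_strength = config$coupling_strength,
                                         missingness_prob = config$missingness_prob) {
  .assert(coupling_strength >= 0 && coupling_strength <= 1,
          "coupling_strength must be in [0, 1]")
  nf <- config$n_features_coupled
  nr <- config$n_responsive_coupled
  .assert(nr <= nf, "more responsive coupled features than features")
  feats <- sprintf("cpd_%03d", seq_len(nf))
  dep <- feats[seq_len(floor(nr / 2))]
  enr <- feats[floor(nr / 2) + seq_len(ceiling(nr / 2))]
  nu <- with_stream(config$seed, "coupled-baselines",
                    stats::rnorm(nf, 0, 1.5))
  eff <- rep(0, nf)
  eff[match(dep, feats)] <- -coupling_strength * config$effect_size
  eff[match(enr, feats)] <- coupling_strength * config$effect_size

  cols <- list(); keep_rows <- list()
  for (sid in unique(primary_metadata$subject_id)) {
    md <- primary_metadata[primary_metadata$subject_id == sid, ]
    md <- md[order(md$week), ]
    n_t <- nrow(md)
    sim <- with_stream(config$seed, paste0("coupled:", sid), {
      b <- stats::rnorm(nf, 0, config$subject_sd)
      e <- matrix(stats::rnorm(n_t * nf, 0, config$temporal_sd), n_t, nf)
      keep <- stats::runif(n_t) >= missingness_prob
      list(b = b, e = e, keep = keep)
    })
    loga <- sweep(sim$e, 2, nu + sim$b, "+")
    loga[md$dysbiotic_true, ] <- sweep(loga[md$dysbiotic_true, , drop = FALSE], 2, eff, "+")
    x <- exp(loga)
    rel <- x / rowSums(x)
    rel[rel < config$detection_limit] <- 0
    rel <- rel / rowSums(rel)
    keep <- sim$keep
    if (!any(keep)) keep[1] <- TRUE
    m <- t(rel[keep, , drop = FALSE])
    dimnames(m) <- list(feats, md$sample_id[keep])
    cols[[sid]] <- m
    keep_rows[[sid]] <- md[keep, ]
  }
  metadata <- do.call(rbind, keep_rows)
  rownames(metadata) <- NULL
  list(table = abundance_table(do.call(cbind, cols), type = "MBX"),
       metadata = metadata,
       truth = list(depleted = dep, enriched = enr))
}

#' Simulate a full synthetic cohort
#'
#' Generates latent state series for every subject in every diagnosis group,
#' the primary taxonomic table, and the coupled measurement type.
#'
#' @param config a [cohort_config()].
#' @return List of class `synthetic_cohort`: `config`, `states`, `taxa`
#'   (primary table + metadata + truth), `coupled`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  states <- list()
  for (dx in names(config$n_subjects_per_group)) {
    n <- config$n_subjects_per_group[[dx]]
    for (k in seq_len(n)) {
      sid <- sprintf("%s%02d", dx, k)
      states[[sid]] <- simulate_state_process(config, dx, sid)
    }
  }
  taxa <- simulate_profiles(config, states)
  coupled <- simulate_coupled_measurement(taxa$metadata, config)
  structure(list(config = config, states = states, taxa = taxa,
                 coupled = coupled),
            class = "synthetic_cohort")
}
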