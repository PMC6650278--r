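#' Build the non-IBD reference sample set
#'
#' Reference samples are taken from non-IBD subjects strictly after week
#' `min_week` of the subject's own time series, skipping the early samples
#' from control subjects whose initial gastrointestinal symptoms may not yet
#' have resolved.
#'
#' @param metadata validated sample metadata.
#' @param min_week cutoff; samples with `week > min_week` are kept
#'   (default 20).
#' @return Character vector of reference sample IDs.
#' @export
build_reference_set <- function(metadata, min_week = 20) {
  metadata <- validate_metadata(metadata)
  metadata$sample_id[metadata$diagnosis == "nonIBD" & metadata$week > min_week]
}

#' Dysbiosis scores: median dissimilarity to the reference set
#'
#' The score of a sample is the median Bray-Curtis dissimilarity to the
#' reference set, excluding reference samples from the sample's own subject
#' (so a subject's unusual-but-stable community does not score itself as
#' normal).
#'
#' @param D sample-by-sample dissimilarity matrix.
#' @param metadata validated sample metadata.
#' @param reference_ids reference sample IDs (see [build_reference_set()]).
#' @return Named numeric vector of scores for every sample in `D`.
#' @export
dysbiosis_score <- function(D, metadata, reference_ids) {
  metadata <- validate_metadata(metadata)
  ids <- colnames(D)
  .assert(all(reference_ids %in% ids), "reference samples missing from D")
  md <- metadata[match(ids, metadata$sample_id), ]
  ref_subject <- md$subject_id[match(reference_ids, ids)]
  scores <- vapply(seq_along(ids), function(k) {
    eligible <- reference_ids[ref_subject != md$subject_id[k]]
    if (length(eligible) == 0) {
      stop(sprintf("no reference samples outside subject '%s' for sample '%s'",
                   md$subject_id[k], ids[k]), call. = FALSE)
    }
    stats::median(D[ids[k], eligible])
  }, numeric(1))
  names(scores) <- ids
  scores
}

#' Cohort dysbiosis threshold
#'
#' The configured percentile (default 90th, type-7 linear interpolation) of
#' the dysbiosis-score distribution among non-IBD samples. Samples above it
#' have a less-than-`(100 - percentile)`% probability of occurring in a
#' participant without IBD.
#'
#' @param scores named score vector from [dysbiosis_score()].
#' @param metadata validated sample metadata.
#' @param percentile percentile in (0, 100), default 90.
#' @return Threshold score.
#' @export
dysbiosis_threshold <- function(scores, metadata, percentile = 90) {
  metadata <- validate_metadata(metadata)
  md <- metadata[match(names(scores), metadata$sample_id), ]
  s <- scores[md$diagnosis == "nonIBD"]
  .assert(length(s) > 0, "no non-IBD samples to derive the threshold from")
  unname(stats::quantile(s, percentile / 100, type = 7))
}

#' Classify samples as dysbiotic
#'
#' Strictly-greater comparison: a score exactly at the threshold is
#' non-dysbiotic.
#'
#' @param scores numeric score vector.
#' @param threshold threshold from [dysbiosis_threshold()].
#' @return Logical vector.
#' @export
classify_dysbiosis <- function(scores, threshold) {
  scores > threshold
}

#' Full dysbiosis scoring pipeline
#'
#' Normalizes (optionally), computes Bray-Curtis dissimilarities, builds the
#' non-IBD reference set, scores every sample, derives the cohort threshold,
#' and classifies.
#'
#' @param table an [abundance_table()].
#' @param metadata validated sample metadata.
#' @param min_week reference-set cutoff (default 20).
#' @param percentile threshold percentile (default 90).
#' @param normalize total-sum scale first (default TRUE).
#' @return List of class `dysbiosis_result`: `scores`, `threshold`,
#'   `dysbiotic` (named logical), `reference_ids`, and the parameters used.
#' @export
dysbiosis_classify <- function(table, metadata, min_week = 20, percentile = 90,
                               normalize = TRUE) {
  metadata <- validate_metadata(metadata)
  if (normalize) table <- relative_normalize(table)
  D <- bray_curtis(table)
  reference_ids <- build_reference_set(metadata, min_week = min_week)
  .assert(length(reference_ids) > 0, "empty reference set")
  scores <- dysbiosis_score(D, metadata, reference_ids)
  threshold <- dysbiosis_threshold(scores, metadata, percentile = percentile)
  structure(list(
    scores = scores,
    threshold = threshold,
    dysbiotic = classify_dysbiosis(scores, threshold),
    reference_ids = reference_ids,
    min_week = min_week,
    percentile = percentile
  ), class = "dysbiosis_result")
}

#' @export
print.dysbiosis_result <- function(x, ...) {
  cat(sprintf("dysbiosis_result: %d samples, threshold %.4f, %d (%.1f%%) dysbiotic\n",
              length(x$scores), x$threshold, sum(x$dysbiotic),
              100 * mean(x$dysbiotic)))
  invisible(x)
}

#' Score a cohort against an external reference cohort
#'
#' Repeats the scoring with an external sample set as the reference (no
#' own-subject exclusion applies since reference subjects are disjoint). The
#' threshold is re-derived as the configured percentile of the
#' external-reference scores among the study's non-IBD samples, and Spearman
#' concordance with the internal-reference scores is reported.
#'
#' @param table study [abundance_table()].
#' @param external_table external reference [abundance_table()] (same feature
#'   space; missing features treated as absent).
#' @param metadata validated metadata for the study samples.
#' @param min_week,percentile,normalize as in [dysbiosis_classify()].
#' @return List: `scores`, `threshold`, `dysbiotic`, `internal` (the internal
#'   result), `spearman_rho`, `concordance` (odds ratio + Fisher p of the two
#'   classifications).
#' @export
score_against_external_reference <- function(table, external_table, metadata,
                                             min_week = 20, percentile = 90,
                                             normalize = TRUE) {
  metadata <- validate_metadata(metadata)
  if (normalize) {
    table <- relative_normalize(table)
    external_table <- relative_normalize(external_table)
  }
  features <- union(rownames(table), rownames(external_table))
  pad <- function(tab) {
    out <- matrix(0, length(features), ncol(tab),
                  dimnames = list(features, colnames(tab)))
    out[rownames(tab), ] <- unclass(tab)
    out
  }
  combined <- abundance_table(cbind(pad(table), pad(external_table)),
                              type = table_type(table))
  D <- bray_curtis(combined)
  ref <- colnames(external_table)
  scores <- vapply(colnames(table), function(s) stats::median(D[s, ref]),
                   numeric(1))
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  nonibd <- scores[md$diagnosis == "nonIBD"]
  .assert(length(nonibd) > 0, "no non-IBD samples to derive the threshold from")
  threshold <- unname(stats::quantile(nonibd, percentile / 100, type = 7))
  dysbiotic <- classify_dysbiosis(scores, threshold)
  internal <- dysbiosis_classify(table, metadata, min_week = min_week,
                                 percentile = percentile, normalize = FALSE)
  conc <- cross_type_concordance(internal$dysbiotic[names(scores)], dysbiotic)
  list(scores = scores, threshold = threshold, dysbiotic = dysbiotic,
       internal = internal,
       spearman_rho = stats::cor(scores, internal$scores[names(scores)],
                                 method = "spearman"),
       concordance = conc)
}

#' Extract dysbiotic episodes and inter-episode intervals
#'
#' A duration runs from the first dysbiotic sample of an excursion to the
#' next non-dysbiotic sample; intervals are defined symmetrically for
#' eubiotic runs between excursions. Runs truncated by the end of a subject's
#' series are right-censored at the last sample. Runs already in progress at
#' the start of the series are dropped by default (their onset is
#' unobserved); `include_initial = "censor"` instead keeps them as censored
#' observations of their visible span.
#'
#' @param metadata validated sample metadata with a logical `dysbiotic`
#'   column.
#' @param include_initial `"drop"` (default) or `"censor"`.
#' @return data.frame of class `episode_set`: `subject_id`, `kind`
#'   (`duration`/`interval`), `length` (weeks), `censored`.
#' @export
extract_episodes <- function(metadata, include_initial = c("drop", "censor")) {
  include_initial <- match.arg(include_initial)
  metadata <- validate_metadata(metadata)
  .assert("dysbiotic" %in% names(metadata) && !anyNA(metadata$dysbiotic),
          "metadata needs a complete logical 'dysbiotic' column")
  out <- list()
  for (s in unique(metadata$subject_id)) {
    md <- metadata[metadata$subject_id == s, ]
    md <- md[order(md$week), ]
    r <- rle(as.logical(md$dysbiotic))
    k <- length(r$lengths)
    starts <- cumsum(c(1, r$lengths))[seq_len(k)]     # index of first sample of run
    start_week <- md$week[starts]
    next_start_week <- c(start_week[-1], NA)          # onset of the following run
    last_week <- md$week[nrow(md)]
    for (q in seq_len(k)) {
      censored <- q == k
      len <- if (censored) last_week - start_week[q] else next_start_week[q] - start_week[q]
      if (q == 1 && include_initial == "drop") next
      if (q == 1) censored <- TRUE                    # onset unobserved: keep as censored span
      if (len <= 0) next                              # single-sample censored run carries no length
      out[[length(out) + 1]] <- data.frame(
        subject_id = s,
        kind = if (r$values[q]) "duration" else "interval",
        length = len,
        censored = censored,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), kind = character(),
               length = numeric(), censored = logical())
  class(res) <- c("episode_set", class(res))
  res
}

#' Censored maximum-likelihood mean of an exponential distribution
#'
#' For exponentially distributed episode lengths with right-censoring, the
#' MLE of the mean is the total observed time (censored spans included)
#' divided by the number of uncensored episodes; its standard error is
#' `mean / sqrt(n_uncensored)`. Incorporating censored spans avoids
#' underestimating durations due to limited observation time.
#'
#' @param lengths numeric episode lengths (weeks), or an `episode_set`
#'   data.frame with `length`/`censored` columns.
#' @param censored logical vector (ignored when `lengths` is an
#'   `episode_set`).
#' @return List: `mean`, `se`, `n`, `n_uncensored`.
#' @export
censored_exponential_mean <- function(lengths, censored = NULL) {
  if (is.data.frame(lengths)) {
    censored <- lengths$censored
    lengths <- lengths$length
  }
  censored <- censored %||% rep(FALSE, length(lengths))
  .assert(length(lengths) == length(censored), "lengths/censored mismatch")
  .assert(all(lengths > 0), "episode lengths must be positive")
  n_unc <- sum(!censored)
  if (n_unc == 0) stop("no uncensored episodes: mean is not identifiable", call. = FALSE)
  m <- sum(lengths) / n_unc
  list(mean = m, se = m / sqrt(n_unc), n = length(lengths), n_uncensored = n_unc)
}

#' Kaplan-Meier survival curve of episode lengths
#'
#' Product-limit estimator (events precede censorings at tied times), via the
#' standard survival machinery.
#'
#' @param lengths numeric episode lengths, or an `episode_set` data.frame.
#' @param censored logical vector (ignored for `episode_set` input).
#' @return data.frame with columns `time`, `survival`, `n_risk`, `n_event`.
#' @export
kaplan_meier <- function(lengths, censored = NULL) {
  if (is.data.frame(lengths)) {
    censored <- lengths$censored
    lengths <- lengths$length
  }
  censored <- censored %||% rep(FALSE, length(lengths))
  fit <- survival::survfit(survival::Surv(lengths, !censored) ~ 1)
  data.frame(time = fit$time, survival = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event)
}

#' Concordance of dysbiosis calls between two measurement types
#'
#' 2x2 contingency of matched classifications; sample odds ratio
#' (Haldane-Anscombe 0.5 correction only when a margin is zero) and Fisher's
#' exact p from the hypergeometric tail.
#'
#' @param class_a,class_b logical classification vectors of equal length
#'   (already matched sample-to-sample).
#' @return List: `odds_ratio`, `p`, `table`.
#' @export
cross_type_concordance <- function(class_a, class_b) {
  .assert(length(class_a) == length(class_b), "classifications must be matched")
  tab <- table(factor(class_a, levels = c(TRUE, FALSE)),
               factor(class_b, levels = c(TRUE, FALSE)))
  t2 <- tab
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = unname(or), p = p, table = tab)
}
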