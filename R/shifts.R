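#' @noRd
.kde_bandwidth <- function(x, sj_min = 20) {
  if (length(x) >= sj_min) {
    bw <- tryCatch(stats::bw.SJ(x), error = function(e) NULL)
    if (!is.null(bw)) return(list(bw = bw, rule = "SJ"))
  }
  list(bw = stats::bw.nrd0(x), rule = "nrd0")
}

#' @noRd
.density_crossing <- function(intra, inter, grid_n = 512L) {
  bwa <- .kde_bandwidth(intra)
  bwe <- .kde_bandwidth(inter)
  da <- stats::density(intra, bw = bwa$bw, from = 0, to = 1, n = grid_n)
  de <- stats::density(inter, bw = bwe$bw, from = 0, to = 1, n = grid_n)
  mode_idx <- which.max(da$y)
  diff_y <- de$y - da$y
  above <- which(seq_len(grid_n) > mode_idx & diff_y > 0)
  if (length(above) == 0) {
    thr <- 1
  } else {
    k <- above[1]
    if (k == 1 || diff_y[k - 1] > 0) {
      thr <- da$x[k]
    } else {
      # linear interpolation of the crossing between grid points k-1 and k
      x0 <- da$x[k - 1]; x1 <- da$x[k]
      y0 <- diff_y[k - 1]; y1 <- diff_y[k]
      thr <- x0 + (0 - y0) / (y1 - y0) * (x1 - x0)
    }
  }
  list(threshold = min(max(thr, 0), 1), bw_intra = bwa, bw_inter = bwe,
       mode = da$x[mode_idx])
}

#' Fit the time-gap-dependent microbiome shift threshold curve
#'
#' For each time-gap window, Gaussian kernel density estimates are built for
#' the within-subject dissimilarities of non-IBD subjects in that window and
#' for the pooled between-subject non-IBD dissimilarities. The raw threshold
#' is the smallest dissimilarity above the intra-individual density mode at
#' which the inter-individual density exceeds the intra-individual density;
#' the final curve is the running maximum over increasing time gaps, since a
#' community naturally diverges from itself over time and the shift boundary
#' must be monotone nondecreasing.
#'
#' @param pairs pair set from [build_pair_sets()] restricted to non-IBD
#'   subjects' samples; within-subject rows supply the windowed intra
#'   dissimilarities, `inter` rows the pooled inter dissimilarities.
#' @param sampling_interval window spacing in weeks (default 2); windows are
#'   centered on its multiples.
#' @param min_pairs minimum intra pairs per window; sparser windows are
#'   pooled upward into the next window (default 30).
#' @param grid_n density grid resolution on `[0, 1]` (default 512).
#' @param consecutive_intra_only use only consecutive within-subject pairs
#'   for the intra densities (default FALSE: all within-subject pairs, each
#'   in its own time-gap window).
#' @return Object of class `shift_threshold_curve`: data.frame `windows`
#'   (`center`, `n_pairs`, `raw`, `threshold`, `bandwidth_rule`), the pooled
#'   inter bandwidth, and parameters.
#' @export
fit_threshold_curve <- function(pairs, sampling_interval = 2, min_pairs = 30,
                                grid_n = 512L, consecutive_intra_only = FALSE) {
  intra <- pairs[pairs$relation != "inter", ]
  if (consecutive_intra_only) intra <- intra[intra$relation == "intra-consecutive", ]
  intra <- intra[intra$dt > 0, ]
  inter <- pairs$dissimilarity[pairs$relation == "inter"]
  .assert(nrow(intra) > 0, "no within-subject pairs to fit the threshold curve")
  .assert(length(inter) > 0, "no between-subject pairs to fit the threshold curve")

  center <- pmax(round(intra$dt / sampling_interval), 1) * sampling_interval
  centers <- sort(unique(center))
  # pool sparse windows upward (the last window pools downward)
  assigned <- center
  counts <- table(factor(assigned, levels = centers))
  kept <- centers
  k <- 1
  while (k < length(kept)) {
    if (sum(assigned == kept[k]) < min_pairs) {
      assigned[assigned == kept[k]] <- kept[k + 1]
      kept <- kept[-k]
    } else k <- k + 1
  }
  if (length(kept) > 1 && sum(assigned == kept[length(kept)]) < min_pairs) {
    assigned[assigned == kept[length(kept)]] <- kept[length(kept) - 1]
    kept <- kept[-length(kept)]
  }

  rows <- lapply(kept, function(ct) {
    d <- intra$dissimilarity[assigned == ct]
    cr <- .density_crossing(d, inter, grid_n = grid_n)
    data.frame(center = ct, n_pairs = length(d), raw = cr$threshold,
               bandwidth_rule = cr$bw_intra$rule, bandwidth = cr$bw_intra$bw,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  win <- win[order(win$center), ]
  win$threshold <- cummax(win$raw)
  structure(list(windows = win,
                 sampling_interval = sampling_interval,
                 min_pairs = min_pairs, grid_n = grid_n,
                 inter_bandwidth = .kde_bandwidth(inter)),
            class = "shift_threshold_curve")
}

#' Evaluate a shift threshold curve at given time gaps
#'
#' Each gap maps to the nearest retained window center (gaps beyond the last
#' window use the last threshold).
#'
#' @param curve a `shift_threshold_curve`.
#' @param dt numeric time gaps (weeks).
#' @return Numeric thresholds.
#' @export
threshold_at <- function(curve, dt) {
  w <- curve$windows
  idx <- vapply(dt, function(g) which.min(abs(w$center - g)), integer(1))
  w$threshold[idx]
}

#' Call microbiome shifts between consecutive samples
#'
#' A shift is a consecutive within-subject sample pair whose dissimilarity
#' exceeds the threshold for its time gap, i.e. the pair looks more like a
#' comparison between different people than within one person.
#'
#' @param pairs pair set from [build_pair_sets()]; only `intra-consecutive`
#'   rows with `dt > 0` are considered.
#' @param curve a `shift_threshold_curve` (or a single numeric threshold, the
#'   time-gap-independent variant).
#' @return data.frame of calls: the qualifying pair rows plus their
#'   `threshold`.
#' @export
call_shifts <- function(pairs, curve) {
  cand <- pairs[pairs$relation == "intra-consecutive" & pairs$dt > 0, ]
  thr <- if (inherits(curve, "shift_threshold_curve")) {
    threshold_at(curve, cand$dt)
  } else {
    rep(as.numeric(curve), nrow(cand))
  }
  out <- cand[cand$dissimilarity > thr, , drop = FALSE]
  out$threshold <- thr[cand$dissimilarity > thr]
  rownames(out) <- NULL
  out
}

#' Rank feature contributions to one shift
#'
#' Per-feature signed abundance change from the earlier to the later sample;
#' the primary contributor is the feature with the largest absolute change,
#' ties broken towards the lexicographically smaller feature ID.
#'
#' @param from_id,to_id sample IDs of the pair (earlier, later).
#' @param table the [abundance_table()] the dissimilarities came from.
#' @return data.frame `feature`, `delta`, sorted by decreasing `|delta|`
#'   (ties by feature ID); the first row is the primary contributor.
#' @export
attribute_shift <- function(from_id, to_id, table) {
  delta <- unclass(table)[, to_id] - unclass(table)[, from_id]
  ord <- order(-abs(delta), names(delta))
  data.frame(feature = names(delta)[ord], delta = unname(delta[ord]),
             stringsAsFactors = FALSE)
}

#' Annotate shift calls with their primary contributors
#'
#' @param calls output of [call_shifts()].
#' @param table the [abundance_table()].
#' @param metadata validated metadata (orders each pair by week).
#' @return `calls` with `week_from`, `week_to`, `primary_contributor`,
#'   `primary_delta` columns.
#' @export
attribute_shifts <- function(calls, table, metadata) {
  metadata <- validate_metadata(metadata)
  wk <- metadata$week[match(calls$sample_i, metadata$sample_id)]
  wk2 <- metadata$week[match(calls$sample_j, metadata$sample_id)]
  from <- ifelse(wk <= wk2, calls$sample_i, calls$sample_j)
  to <- ifelse(wk <= wk2, calls$sample_j, calls$sample_i)
  prim <- character(nrow(calls)); pd <- numeric(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    contrib <- attribute_shift(from[k], to[k], table)
    prim[k] <- contrib$feature[1]
    pd[k] <- contrib$delta[1]
  }
  calls$week_from <- pmin(wk, wk2)
  calls$week_to <- pmax(wk, wk2)
  calls$primary_contributor <- prim
  calls$primary_delta <- pd
  calls
}

#' Shift rate per group, in shifts per year
#'
#' Number of calls divided by the total observed consecutive-pair time in the
#' group (52 weeks per year).
#'
#' @param calls output of [call_shifts()].
#' @param pairs the full consecutive pair set the calls were made from.
#' @param metadata validated metadata (maps subjects to diagnosis groups).
#' @return Named numeric vector of rates per diagnosis group.
#' @export
shift_rate <- function(calls, pairs, metadata) {
  metadata <- validate_metadata(metadata)
  cand <- pairs[pairs$relation == "intra-consecutive" & pairs$dt > 0, ]
  dx_pairs <- metadata$diagnosis[match(cand$subject_id, metadata$subject_id)]
  dx_calls <- metadata$diagnosis[match(calls$subject_id, metadata$subject_id)]
  groups <- sort(unique(dx_pairs))
  rates <- vapply(groups, function(g) {
    obs_years <- sum(cand$dt[dx_pairs == g]) / 52
    if (obs_years == 0) return(0)
    sum(dx_calls == g, na.rm = TRUE) / obs_years
  }, numeric(1))
  names(rates) <- groups
  rates
}

#' Single (time-gap-independent) shift threshold
#'
#' The density-crossing rule applied once to the pooled within-subject
#' dissimilarities, used for measurement types that lack a clear upward
#' divergence trend (e.g. metabolite profiles).
#'
#' @param intra numeric within-subject dissimilarities (non-IBD).
#' @param inter numeric between-subject dissimilarities (non-IBD).
#' @param grid_n density grid resolution (default 512).
#' @return List: `threshold`, bandwidths used.
#' @export
single_threshold_variant <- function(intra, inter, grid_n = 512L) {
  .assert(length(intra) > 0 && length(inter) > 0,
          "need intra and inter dissimilarities")
  cr <- .density_crossing(intra, inter, grid_n = grid_n)
  list(threshold = cr$threshold, bw_intra = cr$bw_intra, bw_inter = cr$bw_inter)
}

#' Subject-weighted kernel density estimate
#'
#' Each observation is weighted by the inverse of its subject's sample count
#' (weights normalized to sum to 1), so densely sampled subjects do not
#' dominate the density. Bandwidth by the Sheather-Jones method, with the
#' Silverman rule as a small-sample fallback.
#'
#' @param values numeric observations.
#' @param subject_ids subject of each observation.
#' @param n grid size (default 512).
#' @param from,to optional grid range.
#' @return A `stats::density` object (with `bw_rule` attribute).
#' @export
weighted_density <- function(values, subject_ids, n = 512, from = NULL, to = NULL) {
  .assert(length(values) == length(subject_ids), "values/subjects mismatch")
  counts <- table(subject_ids)
  w <- 1 / as.numeric(counts[as.character(subject_ids)])
  w <- w / sum(w)
  bw <- .kde_bandwidth(values)
  args <- list(x = values, weights = w, bw = bw$bw, n = n)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  attr(d, "bw_rule") <- bw$rule
  d
}
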