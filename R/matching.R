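#' Lenient temporal matching of samples across measurement types
#'
#' Greedy construction of matched multi-omic sample sets for one subject.
#' Repeatedly: (1) find the earliest time window of width `window` (window
#' starts scanned over the sorted union of remaining sample weeks — any
#' feasible window can be slid left onto a sample week) in which every
#' measurement type still has at least one sample; (2) within the window,
#' take as target the week at which the most measurement types have a sample
#' exactly, ties towards earlier weeks; (3) for each type select the
#' remaining sample nearest the target within the window, ties towards
#' earlier; (4) for each type discard every sample up to and including the
#' later of its selected sample and the target. Each sample therefore joins
#' at most one matched set.
#'
#' @param week_lists named list of sorted numeric week vectors, one per
#'   measurement type.
#' @param window window width in weeks (0 = strict co-occurrence; typical
#'   values 0, 2, 4).
#' @return data.frame with one row per matched set: `target_week`,
#'   `window_start`, and one `<type>_week` column per type. Zero rows when
#'   any type list is empty or no window exists.
#' @export
match_samples <- function(week_lists, window) {
  .assert(window >= 0, "window width must be nonnegative")
  .assert(length(week_lists) >= 1, "need at least one measurement type")
  types <- names(week_lists)
  .assert(!is.null(types) && all(nzchar(types)), "week lists must be named by type")
  remaining <- lapply(week_lists, function(w) sort(as.numeric(w)))
  matches <- list()

  repeat {
    if (any(vapply(remaining, length, integer(1)) == 0)) break
    starts <- sort(unique(unlist(remaining)))
    feasible <- NA
    for (t0 in starts) {
      ok <- all(vapply(remaining, function(w) any(w >= t0 & w <= t0 + window),
                       logical(1)))
      if (ok) { feasible <- t0; break }
    }
    if (is.na(feasible)) break
    in_win <- sort(unique(unlist(lapply(remaining, function(w)
      w[w >= feasible & w <= feasible + window]))))
    counts <- vapply(in_win, function(x)
      sum(vapply(remaining, function(w) x %in% w, logical(1))), integer(1))
    target <- in_win[which.max(counts)]  # which.max takes the earliest on ties

    selected <- vapply(types, function(ty) {
      w <- remaining[[ty]]
      cand <- w[w >= feasible & w <= feasible + window]
      cand[order(abs(cand - target), cand)][1]
    }, numeric(1))

    for (ty in types) {
      cutoff <- max(selected[[ty]], target)
      remaining[[ty]] <- remaining[[ty]][remaining[[ty]] > cutoff]
    }
    row <- as.data.frame(as.list(selected))
    names(row) <- paste0(types, "_week")
    row$target_week <- target
    row$window_start <- feasible
    matches[[length(matches) + 1]] <- row
  }

  if (length(matches) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(types)),
                                  paste0(types, "_week")))
    out$target_week <- numeric(0)
    out$window_start <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, matches)
  rownames(out) <- NULL
  out[, c("target_week", "window_start", paste0(types, "_week"))]
}

#' Match samples across measurement types for every subject
#'
#' @param metadata_by_type named list of validated metadata data.frames, one
#'   per measurement type.
#' @param window window width in weeks.
#' @return data.frame: `subject_id`, `target_week`, `window_start`, and per
#'   type `<type>_week` and `<type>_sample` columns.
#' @export
match_cohort <- function(metadata_by_type, window) {
  types <- names(metadata_by_type)
  subjects <- sort(Reduce(intersect,
                          lapply(metadata_by_type, function(m) unique(m$subject_id))))
  out <- list()
  for (s in subjects) {
    weeks <- lapply(metadata_by_type, function(m) sort(m$week[m$subject_id == s]))
    ms <- match_samples(weeks, window)
    if (nrow(ms) == 0) next
    ms$subject_id <- s
    for (ty in types) {
      m <- metadata_by_type[[ty]]
      ms[[paste0(ty, "_sample")]] <-
        m$sample_id[match(paste(s, ms[[paste0(ty, "_week")]]),
                          paste(m$subject_id, m$week))]
    }
    out[[s]] <- ms
  }
  if (length(out) == 0) {
    return(data.frame(subject_id = character(), target_week = numeric(),
                      window_start = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("subject_id", "target_week", "window_start",
          paste0(rep(types, each = 2), c("_week", "_sample")))]
}

#' Multi-omic completeness report
#'
#' For each requested measurement-type subset and window width, the number
#' of matched sets obtainable across the cohort. Counts are nondecreasing in
#' the window width.
#'
#' @param metadata_by_type named list of validated metadata, one per type.
#' @param type_subsets list of character vectors of type names (default: all
#'   types jointly).
#' @param windows numeric window widths (default `c(0, 2, 4)`).
#' @return data.frame: `types`, `window`, `n_matched`.
#' @export
completeness_report <- function(metadata_by_type,
                                type_subsets = list(names(metadata_by_type)),
                                windows = c(0, 2, 4)) {
  rows <- list()
  for (subset in type_subsets) {
    .assert(all(subset %in% names(metadata_by_type)),
            "unknown measurement type in subset")
    for (w in windows) {
      m <- match_cohort(metadata_by_type[subset], w)
      rows[[length(rows) + 1]] <- data.frame(
        types = paste(subset, collapse = "+"), window = w,
        n_matched = nrow(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
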