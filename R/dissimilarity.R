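#' Pairwise Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` over features, computed for every
#' pair of samples. Zero-sum samples are rejected (undefined denominator).
#'
#' @param table an [abundance_table()] (features x samples).
#' @return Symmetric sample-by-sample matrix with zero diagonal, entries in
#'   `[0, 1]`, with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop(sprintf("zero-sum sample(s) have undefined Bray-Curtis: %s",
                 paste(colnames(table)[cs == 0], collapse = ", ")), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
  diag(d) <- 0
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Ordinal Manhattan distance between dietary questionnaires
#'
#' Intake-frequency levels are ordered from less to more frequent, coded as
#' consecutive integers, and compared with the L1 (Manhattan) distance.
#'
#' @param dietary_table matrix or data.frame, samples in rows, diet items in
#'   columns; cells are level labels.
#' @param level_order character vector giving the levels from least to most
#'   frequent.
#' @return Symmetric sample-by-sample distance matrix with attribute
#'   `metric = "ordinal-manhattan"`.
#' @export
ordinal_manhattan <- function(dietary_table, level_order) {
  m <- as.matrix(dietary_table)
  unknown <- setdiff(unique(as.vector(m)), level_order)
  if (length(unknown) > 0) {
    stop(sprintf("unknown dietary level(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  coded <- matrix(match(m, level_order), nrow = nrow(m),
                  dimnames = dimnames(m))
  d <- as.matrix(stats::dist(coded, method = "manhattan"))
  attr(d, "metric") <- "ordinal-manhattan"
  d
}

#' Decompose sample pairs into within- and between-subject sets
#'
#' Every unordered sample pair is annotated with its dissimilarity, time gap,
#' and relation: `intra-consecutive` (adjacent time points of one subject),
#' `intra-any` (same subject, non-adjacent), or `inter` (different subjects).
#' Identical-week duplicates (technical replicates) form valid intra pairs
#' with a time gap of 0.
#'
#' @param D square dissimilarity matrix with sample IDs as dimnames.
#' @param metadata validated sample metadata covering the samples of `D`.
#' @param consecutive_only if `TRUE`, drop non-adjacent within-subject pairs.
#' @param include_inter if `FALSE`, omit between-subject pairs (saves memory
#'   on large cohorts when only within-subject pairs are needed).
#' @return data.frame with columns `sample_i`, `sample_j`, `dissimilarity`,
#'   `dt` (weeks), `relation`, `subject_id` (NA for inter pairs).
#' @export
build_pair_sets <- function(D, metadata, consecutive_only = FALSE,
                            include_inter = TRUE) {
  metadata <- validate_metadata(metadata)
  ids <- colnames(D)
  .assert(all(ids %in% metadata$sample_id), "samples in D missing from metadata")
  md <- metadata[match(ids, metadata$sample_id), ]
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- md$subject_id[i] == md$subject_id[j]
  if (!include_inter) {
    keep <- same
    i <- i[keep]; j <- j[keep]; same <- same[keep]
  }
  dt <- abs(md$week[i] - md$week[j])

  # time-point rank within subject (ties share a rank, so identical-week
  # technical replicates count as consecutive with dt = 0)
  pos <- stats::ave(md$week, md$subject_id,
                    FUN = function(w) match(w, sort(unique(w))))
  consec <- same & abs(pos[i] - pos[j]) <= 1

  relation <- ifelse(!same, "inter", ifelse(consec, "intra-consecutive", "intra-any"))
  out <- data.frame(
    sample_i = ids[i], sample_j = ids[j],
    dissimilarity = D[cbind(i, j)],
    dt = dt,
    relation = relation,
    subject_id = ifelse(same, md$subject_id[i], NA_character_),
    stringsAsFactors = FALSE
  )
  if (consecutive_only) out <- out[out$relation != "intra-any", ]
  rownames(out) <- NULL
  out
}

#' Per-subject mean profiles
#'
#' The feature-wise mean over all of a subject's samples. Means of
#' compositions already sum to 1, so no renormalization is applied.
#'
#' @param table an [abundance_table()].
#' @param metadata validated sample metadata.
#' @return An [abundance_table()] with one column per subject.
#' @export
subject_mean_profiles <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  .assert(!anyNA(md$subject_id), "samples in table missing from metadata")
  subjects <- unique(md$subject_id)
  out <- vapply(subjects, function(s) {
    rowMeans(unclass(table)[, md$subject_id == s, drop = FALSE])
  }, numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), subjects))
  abundance_table(out, type = table_type(table))
}
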