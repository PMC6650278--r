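#' Construct a feature-by-sample abundance table
#'
#' The substrate of every stage of the pipeline: a nonnegative numeric matrix
#' with unique feature rownames and sample colnames, tagged with a measurement
#' type. Taxonomic feature IDs may carry a pipe-delimited lineage
#' (`k__...|p__...|...|s__species`).
#'
#' @param x numeric matrix, features in rows, samples in columns.
#' @param type measurement-type tag, one of `"MGX-taxa"`, `"MTX"`, `"MPX"`,
#'   `"MBX"`, `"other"`.
#' @return A validated matrix of class `abundance_table` with a `type`
#'   attribute.
#' @export
abundance_table <- function(x, type = c("other", "MGX-taxa", "MTX", "MPX", "MBX")) {
  type <- match.arg(type)
  .assert(is.matrix(x) && is.numeric(x), "abundance table must be a numeric matrix")
  .assert((nrow(x) == 0 || !is.null(rownames(x))) && !is.null(colnames(x)),
          "abundance table requires feature rownames and sample colnames")
  .assert(!anyDuplicated(rownames(x)), "duplicate feature IDs")
  .assert(!anyDuplicated(colnames(x)), "duplicate sample IDs")
  .assert(all(is.finite(x)), "non-finite abundance values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  structure(x, type = type, class = c("abundance_table", class(x)))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s]: %d features x %d samples\n",
              attr(x, "type"), nrow(x), ncol(x)))
  invisible(x)
}

#' Measurement type of an abundance table
#' @param table an `abundance_table`.
#' @return The type tag.
#' @export
table_type <- function(table) attr(table, "type") %||% "other"

#' Read a feature-by-sample profile TSV
#'
#' Expects a header row, feature IDs in the first column and one column per
#' sample (the MetaPhlAn-style layout). Malformed input (duplicate IDs,
#' negative or non-numeric cells) raises an error naming the offending
#' row/column.
#'
#' @param path file path.
#' @param type measurement-type tag to attach.
#' @return An [abundance_table()].
#' @export
read_profile_tsv <- function(path, type = "other") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  .assert(ncol(raw) >= 2, "profile TSV needs a feature-ID column plus sample columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate feature IDs in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 ids[bad[1]], colnames(num)[bad[2]]), call. = FALSE)
  }
  abundance_table(num, type = type)
}

#' Write a profile TSV
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param id_column name for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(table, path, id_column = "feature_id") {
  df <- data.frame(rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' Required columns: `sample_id`, `subject_id`, `week` (weeks since the
#' subject's first stool sample), `diagnosis` (`nonIBD`/`UC`/`CD`). Optional:
#' `dysbiotic` and arbitrary covariates.
#'
#' @param metadata data.frame.
#' @return The validated data.frame (diagnosis as character).
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "subject_id", "week", "diagnosis")
  missing_cols <- setdiff(need, names(metadata))
  .assert(length(missing_cols) == 0,
          paste("metadata missing columns:", paste(missing_cols, collapse = ", ")))
  .assert(!anyDuplicated(metadata$sample_id), "duplicate sample_id in metadata")
  .assert(all(metadata$week >= 0), "negative week in metadata")
  metadata$diagnosis <- as.character(metadata$diagnosis)
  .assert(all(metadata$diagnosis %in% c("nonIBD", "UC", "CD")),
          "diagnosis must be one of nonIBD, UC, CD")
  dx <- tapply(metadata$diagnosis, metadata$subject_id,
               function(d) length(unique(d)))
  .assert(all(dx == 1), "diagnosis must be constant within subject")
  metadata
}

#' Filter MetaPhlAn-style lineage rows to species level
#'
#' Keeps rows whose pipe-delimited lineage terminates at the species rank
#' (`s__`), dropping higher ranks and strain-level (`t__`) rows.
#'
#' @param table an [abundance_table()] with lineage feature IDs.
#' @return The species-level subset.
#' @export
filter_species_level <- function(table) {
  last_rank <- vapply(strsplit(rownames(table), "|", fixed = TRUE),
                      function(p) p[length(p)], character(1))
  keep <- startsWith(last_rank, "s__")
  abundance_table(unclass(table)[keep, , drop = FALSE], type = table_type(table))
}

#' Total-sum scale each sample to relative abundances
#'
#' @param table an [abundance_table()].
#' @return Table with every sample summing to 1. All-zero samples are
#'   rejected.
#' @export
relative_normalize <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop(sprintf("cannot normalize all-zero sample(s): %s",
                 paste(colnames(table)[cs == 0], collapse = ", ")), call. = FALSE)
  }
  abundance_table(sweep(unclass(table), 2, cs, "/"), type = table_type(table))
}

#' Arcsine square-root transform for relative abundances
#'
#' @param table an [abundance_table()] with values in `[0, 1]`.
#' @return Elementwise `asin(sqrt(x))`.
#' @export
arcsinsqrt_transform <- function(table) {
  .assert(all(table >= 0 & table <= 1),
          "arcsine square-root transform requires values in [0, 1]")
  out <- asin(sqrt(unclass(table)))
  abundance_table(out, type = table_type(table))
}

#' Log transform with pseudocount
#'
#' `log(x + pseudocount)` elementwise, the transform used for metabolite and
#' protein intensities (pseudocount 1 so that zeros map to 0).
#'
#' @param table an [abundance_table()].
#' @param pseudocount nonnegative offset, default 1.
#' @return Transformed matrix (plain, may be negative).
#' @export
log_pseudocount_transform <- function(table, pseudocount = 1) {
  .assert(pseudocount >= 0, "pseudocount must be nonnegative")
  log(unclass(table) + pseudocount)
}

#' Log transform without pseudocount, dropping non-finite results
#'
#' Used for expression (transcription) ratios: zero or missing ratios produce
#' non-finite logs, which are removed.
#'
#' @param values numeric vector.
#' @return Named numeric vector of finite `log(values)`.
#' @export
log_ratio_transform <- function(values) {
  out <- suppressWarnings(log(values))
  out[is.finite(out)]
}

#' Remove zero-variance and highly zero-inflated features
#'
#' Features with more than `max_zero_frac` zeros, or with no variance, are
#' removed before model fitting.
#'
#' @param table an [abundance_table()].
#' @param max_zero_frac maximum tolerated zero fraction (default 0.9; a
#'   feature zero in exactly 90% of samples is retained).
#' @return Filtered table (possibly with zero rows, with a warning).
#' @export
prevalence_variance_filter <- function(table, max_zero_frac = 0.9) {
  zero_frac <- rowMeans(unclass(table) == 0)
  v <- apply(unclass(table), 1, stats::var)
  keep <- zero_frac <= max_zero_frac & v > 0
  if (!any(keep)) warning("prevalence/variance filter removed every feature")
  abundance_table(unclass(table)[keep, , drop = FALSE], type = table_type(table))
}

#' Gini-Simpson alpha diversity
#'
#' `1 - sum(p_i^2)` with `p` the relative abundances of one sample.
#'
#' @param sample numeric vector of nonnegative abundances (normalized
#'   internally).
#' @return Diversity in `[0, 1]`.
#' @export
gini_simpson <- function(sample) {
  .assert(length(sample) > 0 && sum(sample) > 0, "empty sample")
  .assert(all(sample >= 0), "negative abundance")
  p <- sample / sum(sample)
  1 - sum(p^2)
}

#' Per-sample species transcription ratio
#'
#' The summed clade-stratified metatranscriptomic relative abundance divided
#' by the summed metagenomic relative abundance. Samples where the clade is
#' absent from the metagenome get `NA` (missing, not an error).
#'
#' @param mtx_table,mgx_table sum-normalized, clade-stratified
#'   [abundance_table()]s; stratified feature IDs are `clade|feature` (or the
#'   bare clade).
#' @param clade clade identifier.
#' @return Named numeric vector of ratios over the shared samples.
#' @export
transcription_ratio <- function(mtx_table, mgx_table, clade) {
  samples <- intersect(colnames(mtx_table), colnames(mgx_table))
  .assert(length(samples) > 0, "no shared samples between MTX and MGX tables")
  pick <- function(tab) {
    ids <- rownames(tab)
    hit <- ids == clade | startsWith(ids, paste0(clade, "|"))
    colSums(unclass(tab)[hit, samples, drop = FALSE])
  }
  num <- pick(mtx_table)
  den <- pick(mgx_table)
  ratio <- ifelse(den == 0, NA_real_, num / den)
  names(ratio) <- samples
  ratio
}
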