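#' Build the differential-abundance design matrix
#'
#' Fixed effects: intercept + diagnosis (non-IBD reference) + dysbiosis
#' nested within diagnosis + antibiotic use + consent age + recruitment site
#' (as a fixed categorical covariate; the subject random intercept is the
#' model's single variance component). Covariate columns absent from the
#' metadata, and factor columns with a single observed level, are skipped.
#'
#' @param metadata validated sample metadata; the dysbiosis indicator column
#'   is named by `dysbiosis_col`.
#' @param dysbiosis_col name of the logical dysbiosis column (default
#'   `"dysbiotic"`); `NULL` omits the nested dysbiosis terms.
#' @param covariates additional covariate columns to include when present.
#' @return Design matrix with informative column names.
#' @export
build_da_design <- function(metadata, dysbiosis_col = "dysbiotic",
                            covariates = c("antibiotics", "consent_age", "site")) {
  df <- data.frame(diagnosis = factor(metadata$diagnosis,
                                      levels = c("nonIBD", "UC", "CD")))
  df$diagnosis <- droplevels(df$diagnosis)
  form <- "~ diagnosis"
  if (!is.null(dysbiosis_col)) {
    .assert(dysbiosis_col %in% names(metadata),
            sprintf("metadata lacks dysbiosis column '%s'", dysbiosis_col))
    df$dysbiotic <- as.logical(metadata[[dysbiosis_col]])
    form <- paste(form, "+ diagnosis:dysbiotic")
  }
  for (cv in covariates) {
    if (!cv %in% names(metadata)) next
    v <- metadata[[cv]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- droplevels(factor(v))
      if (nlevels(v) < 2) next
    }
    df[[cv]] <- v
    form <- paste(form, "+", cv)
  }
  if (nlevels(df$diagnosis) < 2) {
    form <- sub("~ diagnosis \\+ diagnosis:dysbiotic", "~ dysbiotic", form)
    form <- sub("~ diagnosis", "~ 1", form)
  }
  stats::model.matrix(stats::as.formula(form), df)
}

#' Per-feature differential abundance via the random-intercept mixed model
#'
#' Applies the type-appropriate transform (arcsine square root for relative
#' abundances, log with pseudocount 1 for intensity-like tables), fits
#' [lmm_fit()] per feature with the nested diagnosis/dysbiosis design, and
#' adjusts Wald p-values per model term across features with
#' Benjamini-Hochberg.
#'
#' @param table an [abundance_table()], already prevalence/variance
#'   filtered.
#' @param metadata validated metadata with a dysbiosis column.
#' @param transform `"arcsinsqrt"`, `"log1p"`, or `"none"` (default chosen
#'   from the table's measurement type).
#' @param dysbiosis_col name of the dysbiosis column.
#' @return data.frame: `feature`, `term`, `estimate`, `se`, `z`, `p`, `q`
#'   (BH within term).
#' @export
differential_abundance <- function(table, metadata,
                                   transform = NULL,
                                   dysbiosis_col = "dysbiotic") {
  metadata <- validate_metadata(metadata)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  transform <- transform %||%
    (if (table_type(table) %in% c("MGX-taxa", "MTX", "other")) "arcsinsqrt" else "log1p")
  Y <- switch(transform,
              arcsinsqrt = unclass(arcsinsqrt_transform(table)),
              log1p = log_pseudocount_transform(table, 1),
              none = unclass(table),
              stop("unknown transform", call. = FALSE))
  X <- build_da_design(md, dysbiosis_col = dysbiosis_col)
  rows <- list()
  for (f in rownames(Y)) {
    fit <- lmm_fit(Y[f, ], X, md$subject_id)
    keep <- names(fit$coefficients) != "(Intercept)"
    rows[[f]] <- data.frame(
      feature = f,
      term = names(fit$coefficients)[keep],
      estimate = unname(fit$coefficients[keep]),
      se = unname(fit$se[keep]),
      z = unname(fit$z[keep]),
      p = unname(fit$p[keep]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::ave(out$p, out$term, FUN = function(p) stats::p.adjust(p, "BH"))
  out
}

#' Residualize features for cross-measurement association testing
#'
#' Per-feature conditional residuals from the random-intercept model with
#' the stated covariates (age, sex, diagnosis, dysbiosis when
#' `adjust_for_dysbiosis`, antibiotic/immunosuppressant use, bowel surgery
#' status — those present in the metadata). Removing subject intercepts and
#' covariate effects leaves within-person variation over time, so downstream
#' correlations are not driven by inter-individual differences or disease
#' state. Subjects with fewer than `min_samples` samples are dropped for
#' longitudinal measurement types; baseline-only types use the fixed-effects
#' model without subject intercepts.
#'
#' @param table an [abundance_table()].
#' @param metadata validated metadata.
#' @param adjust_for_dysbiosis include the dysbiosis indicator as a covariate
#'   (default TRUE, the "adjusted" network; FALSE gives the "unadjusted"
#'   variant).
#' @param transform as in [differential_abundance()].
#' @param min_samples minimum samples per subject for longitudinal types
#'   (default 4).
#' @param longitudinal if FALSE, fit plain linear models without subject
#'   intercepts and skip the per-subject sample filter.
#' @param dysbiosis_col name of the dysbiosis column.
#' @return Matrix of residuals (features x retained samples).
#' @export
residualize <- function(table, metadata, adjust_for_dysbiosis = TRUE,
                        transform = NULL, min_samples = 4,
                        longitudinal = TRUE, dysbiosis_col = "dysbiotic") {
  metadata <- validate_metadata(metadata)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  if (longitudinal) {
    tab <- table(md$subject_id)
    keep <- md$subject_id %in% names(tab)[tab >= min_samples]
    .assert(any(keep), "no subjects with enough samples to residualize")
    table <- abundance_table(unclass(table)[, keep, drop = FALSE],
                             type = table_type(table))
    md <- md[keep, ]
  }
  transform <- transform %||%
    (if (table_type(table) %in% c("MGX-taxa", "MTX", "other")) "arcsinsqrt" else "log1p")
  Y <- switch(transform,
              arcsinsqrt = unclass(arcsinsqrt_transform(table)),
              log1p = log_pseudocount_transform(table, 1),
              none = unclass(table))
  X <- build_da_design(
    md,
    dysbiosis_col = if (adjust_for_dysbiosis) dysbiosis_col else NULL,
    covariates = c("consent_age", "sex", "antibiotics", "immunosuppressants",
                   "surgery", "site"))
  R <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (f in rownames(Y)) {
    if (longitudinal) {
      R[f, ] <- lmm_fit(Y[f, ], X, md$subject_id)$residuals
    } else {
      R[f, ] <- stats::lm.fit(X, Y[f, ])$residuals
    }
  }
  R
}

#' Cross-measurement-type Spearman association network
#'
#' All-against-all Spearman correlations between residualized features of
#' each pair of measurement types over their matched samples; p-values from
#' the t approximation, BH-adjusted within each type pair; edges kept below
#' the pair's FDR tier (a lenient tier for serology-like sparse types), then
#' ranked by ascending p (ties by decreasing `|rho|`) and truncated to the
#' top `top_k` per pair, optionally restricted to edges touching
#' dysbiosis-associated features. Hubs are nodes with at least `hub_degree`
#' retained edges.
#'
#' @param residuals_by_type named list of residual matrices (features x
#'   samples) as from [residualize()]; shared sample IDs define the matched
#'   sets.
#' @param fdr_standard FDR tier for ordinary type pairs (default 0.05).
#' @param fdr_serology FDR tier applied when a pair involves a type named in
#'   `serology_types` (default 0.25).
#' @param serology_types character vector of lenient-tier type names.
#' @param top_k maximum edges retained per type pair (default 300).
#' @param hub_degree minimum degree for the hub flag (default 20).
#' @param dysbiosis_features optional character vector; when given, retained
#'   edges must touch at least one of these features.
#' @param min_overlap minimum matched samples per pair (default 8).
#' @return List of class `association_network`: `edges` (source, target,
#'   types, rho, p, q), `nodes` (feature, type, degree, hub,
#'   dysbiosis_associated).
#' @export
spearman_network <- function(residuals_by_type,
                             fdr_standard = 0.05, fdr_serology = 0.25,
                             serology_types = "serology",
                             top_k = 300, hub_degree = 20,
                             dysbiosis_features = NULL,
                             min_overlap = 8) {
  types <- names(residuals_by_type)
  .assert(length(types) >= 2, "need at least two measurement types")
  edges <- list()
  for (i in seq_len(length(types) - 1)) {
    for (j in (i + 1):length(types)) {
      ta <- types[i]; tb <- types[j]
      A <- residuals_by_type[[ta]]; B <- residuals_by_type[[tb]]
      shared <- intersect(colnames(A), colnames(B))
      if (length(shared) < min_overlap) next
      n <- length(shared)
      rho <- stats::cor(t(A[, shared, drop = FALSE]),
                        t(B[, shared, drop = FALSE]), method = "spearman")
      r <- as.vector(rho)
      r_cl <- pmin(pmax(r, -0.9999999), 0.9999999)
      tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      df <- data.frame(
        source = rep(rownames(rho), times = ncol(rho)),
        target = rep(colnames(rho), each = nrow(rho)),
        type_source = ta, type_target = tb,
        rho = r, p = p, n = n, stringsAsFactors = FALSE)
      df$q <- stats::p.adjust(df$p, "BH")
      tier <- if (ta %in% serology_types || tb %in% serology_types)
        fdr_serology else fdr_standard
      df <- df[df$q < tier, , drop = FALSE]
      if (!is.null(dysbiosis_features)) {
        df <- df[df$source %in% dysbiosis_features |
                   df$target %in% dysbiosis_features, , drop = FALSE]
      }
      df <- df[order(df$p, -abs(df$rho)), , drop = FALSE]
      if (nrow(df) > top_k) df <- df[seq_len(top_k), , drop = FALSE]
      edges[[paste(ta, tb, sep = ":")]] <- df
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               type_source = character(), type_target = character(),
               rho = numeric(), p = numeric(), n = integer(), q = numeric())
  rownames(edges) <- NULL
  ends <- c(paste(edges$type_source, edges$source, sep = "|"),
            paste(edges$type_target, edges$target, sep = "|"))
  node_ids <- unique(ends)
  deg <- table(ends)
  nodes <- data.frame(
    node = node_ids,
    type = sub("\\|.*$", "", node_ids),
    feature = sub("^[^|]*\\|", "", node_ids),
    degree = as.integer(deg[node_ids]),
    stringsAsFactors = FALSE)
  nodes$hub <- nodes$degree >= hub_degree
  nodes$dysbiosis_associated <- if (is.null(dysbiosis_features)) {
    rep(NA, nrow(nodes))
  } else {
    nodes$feature %in% dysbiosis_features
  }
  structure(list(edges = edges, nodes = nodes,
                 params = list(fdr_standard = fdr_standard,
                               fdr_serology = fdr_serology, top_k = top_k,
                               hub_degree = hub_degree,
                               min_overlap = min_overlap)),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("association_network: %d edges over %d nodes (%d hubs)\n",
              nrow(x$edges), nrow(x$nodes), sum(x$nodes$hub)))
  invisible(x)
}
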