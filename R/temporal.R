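#' Least-squares power-law fit of dissimilarity versus time gap
#'
#' Fits `d(dt) = a * dt^b + c` by derivative-free least squares
#' (Nelder-Mead), multi-started over exponents `b` in `[0.05, 1]` with `a`
#' and `c` initialized by a conditional linear fit at each starting exponent
#' (the RSS surface is multimodal in `b`, so restarts rather than gradients).
#' A flat candidate (`a = 0`, `c = mean(d)`) guarantees the fit never exceeds
#' the flat model's residual sum of squares.
#'
#' @param dt numeric time gaps (weeks).
#' @param d numeric dissimilarities.
#' @param n_starts number of exponent starts (default 8).
#' @return List of class `powerlaw_fit`: `a`, `b`, `c`, `rss`, `rss_flat`,
#'   `n`.
#' @export
fit_powerlaw <- function(dt, d, n_starts = 8) {
  .assert(length(dt) == length(d), "dt/d length mismatch")
  .assert(length(d) >= 4, "need at least 4 pairs")
  .assert(length(unique(dt)) >= 2, "need at least 2 distinct time gaps")
  .assert(all(dt >= 0), "negative time gaps")

  rss_fun <- function(par) {
    a <- par[1]; b <- par[2]; cc <- par[3]
    pred <- a * dt^b + cc
    if (any(!is.finite(pred))) return(Inf)
    sum((d - pred)^2)
  }
  flat_rss <- sum((d - mean(d))^2)

  best <- list(par = c(0, 0.5, mean(d)), value = flat_rss)
  for (b0 in seq(0.05, 1, length.out = n_starts)) {
    x <- dt^b0
    cf <- tryCatch(stats::coef(stats::lm(d ~ x)), error = function(e) c(mean(d), 0))
    start <- c(unname(cf[2]), b0, unname(cf[1]))
    if (any(!is.finite(start))) start <- c(0, b0, mean(d))
    opt <- stats::optim(start, rss_fun, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$value < best$value) best <- opt
  }
  structure(list(a = best$par[1], b = best$par[2], c = best$par[3],
                 rss = min(best$value, flat_rss), rss_flat = flat_rss,
                 n = length(d)),
            class = "powerlaw_fit")
}

#' F-test of a power-law fit against a flat line
#'
#' Compares the 3-parameter power law with the 1-parameter flat model:
#' `F = ((RSS0 - RSS1)/2) / (RSS1/(n - 3))`.
#'
#' @param fit a `powerlaw_fit`.
#' @return List: `F`, `p`, degrees of freedom.
#' @export
powerlaw_vs_flat_test <- function(fit) {
  n <- fit$n
  .assert(n > 3, "need more than 3 observations for the F-test")
  df1 <- 2; df2 <- n - 3
  Fstat <- ((fit$rss_flat - fit$rss) / df1) / (fit$rss / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' F-test comparing power-law fits between groups
#'
#' Compares a single power law fit jointly to all groups (3 parameters)
#' against separate per-group fits (3 parameters each).
#'
#' @param pairs_by_group named list of data.frames with `dt` and
#'   `dissimilarity` columns, one per group (at least 2 groups).
#' @return List: `F`, `p`, per-group and joint fits.
#' @export
powerlaw_group_compare <- function(pairs_by_group) {
  .assert(length(pairs_by_group) >= 2, "need at least two groups to compare")
  joint_dt <- unlist(lapply(pairs_by_group, `[[`, "dt"))
  joint_d <- unlist(lapply(pairs_by_group, `[[`, "dissimilarity"))
  joint <- fit_powerlaw(joint_dt, joint_d)
  fits <- lapply(pairs_by_group, function(g) fit_powerlaw(g$dt, g$dissimilarity))
  rss_sep <- sum(vapply(fits, `[[`, numeric(1), "rss"))
  k_joint <- 3; k_sep <- 3 * length(fits)
  n <- length(joint_d)
  df1 <- k_sep - k_joint; df2 <- n - k_sep
  .assert(df2 > 0, "too few pairs for separate fits")
  Fstat <- ((joint$rss - rss_sep) / df1) / (rss_sep / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       joint = joint, fits = fits, df1 = df1, df2 = df2)
}

#' @noRd
.lower_tri <- function(M) M[lower.tri(M)]

#' Inter-individual Mantel test between subject-level dissimilarity matrices
#'
#' Pearson correlation of the off-diagonal entries; significance by free
#' permutation of subject labels in the second matrix. Variance explained is
#' the squared Mantel statistic.
#'
#' @param DA,DB square subject-by-subject dissimilarity matrices with
#'   matching dimnames.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return List of class `permutation_test`: `statistic` (r), `r2`, `p`,
#'   `n_perm`, `scheme`.
#' @export
mantel_inter <- function(DA, DB, n_perm = 999, seed = 1) {
  .assert(all(dim(DA) == dim(DB)), "matrix dimension mismatch")
  if (!is.null(rownames(DA)) && !is.null(rownames(DB))) {
    DB <- DB[rownames(DA), rownames(DA)]
  }
  obs <- stats::cor(.lower_tri(DA), .lower_tri(DB))
  n <- nrow(DA)
  ge <- with_stream(seed, "mantel-inter", {
    sum(vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      stats::cor(.lower_tri(DA), .lower_tri(DB[p, p])) >= obs
    }, logical(1)))
  })
  structure(list(statistic = obs, r2 = obs^2,
                 p = (1 + ge) / (1 + n_perm),
                 n_perm = n_perm, scheme = "free"),
            class = "permutation_test")
}

#' Intra-individual Mantel test restricted to within-subject distances
#'
#' The statistic is the Pearson correlation between the two matrices'
#' entries over within-subject sample pairs only; the null is generated by
#' permuting sample labels independently within each subject block of the
#' second matrix, so between-subject structure is never exchanged.
#'
#' @param DA,DB square sample-by-sample dissimilarity matrices with matching
#'   sample IDs as dimnames.
#' @param metadata validated sample metadata.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param audit if `TRUE`, attach the permutation matrix used for each
#'   permutation (subject-block contract can then be asserted).
#' @return `permutation_test` list (`scheme = "within-subject"`).
#' @export
mantel_intra <- function(DA, DB, metadata, n_perm = 999, seed = 1, audit = FALSE) {
  metadata <- validate_metadata(metadata)
  ids <- colnames(DA)
  .assert(identical(sort(ids), sort(colnames(DB))), "sample ID mismatch")
  DB <- DB[ids, ids]
  subj <- metadata$subject_id[match(ids, metadata$sample_id)]
  n <- length(ids)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- subj[idx[, 1]] == subj[idx[, 2]]
  ii <- idx[within, , drop = FALSE]
  .assert(nrow(ii) >= 3, "too few within-subject pairs")
  va <- DA[ii]
  obs <- stats::cor(va, DB[ii])
  blocks <- split(seq_len(n), subj)
  perms <- if (audit) vector("list", n_perm) else NULL
  ge <- with_stream(seed, "mantel-intra", {
    count <- 0L
    for (k in seq_len(n_perm)) {
      p <- seq_len(n)
      for (b in blocks) if (length(b) > 1) p[b] <- b[sample.int(length(b))]
      if (audit) perms[[k]] <- p
      if (stats::cor(va, DB[p, p][ii]) >= obs) count <- count + 1L
    }
    count
  })
  out <- structure(list(statistic = obs, r2 = obs^2,
                        p = (1 + ge) / (1 + n_perm),
                        n_perm = n_perm, scheme = "within-subject"),
                   class = "permutation_test")
  if (audit) {
    out$perms <- perms
    out$subjects <- subj
  }
  out
}

#' PERMANOVA with repeated-measures-aware permutation schemes
#'
#' Single-term distance-based variance decomposition: with the Gower-centered
#' matrix `G` of the squared dissimilarities and the hat matrix `H` of the
#' centered single-term design, `R2 = tr(HG)/tr(G)` and
#' `pseudo-F = (tr(HG)/m) / ((tr(G) - tr(HG))/(n - m - 1))`. The null
#' distribution respects the repeated-measures design: `within-subject`
#' permutes the variable within each subject's samples (time-varying
#' variables), `subject-relabel` permutes the subject-to-value map across
#' subjects and relabels samples (subject-constant variables), `free`
#' permutes unrestrictedly. Missing numeric covariate values are
#' mean-imputed.
#'
#' @param D square sample-by-sample dissimilarity matrix.
#' @param variable vector (factor/character/numeric) aligned with the
#'   columns of `D`, or the name of a metadata column.
#' @param metadata validated sample metadata.
#' @param scheme permutation scheme.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return `permutation_test` list with `statistic` (pseudo-F), `r2`, `p`,
#'   `df`, `scheme`.
#' @export
blocked_permanova <- function(D, variable, metadata,
                              scheme = c("within-subject", "subject-relabel", "free"),
                              n_perm = 999, seed = 1) {
  scheme <- match.arg(scheme)
  metadata <- validate_metadata(metadata)
  ids <- colnames(D)
  md <- metadata[match(ids, metadata$sample_id), ]
  if (is.character(variable) && length(variable) == 1 && variable %in% names(metadata)) {
    variable <- md[[variable]]
  }
  .assert(length(variable) == length(ids), "variable length must match samples")
  if (is.numeric(variable) && anyNA(variable)) {
    variable[is.na(variable)] <- mean(variable, na.rm = TRUE)
  }
  .assert(!anyNA(variable), "missing values in a non-numeric variable")

  n <- length(ids)
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  trG <- sum(diag(G))

  stat_fun <- function(v) {
    X <- stats::model.matrix(~v, data.frame(v = v))[, -1, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    qrx <- qr(Xc)
    m <- qrx$rank
    if (m == 0) return(c(NA, NA, 0))
    Q <- qr.Q(qrx)[, seq_len(m), drop = FALSE]
    ssb <- sum(Q * (G %*% Q))       # tr(H G)
    r2 <- ssb / trG
    Fs <- (ssb / m) / ((trG - ssb) / (n - m - 1))
    c(Fs, r2, m)
  }
  obs <- stat_fun(variable)
  .assert(!is.na(obs[1]), "variable has no variation")  # F may be Inf when R2 = 1

  subj <- md$subject_id
  blocks <- split(seq_len(n), subj)
  if (scheme == "subject-relabel") {
    per_subj <- tapply(as.character(variable), subj, function(v) {
      .assert(length(unique(v)) == 1,
              "subject-relabel scheme requires a subject-constant variable")
      v[1]
    })
    subjects <- names(per_subj)
  }
  perm_variable <- function() {
    switch(scheme,
      free = variable[sample.int(n)],
      "within-subject" = {
        v <- variable
        for (b in blocks) if (length(b) > 1) v[b] <- v[b][sample.int(length(b))]
        v
      },
      "subject-relabel" = {
        relab <- per_subj[sample.int(length(per_subj))]
        names(relab) <- subjects
        v <- relab[subj]
        if (is.numeric(variable)) as.numeric(v) else unname(v)
      })
  }
  ge <- with_stream(seed, "permanova", {
    count <- 0L
    for (k in seq_len(n_perm)) {
      s <- stat_fun(perm_variable())
      if (!is.na(s[1]) && s[1] >= obs[1]) count <- count + 1L
    }
    count
  })
  structure(list(statistic = obs[1], r2 = obs[2],
                 p = (1 + ge) / (1 + n_perm),
                 df = c(model = obs[3], residual = n - obs[3] - 1),
                 n_perm = n_perm, scheme = scheme),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test [%s]: statistic %.4f, R2 %.4f, p %.4g (%d perms)\n",
              x$scheme, x$statistic, x$r2, x$p, x$n_perm))
  invisible(x)
}
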