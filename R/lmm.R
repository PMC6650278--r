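#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + b[subject] + e`, `b ~ N(0, sigma2_subject)`,
#' `e ~ N(0, sigma2_resid)`. The restricted likelihood is profiled over the
#' variance ratio `theta = sigma2_subject / sigma2_resid`: for fixed `theta`
#' the GLS coefficients and both variances are closed-form (block structure
#' of `V = I + theta Z Z'` keeps everything O(n)), and `theta` is found by
#' golden-section search on the log scale over `[1e-8, 1e8]`. Wald z and p
#' per coefficient come from the asymptotic normal approximation.
#'
#' @param y numeric response.
#' @param X design matrix (including intercept). Rank-deficient designs are
#'   an error naming the aliased columns.
#' @param subject subject identifier per observation.
#' @return List of class `lmm_fit`: `coefficients`, `se`, `z`, `p`, `theta`,
#'   `sigma2_subject`, `sigma2_resid`, `residuals` (conditional, i.e. after
#'   removing fixed effects and subject BLUPs — orthogonal to the design
#'   columns), `ranef` (subject BLUPs), `reml` (profiled objective at the
#'   optimum), `n`.
#' @export
lmm_fit <- function(y, X, subject) {
  .assert(is.matrix(X), "X must be a design matrix")
  .assert(length(y) == nrow(X) && length(subject) == nrow(X),
          "y, X, subject must align")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; aliased columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  subject <- as.character(subject)
  blocks <- split(seq_along(y), subject)
  n <- length(y); p <- ncol(X)
  ni <- lengths(blocks)

  # sufficient statistics per subject block
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  S1x <- do.call(rbind, lapply(blocks, function(b) colSums(X[b, , drop = FALSE])))
  s1y <- vapply(blocks, function(b) sum(y[b]), numeric(1))

  profile <- function(log_theta) {
    th <- exp(log_theta)
    w <- th / (1 + th * ni)                       # shrinkage per block
    XtVX <- XtX - crossprod(S1x * w, S1x)
    XtVy <- Xty - crossprod(S1x * w, s1y)
    ytVy <- yty - sum(w * s1y^2)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    quad <- ytVy - sum(beta * XtVy)
    quad <- max(quad, 1e-300)
    sigma2 <- quad / (n - p)
    logdetV <- sum(log1p(th * ni))
    logdetXtVX <- 2 * sum(log(diag(ch)))
    obj <- logdetV + logdetXtVX + (n - p) * log(quad)   # -2 REML + const
    list(obj = obj, beta = beta, sigma2 = sigma2, chol = ch, theta = th)
  }

  # golden-section search on log(theta)
  lo <- log(1e-8); hi <- log(1e8)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- profile(c1)$obj; f2 <- profile(c2)$obj
  for (it in seq_len(200)) {
    if (b - a < 1e-10) break
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- profile(c1)$obj
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- profile(c2)$obj
    }
  }
  cand <- (a + b) / 2
  # the boundary theta -> 0 (plain OLS) may beat an interior optimum
  best <- profile(cand)
  for (boundary in c(lo, hi)) {
    at <- profile(boundary)
    if (at$obj < best$obj) best <- at
  }

  theta <- best$theta
  beta <- drop(best$beta)
  names(beta) <- colnames(X)
  sigma2 <- best$sigma2
  XtVXinv <- chol2inv(best$chol)
  se <- sqrt(pmax(diag(XtVXinv), 0) * sigma2)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))

  eps <- y - drop(X %*% beta)
  s1e <- vapply(blocks, function(bl) sum(eps[bl]), numeric(1))
  blup <- theta * s1e / (1 + theta * ni)
  resid <- eps
  for (k in seq_along(blocks)) resid[blocks[[k]]] <- eps[blocks[[k]]] - blup[k]

  structure(list(coefficients = beta, se = se, z = z, p = pval,
                 theta = theta,
                 sigma2_subject = theta * sigma2, sigma2_resid = sigma2,
                 residuals = resid, ranef = blup,
                 reml = best$obj, n = n, rank = p),
            class = "lmm_fit")
}

#' Profiled REML objective on a grid of variance ratios
#'
#' Exposes the (-2x, constant-dropped) restricted-likelihood profile used by
#' [lmm_fit()], for external inspection of the optimization.
#'
#' @param y,X,subject as in [lmm_fit()].
#' @param log_theta numeric vector of log variance ratios.
#' @return Numeric vector of objective values (lower is better).
#' @export
lmm_reml_profile <- function(y, X, subject, log_theta) {
  vapply(log_theta, function(lt) {
    fit <- tryCatch(
      lmm_fit_fixed_theta(y, X, subject, exp(lt)),
      error = function(e) NULL)
    if (is.null(fit)) Inf else fit$reml
  }, numeric(1))
}

#' @noRd
lmm_fit_fixed_theta <- function(y, X, subject, theta) {
  subject <- as.character(subject)
  blocks <- split(seq_along(y), subject)
  n <- length(y); p <- ncol(X)
  ni <- lengths(blocks)
  w <- theta / (1 + theta * ni)
  S1x <- do.call(rbind, lapply(blocks, function(b) colSums(X[b, , drop = FALSE])))
  s1y <- vapply(blocks, function(b) sum(y[b]), numeric(1))
  XtVX <- crossprod(X) - crossprod(S1x * w, S1x)
  XtVy <- crossprod(X, y) - crossprod(S1x * w, s1y)
  ytVy <- sum(y^2) - sum(w * s1y^2)
  ch <- chol(XtVX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  quad <- max(ytVy - sum(beta * XtVy), 1e-300)
  obj <- sum(log1p(theta * ni)) + 2 * sum(log(diag(ch))) + (n - p) * log(quad)
  list(beta = drop(beta), reml = obj, sigma2 = quad / (n - p))
}
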