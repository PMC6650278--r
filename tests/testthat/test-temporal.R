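test_that("power-law fit recovers exact parameters and never beats the flat model backwards", {
  dt <- rep(seq(2, 50, by = 4), each = 2)
  d <- 0.3 * dt^0.2 + 0.1
  fit <- fit_powerlaw(dt, d)
  expect_equal(fit$a, 0.3, tolerance = 1e-3)
  expect_equal(fit$b, 0.2, tolerance = 1e-3)
  expect_equal(fit$c, 0.1, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)

  # constant response: a ~ 0 and fit RSS equals flat RSS
  fitc <- fit_powerlaw(dt, rep(0.4, length(dt)))
  expect_equal(fitc$rss, fitc$rss_flat)
  expect_equal(fitc$a * max(dt)^fitc$b, 0, tolerance = 1e-6)

  # nested-model inequality on random data
  for (seed in 1:5) {
    set.seed(seed)
    y <- runif(20)
    f <- fit_powerlaw(rep(1:5, 4), y)
    expect_lte(f$rss, f$rss_flat + 1e-12)
  }

  expect_error(fit_powerlaw(rep(2, 10), runif(10)), "distinct")
  expect_error(fit_powerlaw(1:3, runif(3)), "at least 4")
})

test_that("power-law F-tests detect trends and compare groups", {
  set.seed(11)
  dt <- rep(seq(2, 40, by = 2), each = 3)
  strong <- 0.2 * dt^0.4 + 0.2 + rnorm(length(dt), 0, 0.01)
  ft <- powerlaw_vs_flat_test(fit_powerlaw(dt, strong))
  expect_lt(ft$p, 1e-6)
  expect_error(powerlaw_vs_flat_test(structure(list(n = 3), class = "powerlaw_fit")),
               "more than 3")

  # groups with different exponents separate; identical groups do not
  g1 <- data.frame(dt = dt, dissimilarity = 0.2 * dt^0.6 + 0.1 + rnorm(length(dt), 0, 0.02))
  g2 <- data.frame(dt = dt, dissimilarity = 0.2 * dt^0.2 + 0.1 + rnorm(length(dt), 0, 0.02))
  cmp <- powerlaw_group_compare(list(a = g1, b = g2))
  expect_lt(cmp$p, 0.01)
  g2b <- data.frame(dt = dt, dissimilarity = 0.2 * dt^0.6 + 0.1 + rnorm(length(dt), 0, 0.02))
  cmp2 <- powerlaw_group_compare(list(a = g1, b = g2b))
  expect_gt(cmp2$p, 0.05)
  expect_error(powerlaw_group_compare(list(a = g1)), "two groups")
})

test_that("inter-individual Mantel matches brute force and the reference implementation", {
  set.seed(21)
  n <- 12
  X <- matrix(rnorm(n * 4), n); Y <- X + matrix(rnorm(n * 4, 0, 0.5), n)
  DA <- as.matrix(dist(X)); DB <- as.matrix(dist(Y))
  dimnames(DA) <- dimnames(DB) <- list(paste0("s", 1:n), paste0("s", 1:n))
  mt <- mantel_inter(DA, DB, n_perm = 199, seed = 4)
  # brute-force correlation of vectorized triangles
  expect_equal(mt$statistic, cor(DA[lower.tri(DA)], DB[lower.tri(DB)]))
  expect_equal(mt$r2, mt$statistic^2)
  # independent cross-check
  ref <- vegan::mantel(as.dist(DA), as.dist(DB), permutations = 99)
  expect_equal(mt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(mt$p, 0.05)
  # perfect agreement
  expect_equal(mantel_inter(DA, DA, n_perm = 99, seed = 1)$statistic, 1)
  # p-value bounds
  expect_gte(mt$p, 1 / 200)
})

test_that("intra-individual Mantel uses only within-subject pairs and blocked permutations", {
  md <- tiny_metadata(subject = rep(c("A", "B"), each = 3),
                      week = rep(c(0, 2, 4), 2), diagnosis = "nonIBD")
  ids <- md$sample_id
  set.seed(3)
  DA <- as.matrix(dist(matrix(rnorm(6 * 3), 6))); dimnames(DA) <- list(ids, ids)
  DB <- as.matrix(dist(matrix(rnorm(6 * 3), 6))); dimnames(DB) <- list(ids, ids)
  mt <- mantel_intra(DA, DB, md, n_perm = 99, seed = 2, audit = TRUE)
  # hand correlation over the six within-subject distances
  pick <- function(D) c(D[ids[2], ids[1]], D[ids[3], ids[1]], D[ids[3], ids[2]],
                        D[ids[5], ids[4]], D[ids[6], ids[4]], D[ids[6], ids[5]])
  expect_equal(mt$statistic, cor(pick(DA), pick(DB)))
  expect_equal(mantel_intra(DA, DA, md, n_perm = 99, seed = 1)$statistic, 1)
  # audit: every permutation maps each subject's samples onto themselves
  for (p in mt$perms) {
    expect_identical(mt$subjects[p], mt$subjects)
  }
})

test_that("PERMANOVA R2 matches hand decomposition, the Gram oracle, and vegan", {
  # two groups of two with d = 0 within and d = 1 between: R2 = 1
  md <- tiny_metadata(subject = paste0("s", 1:4), week = 0, diagnosis = "nonIBD")
  ids <- md$sample_id
  D <- matrix(1, 4, 4, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  g <- c("x", "x", "y", "y")
  pv <- blocked_permanova(D, g, md, scheme = "free", n_perm = 99, seed = 1)
  expect_equal(pv$r2, 1)

  # random instances vs the direct group sum-of-squares formula and vegan
  for (seed in 1:4) {
    set.seed(seed)
    n <- 10
    mdr <- tiny_metadata(subject = paste0("s", 1:n), week = 0, diagnosis = "CD")
    Dr <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(Dr) <- list(mdr$sample_id, mdr$sample_id)
    gr <- sample(c("u", "v"), n, replace = TRUE)
    if (length(unique(gr)) < 2) gr[1] <- setdiff(c("u", "v"), gr[1])
    pvr <- blocked_permanova(Dr, gr, mdr, scheme = "free", n_perm = 9, seed = 1)
    # oracle: SS_total - SS_within from raw squared distances
    ss_tot <- sum(Dr[lower.tri(Dr)]^2) / n
    ss_win <- sum(vapply(unique(gr), function(gg) {
      sel <- gr == gg
      sum((Dr[sel, sel][lower.tri(Dr[sel, sel])])^2) / sum(sel)
    }, numeric(1)))
    expect_equal(pvr$r2, (ss_tot - ss_win) / ss_tot, tolerance = 1e-10)
    ref <- vegan::adonis2(as.dist(Dr) ~ gr, permutations = 9)
    expect_equal(pvr$r2, ref$R2[1], tolerance = 1e-10)
    expect_equal(pvr$statistic, ref$F[1], tolerance = 1e-10)
  }

  # R2 invariant to sample reordering
  set.seed(9)
  n <- 12
  mdr <- tiny_metadata(subject = rep(c("A", "B", "C"), each = 4),
                       week = rep(c(0, 2, 4, 6), 3), diagnosis = "UC")
  Dr <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(Dr) <- list(mdr$sample_id, mdr$sample_id)
  v <- rnorm(n)
  r1 <- blocked_permanova(Dr, v, mdr, scheme = "within-subject", n_perm = 49, seed = 2)
  perm <- sample(n)
  r2 <- blocked_permanova(Dr[perm, perm], v[perm], mdr, scheme = "within-subject",
                          n_perm = 49, seed = 2)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-12)

  # subject-relabel scheme rejects variables that vary within subject
  expect_error(blocked_permanova(Dr, v, mdr, scheme = "subject-relabel",
                                 n_perm = 9, seed = 1), "subject-constant")
  # and accepts subject-constant ones
  vconst <- rep(c("p", "q", "p"), each = 4)
  ok <- blocked_permanova(Dr, vconst, mdr, scheme = "subject-relabel",
                          n_perm = 99, seed = 3)
  expect_gte(ok$p, 1 / 100)
  expect_lte(ok$p, 1)

  # missing numeric covariates are mean-imputed rather than dropped
  vna <- v; vna[1] <- NA
  imp <- blocked_permanova(Dr, vna, mdr, scheme = "free", n_perm = 9, seed = 1)
  expect_true(is.finite(imp$statistic))
})
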