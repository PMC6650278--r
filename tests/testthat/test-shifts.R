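make_pairs <- function(intra_d, intra_dt, inter_d) {
  rbind(
    data.frame(sample_i = paste0("a", seq_along(intra_d)),
               sample_j = paste0("b", seq_along(intra_d)),
               dissimilarity = intra_d, dt = intra_dt,
               relation = "intra-consecutive", subject_id = "S"),
    data.frame(sample_i = paste0("c", seq_along(inter_d)),
               sample_j = paste0("d", seq_along(inter_d)),
               dissimilarity = inter_d, dt = 0,
               relation = "inter", subject_id = NA)
  )
}

test_that("threshold sits between separated intra and inter distributions", {
  set.seed(1)
  pairs <- make_pairs(intra_d = pmin(pmax(rnorm(400, 0.2, 0.03), 0), 1),
                      intra_dt = rep(c(2, 4, 6, 8), 100),
                      inter_d = pmin(pmax(rnorm(400, 0.8, 0.03), 0), 1))
  curve <- fit_threshold_curve(pairs)
  expect_true(all(curve$windows$threshold > 0.2))
  expect_true(all(curve$windows$threshold < 0.8))
  # monotone nondecreasing by construction
  expect_true(all(diff(curve$windows$threshold) >= 0))
})

test_that("density crossing matches an exhaustive grid-scan oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    intra <- pmin(pmax(rnorm(150, 0.35, 0.08), 0), 1)
    inter <- pmin(pmax(rnorm(300, 0.55, 0.1), 0), 1)
    got <- single_threshold_variant(intra, inter)
    # oracle: recompute both KDEs and scan every grid point above the mode
    da <- stats::density(intra, bw = got$bw_intra$bw, from = 0, to = 1, n = 512)
    de <- stats::density(inter, bw = got$bw_inter$bw, from = 0, to = 1, n = 512)
    mode_i <- which.max(da$y)
    k <- which(seq_len(512) > mode_i & de$y > da$y)[1]
    expect_false(is.na(k))
    # interpolated crossing lies within one grid step of the first exceedance
    expect_lte(got$threshold, da$x[k])
    expect_gte(got$threshold, da$x[k - 1])
  }
  # identical distributions: threshold lands at or below the first grid point
  # above the mode where sampling noise lets the inter estimate exceed
  set.seed(9)
  x <- pmin(pmax(rnorm(500, 0.4, 0.1), 0), 1)
  same <- single_threshold_variant(x, x)
  da <- stats::density(x, bw = same$bw_intra$bw, from = 0, to = 1, n = 512)
  expect_lte(same$threshold, 1)
  expect_gte(same$threshold, da$x[which.max(da$y)])
})

test_that("raw thresholds are made monotone by a running maximum", {
  # three well-populated windows with deliberately non-monotone separation
  set.seed(4)
  mk <- function(mu, dt) data.frame(
    sample_i = "x", sample_j = "y",
    dissimilarity = pmin(pmax(rnorm(120, mu, 0.02), 0), 1), dt = dt,
    relation = "intra-consecutive", subject_id = "S")
  pairs <- rbind(mk(0.30, 2), mk(0.25, 4), mk(0.40, 6),
                 data.frame(sample_i = "c", sample_j = "d",
                            dissimilarity = pmin(pmax(rnorm(300, 0.6, 0.05), 0), 1),
                            dt = 0, relation = "inter", subject_id = NA))
  curve <- fit_threshold_curve(pairs)
  expect_equal(curve$windows$threshold, cummax(curve$windows$raw))
  expect_true(all(diff(curve$windows$threshold) >= 0))
})

test_that("sparse windows pool upward into the next window", {
  set.seed(2)
  pairs <- make_pairs(intra_d = runif(70, 0.1, 0.4),
                      intra_dt = c(rep(2, 10), rep(4, 60)),  # dt=2 is sparse
                      inter_d = runif(300, 0.5, 0.9))
  curve <- fit_threshold_curve(pairs, min_pairs = 30)
  expect_equal(curve$windows$center, 4)
  expect_equal(curve$windows$n_pairs, 70)
})

test_that("shift calling is thresholded, monotone, and attributable", {
  pairs <- make_pairs(intra_d = c(0.1, 0.45, 0.9, 0), intra_dt = c(2, 2, 4, 2),
                      inter_d = runif(50, 0.5, 0.9))
  # single numeric threshold variant
  calls <- call_shifts(pairs, 0.4)
  expect_equal(calls$dissimilarity, c(0.45, 0.9))
  # identical consecutive samples (d = 0) are never shifts
  expect_false(any(calls$dissimilarity == 0))
  # nothing called when every dissimilarity is below threshold
  expect_equal(nrow(call_shifts(pairs, 0.95)), 0)
  # superset under a pointwise-lower threshold
  calls_lo <- call_shifts(pairs, 0.05)
  expect_true(all(paste(calls$sample_i, calls$sample_j) %in%
                    paste(calls_lo$sample_i, calls_lo$sample_j)))

  # attribution: largest |delta| wins, ties to the lexicographically smaller
  # ID (exact binary fractions keep the tie exact)
  tab <- tiny_table(cbind(c(0.5, 0.25, 0.25), c(0.0, 0.25, 0.75)),
                    features = c("zeta", "beta", "alpha"),
                    samples = c("s1", "s2"))
  contrib <- attribute_shift("s1", "s2", tab)
  expect_equal(contrib$feature[1], "alpha")   # |0.5| ties with zeta, alpha < zeta
  expect_equal(contrib$delta[1], 0.5)
  expect_equal(contrib$feature[2], "zeta")
  # one feature moving 0 -> 0.5 with everything else static is primary
  tab2 <- tiny_table(cbind(c(0, 0.4, 0.6), c(0.5, 0.2, 0.3)),
                     features = c("mover", "f1", "f2"), samples = c("p", "q"))
  expect_equal(attribute_shift("p", "q", tab2)$feature[1], "mover")
})

test_that("contributor counts on a five-shift fixture match hand tabulation", {
  md <- tiny_metadata(subject = rep("S", 6), week = seq(0, 10, by = 2),
                      diagnosis = "CD")
  m <- cbind(c(0.9, 0.1, 0.0), c(0.1, 0.9, 0.0), c(0.8, 0.1, 0.1),
             c(0.1, 0.2, 0.7), c(0.15, 0.8, 0.05), c(0.9, 0.05, 0.05))
  tab <- tiny_table(m, features = c("fA", "fB", "fC"), samples = md$sample_id)
  D <- bray_curtis(tab)
  pairs <- build_pair_sets(D, md, consecutive_only = TRUE)
  calls <- call_shifts(pairs, 0.1)
  expect_equal(nrow(calls), 5)
  ann <- attribute_shifts(calls, tab, md)
  counts <- table(ann$primary_contributor)
  # hand tabulation of the largest per-pair changes:
  # w0->2 fA(-0.8); w2->4 fA(+0.7); w4->6 fA or fC(0.7 vs 0.6 -> fA... )
  deltas <- m[, -1] - m[, -6]
  hand <- apply(deltas, 2, function(d) c("fA", "fB", "fC")[order(-abs(d),
                                                                 c("fA", "fB", "fC"))][1])
  expect_equal(as.vector(counts[names(table(hand))]), as.vector(table(hand)))
})

test_that("shift rates normalize by observed time and ignore labels", {
  md <- tiny_metadata(subject = c("A", "A", "B", "B"), week = c(0, 52, 0, 52),
                      diagnosis = c("CD", "CD", "nonIBD", "nonIBD"))
  pairs <- data.frame(sample_i = c("A_w00", "B_w00"),
                      sample_j = c("A_w52", "B_w52"),
                      dissimilarity = c(0.9, 0.1), dt = 52,
                      relation = "intra-consecutive", subject_id = c("A", "B"))
  calls <- call_shifts(pairs, 0.5)
  rates <- shift_rate(calls, pairs, md)
  expect_equal(unname(rates["CD"]), 1)       # 1 call over 1 subject-year
  expect_equal(unname(rates["nonIBD"]), 0)   # zero calls
  # two calls over 52 observed weeks = 2 per year
  pairs2 <- data.frame(sample_i = c("A_w00", "A_w26"), sample_j = c("A_w26b", "A_w52"),
                       dissimilarity = 0.9, dt = 26,
                       relation = "intra-consecutive", subject_id = "A")
  md2 <- md[1:2, ]
  expect_equal(unname(shift_rate(call_shifts(pairs2, 0.5), pairs2, md2)["CD"]), 2)
})

test_that("pairs drawn from the inter-individual regime are nearly all called", {
  # fit the curve on the usual regime (intra low, inter high), then evaluate
  # consecutive pairs whose dissimilarities come from the inter distribution:
  # essentially every one must exceed the fitted threshold
  set.seed(8)
  ref <- make_pairs(intra_d = pmin(pmax(rnorm(300, 0.2, 0.03), 0), 1),
                    intra_dt = rep(c(2, 4, 6), 100),
                    inter_d = pmin(pmax(rnorm(300, 0.8, 0.03), 0), 1))
  curve <- fit_threshold_curve(ref)
  swapped <- make_pairs(intra_d = pmin(pmax(rnorm(300, 0.8, 0.03), 0), 1),
                        intra_dt = rep(c(2, 4, 6), 100),
                        inter_d = 0.5)
  calls <- call_shifts(swapped, curve)
  expect_gt(nrow(calls) / 300, 0.95)
})

test_that("weighted density downweights densely sampled subjects", {
  set.seed(5)
  x <- rnorm(60, 0, 1)
  # all singleton subjects: identical to the unweighted KDE
  d1 <- weighted_density(x, paste0("s", seq_along(x)))
  d0 <- stats::density(x, bw = d1$bw, n = 512)
  expect_equal(d1$y, d0$y, tolerance = 1e-10)
  # integral over the grid is 1
  expect_equal(sum(diff(d1$x) * (head(d1$y, -1) + tail(d1$y, -1)) / 2), 1,
               tolerance = 1e-3)
  # a subject duplicated 10x contributes the same mass as a singleton
  vals <- c(rep(-2, 10), 2)
  subj <- c(rep("dense", 10), "single")
  dw <- weighted_density(vals, subj, from = -4, to = 4)
  mass_lo <- sum(dw$y[dw$x < 0]); mass_hi <- sum(dw$y[dw$x > 0])
  expect_equal(mass_lo / mass_hi, 1, tolerance = 0.05)
})
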