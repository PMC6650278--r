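test_that("reference set uses strict week > 20 from non-IBD subjects only", {
  md <- tiny_metadata(subject = c("n1", "n1", "n1", "c1"),
                      week = c(18, 20, 22, 30),
                      diagnosis = c("nonIBD", "nonIBD", "nonIBD", "CD"))
  ref <- build_reference_set(md)
  expect_identical(ref, "n1_w22")
})

test_that("dysbiosis score is the own-subject-excluded median to the reference", {
  # subjects: q (query), r1..r3 (references); r3 shares q's subject
  md <- tiny_metadata(subject = c("S", "A", "B", "S"),
                      week = c(0, 22, 24, 26),
                      diagnosis = c("CD", "nonIBD", "nonIBD", "nonIBD"),
                      sample_id = c("q", "r1", "r2", "r3"))
  ids <- md$sample_id
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["q", c("r1", "r2", "r3")] <- c(0.2, 0.4, 0.9)
  D["r1", c("r2", "r3")] <- c(0.3, 0.5); D["r2", "r3"] <- 0.6
  D <- D + t(D)
  # diagnosis varies within subject S in this crafted fixture; fix it
  md$diagnosis <- c("CD", "nonIBD", "nonIBD", "CD")
  refs <- c("r1", "r2", "r3")
  sc <- dysbiosis_score(D, md, refs)
  # q's own-subject sample r3 (the extreme 0.9) is excluded: median(0.2, 0.4)
  expect_equal(unname(sc["q"]), 0.3)
  # including it would give the odd-count median 0.4
  expect_equal(stats::median(D["q", refs]), 0.4)
  # sample identical to every reference scores 0
  D2 <- D; D2["q", refs] <- 0; D2[refs, "q"] <- 0
  expect_equal(unname(dysbiosis_score(D2, md, refs)["q"]), 0)
  # all references from the query's subject is an error
  expect_error(dysbiosis_score(D, md, "r3"), "no reference samples outside")
  # invariance to reference ordering
  expect_equal(dysbiosis_score(D, md, rev(refs)), sc)
})

test_that("threshold is the type-7 percentile of non-IBD scores", {
  md <- tiny_metadata(subject = sprintf("n%02d", 1:10), week = 0,
                      diagnosis = "nonIBD")
  scores <- stats::setNames(seq(0.1, 1, by = 0.1), md$sample_id)
  expect_equal(dysbiosis_threshold(scores, md), 0.91)
  expect_equal(dysbiosis_threshold(stats::setNames(rep(0.4, 10), md$sample_id), md), 0.4)
  md_cd <- md; md_cd$diagnosis <- "CD"
  expect_error(dysbiosis_threshold(scores, md_cd), "no non-IBD")
  # strict-inequality classification at the boundary
  expect_identical(classify_dysbiosis(c(0.91, 0.9100001, 0.5), 0.91),
                   c(FALSE, TRUE, FALSE))
})

test_that("scoring pipeline marks about 10% of a non-IBD cohort dysbiotic", {
  cfg <- cohort_config(n_subjects_per_group = c(nonIBD = 25, UC = 0, CD = 0),
                       seed = 5)
  coh <- simulate_cohort(cfg)
  res <- dysbiosis_classify(coh$taxa$table, coh$taxa$metadata)
  expect_gte(mean(res$dysbiotic), 0.08)
  expect_lte(mean(res$dysbiotic), 0.12)
  # scoring is invariant to duplicating a query column into the table
  expect_equal(res$threshold, dysbiosis_threshold(res$scores, coh$taxa$metadata))
})

test_that("episode extraction follows the excursion rules and censoring", {
  mk <- function(states, weeks = seq(0, by = 2, length.out = length(states))) {
    tiny_metadata(subject = "S", week = weeks, diagnosis = "CD",
                  dysbiotic = states)
  }
  # series starting dysbiotic: initial run excluded from durations
  e1 <- extract_episodes(mk(c(TRUE, TRUE, FALSE)))
  expect_equal(nrow(e1), 0)
  # with include_initial = "censor" it is kept as a censored span
  e1c <- extract_episodes(mk(c(TRUE, TRUE, FALSE)), include_initial = "censor")
  expect_equal(e1c$kind, "duration")
  expect_true(e1c$censored)
  expect_equal(e1c$length, 4)  # visible span: series start to the next non-dysbiotic sample

  # N D D N: one complete 4-week duration
  e2 <- extract_episodes(mk(c(FALSE, TRUE, TRUE, FALSE)))
  expect_equal(e2$kind, "duration")
  expect_false(e2$censored)
  expect_equal(e2$length, 4)

  # N D D (series ends): one censored 2-week duration
  e3 <- extract_episodes(mk(c(FALSE, TRUE, TRUE)))
  expect_equal(e3$kind, "duration")
  expect_true(e3$censored)
  expect_equal(e3$length, 2)

  # N D N N D: complete duration 2, complete interval 4, censored duration 0 dropped
  e4 <- extract_episodes(mk(c(FALSE, TRUE, FALSE, FALSE, TRUE)))
  expect_equal(sort(e4$kind), c("duration", "interval"))
  expect_equal(e4$length[e4$kind == "duration"], 2)
  expect_equal(e4$length[e4$kind == "interval"], 4)
})

test_that("censored exponential MLE matches closed form and a numeric maximizer", {
  expect_equal(censored_exponential_mean(c(2, 4, 6))$mean, 4)
  est <- censored_exponential_mean(c(4, 6, 8), c(FALSE, FALSE, TRUE))
  expect_equal(est$mean, 9)
  expect_equal(est$se, 9 / sqrt(2))
  expect_error(censored_exponential_mean(c(3, 5), c(TRUE, TRUE)), "no uncensored")

  # oracle: numeric maximizer of the censored exponential log-likelihood
  loglik <- function(m, len, cen) {
    sum(ifelse(cen, -len / m, -log(m) - len / m))
  }
  for (seed in 1:5) {
    set.seed(seed)
    len <- rexp(40, 1 / 6)
    cen <- runif(40) < 0.25
    if (all(cen)) cen[1] <- FALSE
    opt <- stats::optimize(loglik, c(1e-3, 1e3), len = len, cen = cen,
                           maximum = TRUE, tol = 1e-10)
    expect_equal(censored_exponential_mean(len, cen)$mean, opt$maximum,
                 tolerance = 1e-6)
  }
})

test_that("Kaplan-Meier product-limit handles censoring", {
  km <- kaplan_meier(c(2, 4))
  expect_equal(km$survival[km$time == 2], 0.5)
  expect_equal(km$survival[km$time == 4], 0)
  km2 <- kaplan_meier(c(2, 4, 4), c(FALSE, FALSE, TRUE))
  expect_equal(km2$survival[km2$time == 2], 2 / 3)
  expect_equal(km2$survival[km2$time == 4], 1 / 3, tolerance = 1e-12)
  km3 <- kaplan_meier(c(2, 4), c(TRUE, TRUE))
  expect_true(all(km3$survival == 1))
})

test_that("cross-type concordance odds ratios match hand calculations", {
  perfect <- cross_type_concordance(rep(c(TRUE, FALSE), each = 10),
                                    rep(c(TRUE, FALSE), each = 10))
  expect_true(is.infinite(perfect$odds_ratio))
  expect_lt(perfect$p, 1e-4)

  indep <- cross_type_concordance(rep(c(TRUE, FALSE), 10),
                                  rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(indep$odds_ratio, 1)
  expect_equal(indep$p, 1)

  a <- c(rep(TRUE, 30), rep(FALSE, 30))
  b <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  expect_equal(cross_type_concordance(a, b)$odds_ratio, 4)  # (20*20)/(10*10)
})

test_that("external-reference scoring reproduces internal scores for outside subjects", {
  cfg <- cohort_config(n_subjects_per_group = c(nonIBD = 10, UC = 0, CD = 4),
                       seed = 9, missingness_prob = 0)
  coh <- simulate_cohort(cfg)
  tab <- relative_normalize(coh$taxa$table)
  md <- coh$taxa$metadata
  internal <- dysbiosis_classify(tab, md, normalize = FALSE)
  # external table = the internal reference samples, renamed
  ext <- unclass(tab)[, internal$reference_ids, drop = FALSE]
  colnames(ext) <- paste0("ext_", colnames(ext))
  ext <- abundance_table(ext, type = "MGX-taxa")
  out <- score_against_external_reference(tab, ext, md, normalize = FALSE)
  # CD subjects contribute no reference samples, so own-subject exclusion is
  # a no-op for them and both scores must coincide exactly
  cd <- md$sample_id[md$diagnosis == "CD"]
  expect_equal(out$scores[cd], internal$scores[cd], tolerance = 1e-12)
  expect_gt(out$spearman_rho, 0.9)
  # permuting external sample order changes nothing
  ext2 <- abundance_table(unclass(ext)[, rev(colnames(ext))], type = "MGX-taxa")
  out2 <- score_against_external_reference(tab, ext2, md, normalize = FALSE)
  expect_equal(out2$scores, out$scores)
  # same-distribution external reference agrees with internal classification
  expect_gt(out$concordance$odds_ratio, 1)
})
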