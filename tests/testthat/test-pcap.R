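test_that("precision/recall at a percentile matches hand cases", {
  r <- precision_recall_at_percentile(c(0.1, 0.2, 0.8, 0.9),
                                      c(-1, -1, 1, 1), 50)
  expect_equal(r$threshold, 0.5)
  expect_equal(r$precision, 1.0)
  expect_equal(r$recall, 1.0)
  expect_equal(r$n_pred, 2)

  # no true positives: precision 0 (something predicted), recall 0 by
  # convention
  r2 <- precision_recall_at_percentile(c(0.2, 0.6, 0.9), c(-1, -1, -1), 60)
  expect_equal(r2$precision, 0)
  expect_equal(r2$recall, 0)

  expect_error(precision_recall_at_percentile(numeric(0), numeric(0), 50),
               "empty")
})

test_that("precision/recall equals the brute-force oracle across the grid", {
  set.seed(31)
  probs <- runif(200)
  labels <- sample(c(1, -1), 200, replace = TRUE, prob = c(0.3, 0.7))
  for (p in seq(50, 99, 7)) {
    got <- precision_recall_at_percentile(probs, labels, p)
    want <- oracle_pr(probs, labels, p)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("cutoff selection follows the smallest-percentile-most-hits rule", {
  # two folds over a two-point grid
  prec <- rbind(c(0.80, 0.95), c(0.85, 0.92))
  rec <- rbind(c(0.9, 0.6), c(0.8, 0.5))
  sel <- select_cutoff_percentile(prec, rec, 90, grid = c(50, 60))
  expect_equal(sel$percentile, 60)
  expect_equal(sel$recall, 0.55)
  expect_true(sel$attainable)

  # tie in counts: the smallest percentile wins
  prec2 <- rbind(c(0.95, 0.95), c(0.92, 0.93))
  sel2 <- select_cutoff_percentile(prec2, rec, 90, grid = c(50, 60))
  expect_equal(sel2$percentile, 50)

  # unattainable target
  sel3 <- select_cutoff_percentile(prec / 10, rec, 90, grid = c(50, 60))
  expect_false(sel3$attainable)
  expect_equal(sel3$percentile, 60)
  expect_equal(sel3$recall, 0)
})

test_that("cutoff selection matches the exhaustive oracle on random tables", {
  set.seed(17)
  grid <- 50:99
  for (i in 1:25) {
    k <- sample(3:10, 1)
    prec <- matrix(runif(k * length(grid)), k)
    rec <- matrix(runif(k * length(grid)), k)
    npos <- sample(0:5, k, replace = TRUE)
    x <- sample(c(80, 90, 95), 1)
    got <- select_cutoff_percentile(prec, rec, x, n_pos = npos, grid = grid)
    want <- oracle_select_cutoff(prec, rec, x, n_pos = npos, grid = grid)
    expect_equal(got$percentile, want$percentile)
    expect_equal(got$recall, want$recall)
    expect_equal(got$attainable, want$attainable)
  }
})

test_that("nested-CV estimation matches a brute-force re-implementation", {
  # random small instances, every fold split materialized explicitly
  for (inst in 1:20) {
    d <- small_synth(n = 48, genes = 30, informative = 6, effect = 1.2,
                     minority = 0.35, noise = 1, seed = 100 + inst)
    spec <- fast_spec(tuning_budget = 2, seed = inst)
    # tiny instances legitimately screen fewer than 10 genes; the logged
    # RFE warning is expected
    est <- suppressWarnings(
      estimate_pcap(d$expression, d$labels, spec, x = 90,
                    outer_folds = 3, inner_folds = 3, seed = 500 + inst)
    )
    want <- suppressWarnings(
      oracle_estimate_pcap(d$expression, d$labels, spec, 90, 3, 3,
                           500 + inst)
    )
    expect_equal(unname(est$pcap), want$pcap, label = paste("instance", inst))
    expect_equal(unname(est$percentile[, 1]), want$percentile)
    expect_equal(unname(est$inner_recall[, 1]), want$inner_recall)
    expect_equal(unname(est$achieved_precision[, 1]), want$achieved_precision)
    expect_equal(unname(est$cutoff), want$cutoff, ignore_attr = TRUE)
  }
})

test_that("separable data gives PCAP_90 near 1 with perfect test precision", {
  d <- small_synth(n = 100, genes = 60, informative = 30, effect = 5,
                   minority = 0.3, noise = 0.2, seed = 6)
  est <- estimate_pcap(d$expression, d$labels, fast_spec(seed = 2), x = 90,
                       outer_folds = 5, inner_folds = 5, seed = 8)
  expect_gte(unname(est$pcap), 0.95)
  expect_equal(mean(est$achieved_precision, na.rm = TRUE), 1.0)
})

test_that("pure-noise labels collapse the PCAP estimate and trip the unattainable flag", {
  # under the null a lucky top-percentile hit in any single inner fold
  # already counts as "attainable", so the flag fires in a fraction of the
  # outer folds while the recall estimate itself stays near zero
  set.seed(23)
  n <- 80
  X <- matrix(2^rnorm(300 * n, 6), 300, n,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%03d", 1:n)))
  y <- setNames(sample(rep(c(1, -1), c(24, n - 24))), colnames(X))
  est <- suppressWarnings(
    estimate_pcap(X, y, fast_spec(tuning_budget = 2, seed = 3), x = 90,
                  outer_folds = 4, inner_folds = 4, seed = 13)
  )
  expect_true(any(!est$attainable))
  expect_lt(unname(est$pcap), 0.35)
  expect_lt(mean(est$achieved_precision, na.rm = TRUE), 0.9)
})

test_that("the same seed reproduces an estimate exactly", {
  d <- small_synth(n = 60, genes = 40, informative = 8, seed = 9)
  spec <- fast_spec(tuning_budget = 2, seed = 4)
  e1 <- suppressWarnings(estimate_pcap(d$expression, d$labels, spec, x = 90,
                                       outer_folds = 3, inner_folds = 3,
                                       seed = 77))
  e2 <- suppressWarnings(estimate_pcap(d$expression, d$labels, spec, x = 90,
                                       outer_folds = 3, inner_folds = 3,
                                       seed = 77))
  expect_identical(e1$pcap, e2$pcap)
  expect_identical(e1$percentile, e2$percentile)
  expect_identical(e1$achieved_precision, e2$achieved_precision)
})

test_that("model selection prefers the best median, not the best maximum", {
  report <- rbind(A = c(0.2, 0.9, 0.2), B = c(0.4, 0.5, 0.6))
  expect_equal(median_winner(report), 2)
  # tie keeps the earliest candidate
  expect_equal(median_winner(rbind(c(0.5, 0.5), c(0.5, 0.5))), 1)
})

test_that("select_model returns a per-fold report and a single candidate unchanged", {
  d <- small_synth(n = 60, genes = 40, informative = 10, effect = 2,
                   noise = 0.5, seed = 5)
  spec <- fast_spec(tuning_budget = 2, seed = 1)
  sel <- suppressWarnings(
    select_model(list(spec), d$expression, d$labels, criterion = "pcap",
                 x = 90, outer_folds = 3, inner_folds = 3, seed = 21)
  )
  expect_identical(sel$best_spec, spec)
  expect_equal(dim(sel$report), c(1L, 3L))
  # alternative criteria reuse the same estimates
  self <- suppressWarnings(
    select_model(list(spec), d$expression, d$labels, criterion = "f1",
                 x = 90, outer_folds = 3, inner_folds = 3, seed = 21)
  )
  expect_equal(self$estimates[[1]]$pcap, sel$estimates[[1]]$pcap)
  expect_true(all(self$report >= 0 & self$report <= 1))
})

test_that("confident prediction respects percentile and interval semantics", {
  d <- small_synth(n = 100, genes = 60, informative = 15, effect = 3,
                   minority = 0.3, noise = 0.3, seed = 12)
  cal <- calibrate_model(d$expression, d$labels, fast_spec(seed = 3), x = 90,
                         folds = 5, seed = 15)
  expect_true(cal$cutoff >= 50 && cal$cutoff <= 99)
  pred <- predict_confident(cal, d$expression)
  t <- quantile(pred$probability, cal$cutoff / 100, type = 7)
  expect_setequal(pred$sample_id[!is.na(pred$label)],
                  pred$sample_id[pred$probability >= t])

  # absolute mode freezes the calibration threshold instead of re-reading
  # the percentile on the new cohort
  expect_true(is.finite(cal$abs_threshold))
  pa <- predict_confident(cal, d$expression, threshold = "absolute")
  expect_setequal(pa$sample_id[!is.na(pa$label)],
                  pa$sample_id[pa$probability >= cal$abs_threshold])

  # two-sided interval membership
  two <- predict_confident(cal, d$expression, mode = "two-sided", c = 0.05)
  expect_true(all(two$label[two$probability >= 0.95] == 1, na.rm = FALSE))
  expect_true(all(is.na(two$label[two$probability >= 0.05 &
                                    two$probability < 0.95])))
  # c = 0.5 labels everything
  allp <- predict_confident(cal, d$expression, mode = "two-sided", c = 0.5)
  expect_false(any(is.na(allp$label)))
})
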