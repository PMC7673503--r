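test_that("differential t-tests flag strong shifts and control type-I error", {
  set.seed(41)
  n <- 40
  X <- matrix(2^(rnorm(200 * n, 6, 0.3)), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:n)))
  g1 <- colnames(X)[1:20]
  g2 <- colnames(X)[21:40]
  # 10 genes with a 4-fold shift in group 1
  X[1:10, g1] <- X[1:10, g1] * 4
  deg <- deg_ttest(X, g1, g2, threshold = 0.05)
  expect_true(all(sprintf("g%03d", 1:10) %in% deg$significant))

  # permuted labels: significant fraction near the threshold
  set.seed(42)
  fracs <- replicate(10, {
    perm <- sample(colnames(X))
    d <- deg_ttest(X[11:200, ], perm[1:20], perm[21:40], threshold = 0.05)
    length(d$significant) / 190
  })
  expect_lt(abs(mean(fracs) - 0.05), 3 * sqrt(0.05 * 0.95 / 1900))
})

test_that("invalid group definitions are rejected", {
  X <- rand_matrix(10, 6)
  expect_error(deg_ttest(X, c("s001", "s002"), c("s002", "s003")), "disjoint")
  expect_error(deg_ttest(X, "s001", c("s002", "s003")), "at least 2")
})

test_that("overlap counts and percentages follow set arithmetic", {
  X <- rand_matrix(5, 8)
  mk <- function(sig) {
    structure(list(significant = sig, genes = rownames(X)),
              class = "deg_list")
  }
  a <- mk(c("g001", "g002", "g003"))
  b <- mk(c("g002", "g003", "g004"))
  o <- deg_overlap(a, b)
  expect_equal(o$n_overlap, 2)
  expect_equal(o$percent, 100 * 2 / 3, tolerance = 1e-6)
  expect_equal(deg_overlap(a, a)$percent, 100)
  expect_equal(deg_overlap(a, mk(c("g004", "g005")))$n_overlap, 0)
  bad <- mk("g001")
  bad$genes <- paste0("x", 1:5)
  expect_error(deg_overlap(a, bad), "universes differ")
})

test_that("perfect oracle probabilities make prediction arms equal the truth arm", {
  d <- small_synth(n = 100, genes = 150, informative = 20, effect = 1.5,
                   minority = 0.3, noise = 0.6, seed = 31)
  oracle_fun <- function(X1, y1, X2) {
    oracle_probabilities(list(labels = d$labels[colnames(X2)]), 0, seed = 1)
  }
  res <- fiveway_overlap_experiment(d$expression, d$labels,
                                    x_list = c(95, 90), folds = 5,
                                    repeats = 2, seed = 3,
                                    prob_fun = oracle_fun, two_sided_c = 0.25)
  expect_equal(res$pcap95, res$true)
  expect_equal(res$pcap90, res$true)
  expect_true(all(res$random <= res$true))
})

test_that("noisy oracle predictions still separate Random from True", {
  d <- small_synth(n = 120, genes = 150, informative = 20, effect = 1.5,
                   minority = 0.3, noise = 0.6, seed = 32)
  oracle_fun <- function(X1, y1, X2) {
    oracle_probabilities(list(labels = d$labels[colnames(X2)]), 0.1,
                         seed = 99)
  }
  res <- fiveway_overlap_experiment(d$expression, d$labels,
                                    x_list = 90, folds = 5, repeats = 5,
                                    seed = 8, prob_fun = oracle_fun)
  tt <- t.test(res$true, res$random, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("cutoff sweep applies half-open interval semantics", {
  # a probability exactly equal to c is NOT in the negative-confident group
  probs <- c(a = 0.05, b = 0.04, c = 0.96, d = 0.95, e = 0.5)
  grp <- pcapmeta:::confident_groups(probs, 0.05)
  expect_identical(grp$neg, "b")       # 0.05 excluded (half-open [0, c))
  expect_setequal(grp$pos, c("c", "d"))  # 0.95 included (closed [1-c, 1])
})

test_that("cutoff sweep finds high overlap for accurate confident subsets", {
  d <- small_synth(n = 120, genes = 150, informative = 20, effect = 2,
                   minority = 0.3, noise = 0.5, seed = 33)
  fold <- setNames(rep(1:5, length.out = 120), names(d$labels))
  # perfect probabilities, c = 0.5, one fold spanning all samples: the
  # predicted groups equal the true groups, so the overlap is exactly 100%
  p0 <- oracle_probabilities(d$truth, 0, seed = 1)
  all_fold <- setNames(rep(1, 120), names(d$labels))
  sw0 <- cutoff_sweep(d$expression, d$labels, p0, all_fold, c_grid = 0.5)
  expect_equal(sw0$table$percent, 100)
  # per-fold groups with perfect probabilities still overlap substantially
  swf <- cutoff_sweep(d$expression, d$labels, p0, fold, c_grid = 0.5)
  expect_true(all(swf$table$percent > 0, na.rm = TRUE))

  # noisy probabilities: small-c (high accuracy) beats or matches c = 0.5
  p <- oracle_probabilities(d$truth, 0.2, seed = 2)
  sw <- cutoff_sweep(d$expression, d$labels, p, fold,
                     c_grid = c(0.25, 0.5))
  m <- sw$median_by_c
  expect_gte(m["0.25"] + 15, m["0.5"])  # sampling slack
  expect_true(sw$best_c %in% c(0.25, 0.5))
})

test_that("undefined sweep cells are excluded from medians", {
  d <- small_synth(n = 40, genes = 60, informative = 10, effect = 2,
                   minority = 0.3, noise = 0.5, seed = 34)
  fold <- setNames(rep(1:4, length.out = 40), names(d$labels))
  p <- oracle_probabilities(d$truth, 0.05, seed = 3)
  # c tiny enough that some folds lack 2 confident samples per group is
  # tolerated: cells are NA, medians skip them
  sw <- cutoff_sweep(d$expression, d$labels, pmin(pmax(p, 0.3), 0.7) ,
                     fold, c_grid = c(0.05, 0.35))
  expect_true(all(is.na(sw$table$percent[sw$table$c == 0.05])))
  expect_true(is.na(sw$median_by_c["0.05"]))
})
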