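test_that("Welch screen matches the closed-form hand case and stats::t.test", {
  X <- rbind(gX = c(10, 12, 14, 20, 22, 24))
  colnames(X) <- paste0("s", 1:6)
  y <- setNames(c(1, 1, 1, -1, -1, -1), colnames(X))
  res <- welch_screen(X, y, alpha = 0.1)
  expect_equal(res$t, -6.123724, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.003602, tolerance = 1e-4)
  expect_true(res$pass)

  # cross-check a batch of genes against stats::t.test
  set.seed(21)
  X2 <- matrix(rnorm(20 * 12), 20, 12,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  y2 <- setNames(rep(c(1, -1), each = 6), colnames(X2))
  res2 <- welch_screen(X2, y2)
  for (g in c(1, 7, 20)) {
    tt <- t.test(X2[g, y2 == 1], X2[g, y2 == -1])
    expect_equal(res2$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res2$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("Welch screen handles degenerate and undersized groups", {
  X <- rbind(flat = rep(3, 8), shifted = rep(c(1, 2), each = 4))
  colnames(X) <- paste0("s", 1:8)
  y <- setNames(rep(c(1, -1), each = 4), colnames(X))
  res <- welch_screen(X, y)
  expect_equal(res$p[res$gene_id == "flat"], 1)
  expect_false(res$pass[res$gene_id == "flat"])
  expect_equal(res$p[res$gene_id == "shifted"], 0)

  ybad <- setNames(c(1, rep(-1, 7)), colnames(X))
  expect_error(welch_screen(X, ybad), "at least 2")
})

test_that("screening under the global null passes about alpha of genes", {
  set.seed(42)
  X <- matrix(rnorm(2000 * 60), 2000, 60,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:60)))
  y <- setNames(rep(c(1, -1), each = 30), colnames(X))
  frac <- mean(welch_screen(X, y, alpha = 0.1)$pass)
  # 3 standard errors of a binomial proportion at p = 0.1, n = 2000
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("SMOTE equalizes classes with interpolated minority points", {
  X <- rbind(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
             matrix(5 + runif(8), 4, 2))
  rownames(X) <- paste0("s", 1:6)
  colnames(X) <- c("f1", "f2")
  y <- c(1, 1, -1, -1, -1, -1)
  out <- smote_oversample(X, y, seed = 3)
  expect_equal(sum(out$y == 1), sum(out$y == -1))
  syn <- out$X[-(1:6), , drop = FALSE]
  # with two minority points, synthetics lie on the segment (0,0)-(1,1)
  expect_equal(syn[, "f1"], syn[, "f2"], ignore_attr = TRUE)
  expect_true(all(syn >= 0 & syn <= 1))
  # originals untouched
  expect_equal(out$X[1:6, ], X)
})

test_that("SMOTE is an identity on balanced input and errors on a singleton", {
  d <- separable_toy(20)
  out <- smote_oversample(d$X, d$y)
  expect_identical(out$X, d$X)
  y1 <- c(1, rep(-1, 19))
  expect_error(smote_oversample(d$X, y1), "fewer than 2")
})

test_that("SMOTE synthetics respect the minority bounding box and counts", {
  set.seed(8)
  X <- matrix(rnorm(120 * 4), 120, 4,
              dimnames = list(sprintf("s%03d", 1:120), paste0("f", 1:4)))
  y <- c(rep(1, 20), rep(-1, 100))
  out <- smote_oversample(X, y, seed = 5)
  expect_equal(as.vector(table(out$y)), c(100, 100))
  syn <- out$X[-(1:120), ]
  minmax <- apply(X[y == 1, ], 2, range)
  for (j in 1:4) {
    expect_gte(min(syn[, j]), minmax[1, j])
    expect_lte(max(syn[, j]), minmax[2, j])
  }
})

test_that("RFE recovers informative genes and honours the mode contracts", {
  # 5 informative + 95 noise genes, strong effect: elimination down to 10
  # genes keeps the informative ones; median recovery >= 4/5 over seeds
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- setNames(rep(c(1, -1), each = n / 2), sprintf("s%02d", 1:n))
    X <- matrix(rnorm(n * 100), n, 100,
                dimnames = list(names(y), sprintf("g%03d", 1:100)))
    X[y == 1, 1:5] <- X[y == 1, 1:5] + 2.5
    sel <- rfe_select(X, y, model_spec("lasso"), mode = "fixed-10", seed = s)
    sum(sprintf("g%03d", 1:5) %in% sel)
  })
  expect_gte(median(hits), 4)

  # fixed mode returns exactly k genes out of many candidates
  set.seed(2)
  n <- 40
  y <- setNames(rep(c(1, -1), each = 20), sprintf("s%02d", 1:n))
  X <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(names(y), sprintf("g%03d", 1:200)))
  sel10 <- rfe_select(X, y, model_spec("lasso"), mode = "fixed-10",
                      seed = 1, step = 0.3)
  expect_length(sel10, 10)
  expect_true(all(sel10 %in% colnames(X)))

  # single candidate gene comes back in every mode
  X1 <- X[, 1, drop = FALSE]
  expect_equal(rfe_select(X1, y, model_spec("lasso"), mode = "auto"), "g001")
  expect_equal(rfe_select(X1, y, model_spec("lasso"), mode = "fixed-10"),
               "g001")

  # fewer candidates than k: warn and return them all
  X5 <- X[, 1:5]
  expect_warning(sel <- rfe_select(X5, y, model_spec("lasso"),
                                   mode = "fixed-10"), "returning all")
  expect_setequal(sel, colnames(X5))
})

test_that("auto-mode RFE output stays within the screened set and size cap", {
  d <- small_synth(n = 80, genes = 150, informative = 15, seed = 4)
  Xn <- rank_normalize(d$expression)
  scr <- welch_screen(Xn, d$labels, alpha = 0.1)
  cand <- scr$gene_id[scr$pass]
  sel <- rfe_select(t(Xn[cand, ]), d$labels, model_spec("lasso"),
                    mode = "auto", seed = 9, step = 0.2)
  expect_lte(length(sel), 100)
  expect_true(all(sel %in% cand))
})
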