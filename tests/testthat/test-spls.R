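# Sparse PLS core: multilevel split, thresholding, oracles, VAF, support.

test_that("within/between decomposition reconstructs X exactly and centres within parts", {
  withr::with_seed(10, {
    X <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    subj <- rep(c("a", "b", "c", "d"), each = 5)
  })
  sp <- within_decompose(X, y, subj)
  expect_equal(sp$X_within + sp$X_between, X, tolerance = 1e-15)
  expect_equal(sp$y_within + sp$y_between, y, tolerance = 1e-15)
  bysub <- rowsum(sp$X_within, subj)
  expect_lt(max(abs(bysub)), 1e-12)

  # constant rows per participant leave no within variance
  Xc <- rbind(matrix(3, 4, 2), matrix(7, 4, 2))
  spc <- within_decompose(Xc, rep(c(1, 2), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(max(abs(spc$X_within)), 0)

  # a single participant reduces to global centring
  sp1 <- within_decompose(X, y, rep("only", 20))
  expect_equal(sp1$X_within, sweep(X, 2, colMeans(X)), ignore_attr = TRUE)

  expect_error_class(within_decompose(X, y, c("solo", subj[-1])), "singleton_subject_error")
})

test_that("an exactly representable response is captured by one sparse component", {
  withr::with_seed(21, {
    Q <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
  })
  y <- 2 * Q[, 1]
  m <- fit_spls(Q, y, K = 1, keepX = 1)
  expect_equal(m$support, 1L, ignore_attr = TRUE)
  beta_raw <- m$beta / 1  # columns of Q are not unit variance; check via fit
  expect_equal(predict(m, Q), y, tolerance = 1e-10)
  expect_equal(m$vaf, 1, tolerance = 1e-10)
  expect_equal(sum(m$beta != 0), 1L)
})

test_that("dense PLS with full rank reproduces least squares", {
  withr::with_seed(22, {
    X <- matrix(rnorm(35 * 6), 35, 6)
    y <- rnorm(35)
  })
  m <- fit_spls(X, y, K = 6, keepX = 6)
  ols <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(predict(m, X) - ols$fitted.values)), 1e-8)
})

test_that("a single component selects the k largest covariances, ties to the lower index", {
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      X <- matrix(rnorm(50 * 12), 50, 12)
      y <- rnorm(50)
    })
    for (k in c(1, 3, 7)) {
      m <- fit_spls(X, y, K = 1, keepX = k)
      w <- abs(as.numeric(crossprod(sweep(X, 2, colMeans(X)), y - mean(y))))
      expect_equal(sort(m$support), sort(order(-w)[seq_len(k)]))
    }
  }
  # exact ties: lower column index wins
  X <- cbind(c(1, -1, 1, -1), c(1, -1, 1, -1), c(1, 1, -1, -1))
  y <- c(2, -2, 0, 0)
  m <- fit_spls(X, y, K = 1, keepX = 1)
  expect_equal(m$support, 1L, ignore_attr = TRUE)
})

test_that("prediction is consistent in-sample and at the training mean", {
  withr::with_seed(23, {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rnorm(30)
  })
  m <- fit_spls(X, y, K = 2, keepX = 3)
  fitted <- m$y_mean + as.numeric(sweep(X, 2, m$x_means) %*% m$beta)
  expect_equal(predict(m, X), fitted)
  expect_equal(predict(m, m$x_means), mean(y))
  expect_error_class(predict(m, matrix(0, 2, 4)), "shape_error")
})

test_that("out-of-sample error vanishes for a noiseless linear truth as n grows", {
  mspe_at <- function(n) {
    withr::with_seed(n, {
      X <- matrix(rnorm(n * 5), n, 5)
      Xn <- matrix(rnorm(200 * 5), 200, 5)
    })
    y <- X %*% c(2, -1, 0.5, 0, 0)
    m <- fit_spls(X, y, K = 3, keepX = 3)
    mean((Xn %*% c(2, -1, 0.5, 0, 0) - predict(m, Xn))^2)
  }
  expect_lt(mspe_at(400), 1e-20)
})

test_that("variance accounted for behaves across regimes", {
  # independent response: every component's VAF is small
  withr::with_seed(31, {
    X <- matrix(rnorm(2000 * 10), 2000, 10)
    y <- rnorm(2000)
  })
  m <- fit_spls(X, y, K = 3, keepX = 2)
  expect_lt(max(m$vaf), 0.02)
  expect_equal(m$vaf, vaf_per_component(m))

  # two orthogonal signal directions of equal strength split the explained share
  withr::with_seed(32, {
    n <- 4000
    Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)
    eps <- rnorm(n)
  })
  X2 <- Q
  y2 <- Q[, 1] + Q[, 2] + eps
  m2 <- fit_spls(X2, y2, K = 2, keepX = 1)
  r2 <- 2 / (2 + 1)
  expect_equal(m2$vaf, rep(r2 / 2, 2), tolerance = 0.05)
  expect_lte(sum(m2$vaf), 1)

  # the predictor-variance reading is a different denominator
  vp <- vaf_per_component(m2, denominator = "predictor")
  expect_true(all(vp >= 0 & vp <= 1))
})

test_that("distinct-support counting deduplicates across components", {
  withr::with_seed(33, {
    Q <- qr.Q(qr(matrix(rnorm(60 * 8), 60, 8))) * sqrt(60)
  })
  y <- Q %*% c(10, 8, 6, 0.9, 0.7, 0.5, 0, 0)
  m5 <- fit_spls(Q, y, K = 5, keepX = 1)
  expect_equal(unique_support_size(m5), 5L)
  # equal weights within tiers deflate the first tier away completely, so the
  # second component selects the disjoint next tier
  y2 <- Q %*% c(10, 10, 10, 1, 1, 1, 0, 0)
  m6 <- fit_spls(Q, y2, K = 2, keepX = 3)
  expect_equal(unique_support_size(m6), 6L)

  # saturated response: later components cannot add support
  ysat <- Q[, 1]
  msat <- fit_spls(Q, ysat, K = 2, keepX = 1)
  expect_equal(unique_support_size(msat), 1L)
})

test_that("successive scores are mutually orthogonal", {
  for (s in 1:5) {
    withr::with_seed(200 + s, {
      X <- matrix(rnorm(80 * 15), 80, 15)
      y <- rnorm(80)
    })
    m <- fit_spls(X, y, K = 6, keepX = 4)
    G <- crossprod(m$x_scores)
    off <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] * diag(G)[col(G)[upper.tri(G)]])
    expect_lt(max(off), 1e-8)
  }
})

test_that("parameter validation rejects impossible settings", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error_class(fit_spls(X, rnorm(10), K = 1, keepX = 3), "parameter_error")
  expect_error_class(fit_spls(X, rep(1, 10), K = 1, keepX = 1), "degenerate_response_error")
})

test_that("the sparse fit agrees with the reference mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(41, {
    X <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    y <- X[, 2] * 3 - X[, 7] * 2 + rnorm(40)
  })
  ours <- fit_spls(scale(X), y, K = 2, keepX = 2)
  ref <- mixOmics::spls(X, y, ncomp = 2, keepX = c(2, 2), mode = "regression",
                        scale = TRUE)
  ref_support <- which(rowSums(abs(ref$loadings$X)) > 0)
  expect_equal(sort(unname(ours$support)), sort(unname(ref_support)))
  ref_pred <- predict(ref, X)$predict[, 1, 2]
  expect_equal(unname(predict(ours, scale(X))), unname(ref_pred), tolerance = 1e-6)
})
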