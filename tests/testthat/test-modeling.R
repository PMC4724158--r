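test_that("rmse and balanced accuracy have their standard closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt(25 / 2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  y <- c(rep("a", 8), rep("b", 2))
  expect_equal(balanced_accuracy(y, rep("a", 10)), 0.5)
  expect_equal(balanced_accuracy(y, y), 1)
})

test_that("fivefold CV balances folds and predicts every row once", {
  d <- small_qspr()
  X <- unsupervised_filter(qnpr_descriptors(d$smiles, min_freq = 3))$X
  cv <- fixture("cv_small", function()
    fivefold_cv(X, d$mp_obs, svm_params(), seed = 42))
  tab <- table(cv$fold_assignment)
  expect_length(tab, 5)
  expect_lte(diff(range(tab)), 1)
  expect_length(cv$oof_predictions, nrow(X))
  expect_true(all(is.finite(cv$oof_predictions)))
  expect_equal(cv$rmse, rmse(d$mp_obs, cv$oof_predictions))
  expect_error(fivefold_cv(X[1:8, ], d$mp_obs[1:8], seed = 1), "too few")
  expect_error(fivefold_cv(X, d$mp_obs), "seed")
})

test_that("fivefold CV is deterministic and invariant to row permutation", {
  d <- small_qspr()
  X <- as.matrix(qnpr_descriptors(d$smiles[1:200], min_freq = 3))
  y <- d$mp_obs[1:200]
  p <- svm_params(C = 8, epsilon = 8)
  cv1 <- fivefold_cv(X, y, p, seed = 7)
  cv2 <- fivefold_cv(X, y, p, seed = 7)
  expect_identical(cv1$rmse, cv2$rmse)
  # permuting rows with the same seed: same fold sizes, same RMSE after
  # re-alignment of the fold assignment to rows
  perm <- sample(200)
  cv3 <- fivefold_cv(X[perm, ], y[perm], p, seed = 7)
  expect_identical(cv1$fold_assignment, cv3$fold_assignment)
  expect_equal(cv3$rmse, rmse(y[perm], cv3$oof_predictions))
})

test_that("an exactly learnable response yields near-zero CV error", {
  set.seed(14)
  x <- matrix(seq(0, 1, length.out = 300), ncol = 1)
  y <- 2 * x[, 1]
  cv <- fivefold_cv(x, y, svm_params(C = 1000, gamma = 1, epsilon = 1e-4),
                    seed = 3)
  expect_lt(cv$rmse, 0.02 * sd(y))
})

test_that("pure-noise responses give CV RMSE near the noise SD", {
  set.seed(15)
  n <- 2000
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)                       # descriptors carry no signal
  cv <- fivefold_cv(X, y, svm_params(C = 1, epsilon = 0.1), seed = 4)
  expect_gt(cv$rmse, 0.9)
  expect_lt(cv$rmse, 1.1)
})

test_that("grid search returns the best triple with deterministic tie-breaks", {
  d <- small_qspr()
  X <- as.matrix(qnpr_descriptors(d$smiles[1:250], min_freq = 3))
  y <- d$mp_obs[1:250]
  single <- data.frame(C = 4, gamma = 0.05, epsilon = 8)
  expect_equal(grid_search(X, y, single, seed = 5)$C, 4)
  # a grid containing an absurd member and a sensible one
  grid <- data.frame(C = c(1e-4, 64), gamma = c(50, 1 / ncol(X)),
                     epsilon = c(200, 8))
  best <- grid_search(X, y, grid, seed = 5)
  expect_equal(best$C, 64)
  res <- attr(best, "results")
  expect_equal(nrow(res), 2)
  expect_equal(which.min(res$rmse), 2L)
  # exact ties break toward the smallest C
  tie <- data.frame(C = c(16, 2), gamma = c(0.1, 0.1), epsilon = c(300, 300))
  bt <- grid_search(X, y, tie, seed = 5)    # epsilon tube swallows everything
  expect_equal(bt$C, 2)
})

test_that("consensus strategies combine members as documented", {
  mk_member <- function(pred, r) {
    list(final_model = structure(list(value = pred), class = "const_model"),
         rmse = r, oof_predictions = rep(pred, 20))
  }
  assign("predict.const_model",
         function(object, newdata, ...) rep(object$value, nrow(as.matrix(newdata))),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)

  x <- matrix(0, 1, 2)
  cm <- consensus_model(list(mk_member(150, 10), mk_member(160, 10),
                             mk_member(170, 10)), "simple")
  out <- consensus_predict(cm, x)
  expect_equal(out$prediction, 160)
  expect_equal(out$distance_to_model, sd(c(150, 160, 170)))

  # equal member RMSEs: weighted (sum-normalized) equals simple exactly
  cw <- consensus_model(cm$members, "weighted")
  expect_equal(consensus_predict(cw, x)$prediction, 160)
  # the root-sum-square normalization from the printed form differs
  cr <- consensus_model(cm$members, "weighted", normalization = "rms")
  w <- rep(1 / 10, 3)
  expect_equal(consensus_predict(cr, x)$prediction,
               sum(w * c(150, 160, 170)) / sqrt(sum(w^2)))

  # single member: prediction passes through, distance 0
  c1 <- consensus_model(list(mk_member(150, 10)), "simple")
  out1 <- consensus_predict(c1, x)
  expect_equal(out1$prediction, 150)
  expect_equal(out1$distance_to_model, 0)

  # mlra without stored coefficients errors
  cm$strategy <- "mlra"
  expect_error(consensus_predict(cm, x), "stack")
})

test_that("consensus of diverse members does not exceed the worst member", {
  d <- small_qspr()
  y <- d$mp_obs
  Xq <- unsupervised_filter(qnpr_descriptors(d$smiles, min_freq = 3))$X
  Xq <- as.matrix(Xq)
  p <- ncol(Xq)
  thirds <- split(seq_len(p), rep(1:3, length.out = p))
  members <- fixture("consensus_members", function() lapply(thirds, function(js)
    fivefold_cv(Xq[, js, drop = FALSE], y, svm_params(C = 64, epsilon = 8),
                seed = 11)))
  cm <- consensus_model(members, "simple")
  cons_rmse <- rmse(y, consensus_oof(cm))
  member_rmse <- vapply(members, `[[`, numeric(1), "rmse")
  expect_lte(cons_rmse, max(member_rmse))
  # prediction lies within the member envelope
  P <- vapply(members, function(m) predict(m$final_model, Xq[1:20, ]),
              numeric(20))
  cp <- consensus_predict(cm, Xq[1:20, ])
  expect_true(all(cp$prediction >= apply(P, 1, min) - 1e-9))
  expect_true(all(cp$prediction <= apply(P, 1, max) + 1e-9))

  # the mlra stack reproduces y no worse than the simple mean on its
  # training criterion (residual sum of squares)
  cmlra <- consensus_model(members, "mlra", y = y)
  expect_lte(sum((y - consensus_oof(cmlra))^2),
             sum((y - consensus_oof(cm))^2) + 1e-6)
})

test_that("outlier filtering reproduces the Gaussian-null arithmetic", {
  set.seed(16)
  res <- rnorm(1000, 0, 10)
  rep1 <- filter_outliers(res, sigma = 10, p = 1e-4)
  expect_equal(rep1$expected_count, 0.1)
  expect_equal(rep1$z_threshold, qnorm(1 - 1e-4 / 2))
  expect_equal(rep1$threshold_c, rep1$z_threshold * 10)
  # z = 2 corresponds to p just under 0.05
  p2 <- 2 * (1 - pnorm(2))
  expect_lt(p2, 0.05)
  expect_equal(filter_outliers(res, 10, p2)$z_threshold, 2, tolerance = 1e-12)
  expect_error(filter_outliers(res, 0, 0.01), "sigma")
})

test_that("true-Gaussian residuals give SNR near one", {
  set.seed(17)
  res <- rnorm(1e5, 0, 20)
  for (p in c(0.05, 0.01, 0.001)) {
    rep0 <- filter_outliers(res, 20, p)
    tol <- 3 / sqrt(length(res) * p)
    expect_gt(rep0$snr, 1 - tol)
    expect_lt(rep0$snr, 1 + tol)
    expect_equal(rep0$observed_count, sum(abs(res) > rep0$threshold_c))
  }
})

test_that("stratified bags hold twice the minority class with equal counts", {
  set.seed(18)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  labels <- factor(c(rep("decompose", 30), rep("melt", 270)))
  X[labels == "decompose", 1] <- X[labels == "decompose", 1] + 3
  bag <- stratified_bagging_classify(X, labels, n_models = 16, seed = 19)
  expect_equal(bag$positive, "decompose")
  for (idx in bag$bags) {
    expect_length(idx, 60)                       # 2 x minority
    expect_equal(sum(labels[idx] == "decompose"), 30)
    expect_equal(sum(labels[idx] == "melt"), 30)
  }
  expect_gt(bag$balanced_accuracy, 0.8)
  expect_error(stratified_bagging_classify(X, factor(rep("a", n)), seed = 1))
})

test_that("separable classes classify well and shuffled labels are at chance", {
  set.seed(20)
  n <- 600
  X <- matrix(rnorm(n * 3), n, 3)
  labels <- factor(ifelse(runif(n) < 0.1, "decompose", "melt"))
  X[labels == "decompose", ] <- X[labels == "decompose", ] + 6  # separable
  bag <- stratified_bagging_classify(X, labels, n_models = 24, seed = 21)
  expect_gte(bag$balanced_accuracy, 0.95)
  shuf <- stratified_bagging_classify(X, sample(labels), n_models = 24, seed = 22)
  expect_gt(shuf$balanced_accuracy, 0.4)
  expect_lt(shuf$balanced_accuracy, 0.6)
  # prediction on new data returns probabilities in [0, 1]
  pr <- predict(bag, X[1:10, ])
  expect_true(all(pr >= 0 & pr <= 1))
})
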