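# Kernel QSPR modeling: fivefold cross-validated epsilon-SVR (RBF kernel,
# via e1071/libsvm), grid search over (C, gamma, epsilon), consensus
# averaging of member models with a standard-deviation distance-to-model,
# Gaussian-null outlier filtering with signal-to-noise accounting, and a
# stratified-bagging classifier for decomposing compounds.
#
# Predictors are standardized inside the fit and the response is left on
# its natural scale, so epsilon and C are in degrees C as reported for
# melting-point work.

#' SVR hyper-parameters
#'
#' Defaults are the triple found optimal for large-scale melting-point
#' modeling (C = 256, epsilon = 16 degrees C); `gamma = NULL` uses the
#' libsvm convention 1/(number of descriptors).
#'
#' @param C cost parameter (positive).
#' @param gamma RBF kernel width, or `NULL` for 1/ncol(X).
#' @param epsilon epsilon-insensitive tube half-width, in the units of the
#'   response (degrees C for melting points).
#' @return an object of class `svm_params`.
#' @export
svm_params <- function(C = 256, gamma = NULL, epsilon = 16) {
  stopifnot(is.finite(C), C > 0, is.finite(epsilon), epsilon >= 0,
            is.null(gamma) || (is.finite(gamma) && gamma > 0))
  structure(list(C = C, gamma = gamma, epsilon = epsilon), class = "svm_params")
}

.as_dense <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

# Standardize columns (constant columns are left centered only).
.scale_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# epsilon-SVR fit with a constant-model fallback: with a wide epsilon tube
# libsvm can return a model with no support vectors, which cannot predict;
# the fallback then predicts the training mean.
.fit_svr <- function(X, y, params) {
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  g <- if (is.null(params$gamma)) 1 / ncol(X) else params$gamma
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = params$C, gamma = g, epsilon = params$epsilon,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, scale = sc, fallback = mean(y),
                 empty = fit$tot.nSV == 0, cols = colnames(X)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- .as_dense(newdata)
  if (!is.null(object$cols) && !is.null(colnames(X)))
    X <- X[, object$cols, drop = FALSE]
  if (object$empty) return(rep(object$fallback, nrow(X)))
  as.numeric(stats::predict(object$fit, .scale_apply(X, object$scale)))
}

#' Root mean squared error
#' @param y_true,y_pred numeric vectors of equal length.
#' @return RMSE.
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (!length(y_true)) stop("empty input")
  sqrt(mean((y_true - y_pred)^2))
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls (sensitivity + specificity) / 2 for a
#' binary problem.
#'
#' @param y_true,y_pred factors or vectors of equal length.
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (!length(y_true)) stop("empty input")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  mean(vapply(unique(y_true), function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1)))
}

#' Fivefold cross-validated epsilon-SVR
#'
#' Rows are assigned to five folds by a uniform random permutation (each
#' fold holds 20 percent, within one row).  Each model is trained on 4/5
#' of the rows and predicts the held-out fifth, giving every row exactly
#' one out-of-fold prediction; the final model is fit on all rows.
#' Interval targets should be collapsed to their midpoint upstream.
#'
#' @param X descriptor matrix (dense or sparse); rows aligned with `y`.
#' @param y numeric response (degrees C).
#' @param params an [svm_params()] object.
#' @param seed integer seed controlling the fold assignment (mandatory:
#'   results are deterministic given the seed).
#' @return an object of class `cv_result`: `fold_assignment` (0..4 per
#'   row), `oof_predictions`, `rmse`, `rmse_se` (standard error over the
#'   five fold RMSEs), `final_model`, `params`.
#' @export
fivefold_cv <- function(X, y, params = svm_params(), seed) {
  X <- .as_dense(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (n < 10) stop("too few rows for 5 folds")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(0:4, n))
  oof <- numeric(n)
  fold_rmse <- numeric(5)
  for (f in 0:4) {
    te <- fold == f
    m <- .fit_svr(X[!te, , drop = FALSE], y[!te], params)
    oof[te] <- predict(m, X[te, , drop = FALSE])
    fold_rmse[f + 1] <- rmse(y[te], oof[te])
  }
  structure(list(
    fold_assignment = fold,
    oof_predictions = oof,
    rmse = rmse(y, oof),
    rmse_se = stats::sd(fold_rmse) / sqrt(5),
    fold_rmse = fold_rmse,
    final_model = .fit_svr(X, y, params),
    params = params,
    n = n
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n = %d, CV RMSE = %.2f +/- %.2f\n",
              x$n, x$rmse, x$rmse_se))
  invisible(x)
}

#' Grid search over SVR hyper-parameters
#'
#' Runs fivefold CV for every (C, gamma, epsilon) triple of the grid on a
#' random fraction of the rows and returns the triple with the smallest
#' CV RMSE.  Ties are broken toward the smallest C, then gamma, then
#' epsilon.
#'
#' @param X,y as in [fivefold_cv()].
#' @param grid data frame with columns `C`, `gamma`, `epsilon`.
#' @param fraction fraction of rows (0, 1] used for the search.
#' @param seed integer seed (row subsample and fold assignments).
#' @return the selected [svm_params()]; the full result table is attached
#'   as attribute `"results"`.
#' @export
grid_search <- function(X, y, grid, fraction = 1, seed) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0,
            all(c("C", "gamma", "epsilon") %in% names(grid)),
            fraction > 0, fraction <= 1)
  X <- .as_dense(X)
  set.seed(as.integer(seed))
  idx <- sort(sample(nrow(X), max(10L, round(fraction * nrow(X)))))
  Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
  res <- grid
  res$rmse <- vapply(seq_len(nrow(grid)), function(i) {
    p <- svm_params(C = grid$C[i], gamma = grid$gamma[i], epsilon = grid$epsilon[i])
    fivefold_cv(Xi, yi, p, seed = seed)$rmse
  }, numeric(1))
  best <- order(res$rmse, res$C, res$gamma, res$epsilon)[1]
  out <- svm_params(C = res$C[best], gamma = res$gamma[best],
                    epsilon = res$epsilon[best])
  attr(out, "results") <- res
  out
}

#' Build a consensus model from cross-validated members
#'
#' Three combination strategies are supported.  `simple`: the unweighted
#' mean of the member predictions.  `weighted`: accuracy weighting with
#' `w_i = 1/RMSE_i`; by default the weights are normalized by their sum
#' (a weighted mean, which reduces to the simple average when all member
#' RMSEs are equal); `normalization = "rms"` instead divides by
#' `sqrt(sum(w_i^2))`.  `mlra`: a multiple linear regression stack fit to
#' the members' out-of-fold predictions.  The distance-to-model of a
#' prediction is the standard deviation of the member predictions
#' (CONSENSUS-STD): large member disagreement signals an input far from
#' the applicability domain.
#'
#' @param members list of `cv_result` objects (or of lists with elements
#'   `final_model`, `rmse` and optionally `oof_predictions`).
#' @param strategy `"simple"`, `"weighted"` or `"mlra"`.
#' @param y training response; required for `strategy = "mlra"`.
#' @param normalization weight normalization for `"weighted"`.
#' @return an object of class `consensus_model`.
#' @export
consensus_model <- function(members, strategy = c("simple", "weighted", "mlra"),
                            y = NULL, normalization = c("sum", "rms")) {
  strategy <- match.arg(strategy)
  normalization <- match.arg(normalization)
  stopifnot(length(members) >= 1)
  stack <- NULL
  if (strategy == "mlra") {
    oof <- vapply(members, function(m) m$oof_predictions,
                  numeric(length(members[[1]]$oof_predictions)))
    if (is.null(y)) stop("y is required to train the mlra stack")
    stack <- stats::coef(stats::lm.fit(cbind(1, oof), y))
  }
  structure(list(members = members, strategy = strategy,
                 normalization = normalization,
                 stack_coefficients = stack),
            class = "consensus_model")
}

# Member predictions as an n x k matrix.
.member_predictions <- function(cm, newdata) {
  vapply(cm$members, function(m) predict(m$final_model, newdata),
         numeric(nrow(as.matrix(newdata))))
}

.combine_predictions <- function(cm, P) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  pred <- switch(cm$strategy,
    simple = rowMeans(P),
    weighted = {
      w <- 1 / vapply(cm$members, function(m) m$rmse, numeric(1))
      denom <- if (cm$normalization == "sum") sum(w) else sqrt(sum(w^2))
      as.numeric(P %*% w) / denom
    },
    mlra = {
      if (is.null(cm$stack_coefficients)) stop("mlra strategy without stack coefficients")
      as.numeric(cbind(1, P) %*% cm$stack_coefficients)
    })
  dist <- apply(P, 1, function(r) if (length(r) > 1) stats::sd(r) else 0)
  list(prediction = pred, distance_to_model = dist)
}

#' Predict with a consensus model
#'
#' @param cm a [consensus_model()].
#' @param newdata descriptor matrix.
#' @return list with `prediction` (degrees C) and `distance_to_model`
#'   (standard deviation of the member predictions, CONSENSUS-STD).
#' @export
consensus_predict <- function(cm, newdata) {
  stopifnot(inherits(cm, "consensus_model"))
  .combine_predictions(cm, .member_predictions(cm, .as_dense(newdata)))
}

#' @export
predict.consensus_model <- function(object, newdata, ...) {
  consensus_predict(object, newdata)$prediction
}

#' Out-of-fold consensus predictions
#'
#' Combines the members' stored out-of-fold predictions under the
#' consensus strategy, giving a cross-validated estimate of the consensus
#' model's accuracy.
#'
#' @param cm a [consensus_model()] whose members are `cv_result`s.
#' @return numeric vector of combined out-of-fold predictions.
#' @export
consensus_oof <- function(cm) {
  P <- vapply(cm$members, function(m) m$oof_predictions,
              numeric(length(cm$members[[1]]$oof_predictions)))
  .combine_predictions(cm, P)$prediction
}

#' Gaussian-null outlier filtering
#'
#' Under the null hypothesis the residuals (predicted minus observed) are
#' N(0, sigma) with sigma equal to the model RMSE.  For a two-sided tail
#' probability `p`, the threshold is `z * sigma` with `z` solving
#' `2 * (1 - Phi(z)) = p`; rows with `|residual|` beyond it are flagged.
#' `N * p` rows are expected to exceed the threshold by chance alone; the
#' ratio of observed to expected flags is the signal-to-noise ratio (SNR).
#' An SNR near 1 means the flagged rows are consistent with chance and
#' removing them would discard good data.
#'
#' @param residuals numeric vector of predicted - observed values.
#' @param sigma residual dispersion (typically the model's CV RMSE).
#' @param p two-sided tail probability in (0, 0.5).
#' @return an object of class `outlier_report`: `sigma`, `p`,
#'   `z_threshold`, `threshold_c`, `expected_count` (= N p, exact),
#'   `observed_count`, `snr`, `outlier_rows`.
#' @export
filter_outliers <- function(residuals, sigma, p) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  stopifnot(p > 0, p < 0.5)
  z <- stats::qnorm(1 - p / 2)
  thr <- z * sigma
  rows <- which(abs(residuals) > thr)
  expected <- length(residuals) * p
  structure(list(sigma = sigma, p = p, z_threshold = z, threshold_c = thr,
                 expected_count = expected, observed_count = length(rows),
                 snr = length(rows) / expected, outlier_rows = rows),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> p = %g: |residual| > %.1f (z = %.2f); observed %d vs expected %.1f, SNR = %.2f\n",
    x$p, x$threshold_c, x$z_threshold, x$observed_count, x$expected_count, x$snr))
  invisible(x)
}

#' Base learners for the decomposition classifier
#'
#' A pluggable learner is a list with `fit(X, y)` returning a fitted
#' object and `prob(fit, X)` returning the probability of the positive
#' class.  The defaults pair an RBF-kernel SVM with a decision tree, so
#' the bagged consensus mixes heterogeneous members.
#'
#' @param C,gamma SVM parameters for the kernel learner.
#' @return list of learners.
#' @export
default_learners <- function(C = 4, gamma = NULL) {
  svm_learner <- list(
    name = "svm",
    fit = function(X, y) {
      g <- if (is.null(gamma)) 1 / ncol(X) else gamma
      e1071::svm(X, y, type = "C-classification", kernel = "radial",
                 cost = C, gamma = g, probability = TRUE, scale = FALSE)
    },
    prob = function(fit, X) {
      pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
      pr[, levels(fit$fitted)[1]]
    })
  tree_learner <- list(
    name = "tree",
    fit = function(X, y) {
      colnames(X) <- paste0("V", seq_len(ncol(X)))  # descriptor names need not be syntactic
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class")
    },
    prob = function(fit, X) {
      colnames(X) <- paste0("V", seq_len(ncol(X)))
      stats::predict(fit, as.data.frame(X), type = "prob")[, 1]
    })
  list(svm_learner, tree_learner)
}

#' Stratified-bagging classifier for imbalanced binary labels
#'
#' For each of `n_models` bags, the minority class is sampled with
#' replacement to its own size and the majority class is sampled (with
#' replacement) down to the same number, so every bag holds exactly twice
#' the minority-class size with equal class counts.  Bags alternate over
#' the supplied base learners.  Each row's prediction is the mean
#' positive-class probability over the bags whose training sample did not
#' include it (out-of-bag), and the reported balanced accuracy is the
#' mean of the per-class recalls of those out-of-bag predictions.
#'
#' @param X descriptor matrix.
#' @param labels binary factor (or coercible); the minority class is
#'   treated as the positive class.
#' @param n_models number of bags.
#' @param learners list of base learners (see [default_learners()]).
#' @param seed integer seed.
#' @return an object of class `stratified_bagging`: `bags` (row indices),
#'   `oob_probability`, `oob_class`, `balanced_accuracy`, `positive`,
#'   `levels`.
#' @export
stratified_bagging_classify <- function(X, labels, n_models = 64,
                                        learners = default_learners(), seed) {
  X <- .as_dense(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  tab <- table(labels)
  if (any(tab == 0)) stop("a class is empty")
  positive <- names(tab)[which.min(tab)]
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  min_idx <- which(labels == positive)
  maj_idx <- which(labels != positive)
  m <- length(min_idx)
  set.seed(as.integer(seed))
  bags <- vector("list", n_models)
  fits <- vector("list", n_models)
  lrn_of <- (seq_len(n_models) - 1L) %% length(learners) + 1L
  # order the two classes consistently so the positive level is first
  ylev <- factor(as.character(labels), levels = c(positive, setdiff(levels(labels), positive)))
  for (b in seq_len(n_models)) {
    idx <- c(sample(min_idx, m, replace = TRUE),
             sample(maj_idx, m, replace = TRUE))
    bags[[b]] <- idx
    lr <- learners[[lrn_of[b]]]
    fits[[b]] <- lr$fit(Xs[idx, , drop = FALSE], droplevels(ylev[idx]))
  }
  n <- nrow(Xs)
  prob_sum <- numeric(n); prob_cnt <- integer(n)
  all_sum <- numeric(n); all_cnt <- integer(n)
  for (b in seq_len(n_models)) {
    lr <- learners[[lrn_of[b]]]
    pr <- lr$prob(fits[[b]], Xs)
    oob <- !(seq_len(n) %in% bags[[b]])
    prob_sum[oob] <- prob_sum[oob] + pr[oob]
    prob_cnt[oob] <- prob_cnt[oob] + 1L
    all_sum <- all_sum + pr
    all_cnt <- all_cnt + 1L
  }
  oob_prob <- ifelse(prob_cnt > 0, prob_sum / prob_cnt, all_sum / all_cnt)
  oob_class <- ifelse(oob_prob >= 0.5, positive,
                      setdiff(levels(labels), positive))
  structure(list(
    bags = bags, fits = fits, learner_index = lrn_of, learners = learners,
    scale = sc, positive = positive, levels = levels(labels),
    oob_probability = oob_prob, oob_class = oob_class,
    balanced_accuracy = balanced_accuracy(as.character(labels), oob_class)
  ), class = "stratified_bagging")
}

#' @export
predict.stratified_bagging <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  Xs <- .scale_apply(.as_dense(newdata), object$scale)
  P <- vapply(seq_along(object$fits), function(b) {
    lr <- object$learners[[object$learner_index[b]]]
    lr$prob(object$fits[[b]], Xs)
  }, numeric(nrow(Xs)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(Xs))
  pr <- rowMeans(P)
  if (type == "prob") pr
  else ifelse(pr >= 0.5, object$positive, setdiff(object$levels, object$positive))
}

#' @export
print.stratified_bagging <- function(x, ...) {
  cat(sprintf("<stratified_bagging> %d bags of %d rows, positive = %s, OOB balanced accuracy = %.3f\n",
              length(x$bags), length(x$bags[[1]]), x$positive, x$balanced_accuracy))
  invisible(x)
}
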