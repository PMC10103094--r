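#' Propensity model specification
#'
#' Two complementary families, matched to the two confounder
#' representations: `"lr"`, an L1-penalized (sparse) logistic regression
#' suited to the high-dimensional one-hot matrix; and `"rf"`, a
#' probability random forest suited to the dense embedding matrix, where
#' an unpenalized logistic fit is a poor match.
#'
#' For `"lr"`, `lambda` fixes the penalty; if `NULL` it is selected over
#' a small fixed grid, by default choosing the penalty whose weights
#' minimize the post-weighting maximum absolute standardized mean
#' difference (`selection = "balance"` -- the selection target is
#' confounder balance, which is what the weights are for).
#' `selection = "cv"` selects by 3-fold cross-validated deviance
#' instead; deviance-optimal shrinkage tends to under-adjust.
#'
#' @param family `"lr"` or `"rf"`.
#' @param lambda Fixed L1 penalty (lr), or `NULL` to select from
#'   `lambda_grid`.
#' @param lambda_grid Decreasing penalty grid for selection.
#' @param selection `"balance"` (default) or `"cv"`.
#' @param nfolds Cross-validation folds when `selection = "cv"`.
#' @param n_trees,max_depth,min_leaf Random-forest size, depth limit
#'   (0 = unbounded) and minimum node size.
#' @param thresh Coordinate-descent convergence threshold for the L1
#'   fit; the default is glmnet's. A looser value (e.g. `1e-5`) speeds
#'   up bootstrap refits with negligible effect on the weighted
#'   estimate.
#' @param seed Seed for fold assignment / tree growing.
#' @return A `propensity_spec` list.
#' @export
propensity_spec <- function(family = c("lr", "rf"), lambda = NULL,
                            lambda_grid = c(0.01, 0.003, 0.001,
                                            3e-4, 1e-4),
                            selection = c("balance", "cv"),
                            nfolds = 3, n_trees = 200, max_depth = 0,
                            min_leaf = 100, thresh = 1e-7, seed = 1) {
  family <- match.arg(family)
  selection <- match.arg(selection)
  stopifnot(nfolds >= 2, n_trees >= 1, max_depth >= 0, min_leaf >= 1,
            all(lambda_grid > 0), thresh > 0)
  if (!is.null(lambda)) stopifnot(lambda > 0)
  structure(list(family = family, lambda = lambda,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 selection = selection,
                 nfolds = nfolds, n_trees = n_trees, max_depth = max_depth,
                 min_leaf = min_leaf, thresh = thresh, seed = seed),
            class = "propensity_spec")
}

#' Fit a propensity model
#'
#' Estimates P(treated | covariates) with the family given in `spec`.
#' Both fits are deterministic for a fixed `spec$seed` (the forest is
#' grown single-threaded).
#'
#' @param x Covariate matrix (sparse allowed for `"lr"`).
#' @param labels 0/1 treatment labels, one per row of `x`.
#' @param spec A [propensity_spec()].
#' @return A `propensity_fit` with the fitted model, the family, the
#'   selected penalty (lr) and the training column names.
#' @export
fit_propensity <- function(x, labels, spec = propensity_spec()) {
  stopifnot(inherits(spec, "propensity_spec"))
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("matrix rows must match label count")
  if (length(unique(labels)) < 2) {
    stop("single-class labels: both arms must be present to fit a ",
         "propensity model")
  }
  if (inherits(x, "sparseMatrix")) {
    if (any(!is.finite(x@x))) stop("non-finite features")
  } else if (any(!is.finite(x))) {
    stop("non-finite features")
  }

  if (spec$family == "lr") {
    lambda <- spec$lambda
    if (is.null(lambda) && spec$selection == "cv") {
      set.seed(spec$seed)
      foldid <- sample(rep_len(seq_len(spec$nfolds), nrow(x)))
      cv <- glmnet::cv.glmnet(x, labels, family = "binomial", alpha = 1,
                              lambda = spec$lambda_grid, foldid = foldid,
                              type.measure = "deviance",
                              standardize = FALSE)
      lambda <- cv$lambda.min
    } else if (is.null(lambda)) {
      # balance selection: one warm-started path, then pick the penalty
      # whose clipped-weight pseudopopulation is best balanced
      path_fit <- glmnet::glmnet(x, labels, family = "binomial",
                                 alpha = 1, lambda = spec$lambda_grid,
                                 standardize = FALSE,
                                 thresh = spec$thresh)
      worst <- vapply(spec$lambda_grid, function(l) {
        p <- as.numeric(stats::predict(path_fit, newx = x, s = l,
                                       type = "response"))
        p <- pmin(pmax(p, 0.01), 0.99)
        w <- ifelse(labels == 1L, 1 / p, 1 / (1 - p))
        max(abs(balance_diagnostics(x, labels, w)$smd))
      }, numeric(1))
      lambda <- spec$lambda_grid[which.min(worst)]
    }
    # fit the warm-started path down to the requested penalty so the
    # prediction at s = lambda is exact, not an interpolation endpoint
    path <- sort(unique(c(spec$lambda_grid, lambda)), decreasing = TRUE)
    path <- path[path >= lambda]
    fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 1,
                          lambda = path, standardize = FALSE,
                          thresh = spec$thresh)
    model <- list(fit = fit, s = lambda)
    train_scores <- as.numeric(stats::predict(fit, newx = x, s = lambda,
                                              type = "response"))
  } else {
    xd <- as.data.frame(as.matrix(x))
    colnames(xd) <- make.names(colnames(xd), unique = TRUE)
    model <- ranger::ranger(
      x = xd, y = factor(labels, levels = c(0, 1)),
      num.trees = spec$n_trees, probability = TRUE,
      min.node.size = spec$min_leaf,
      max.depth = if (spec$max_depth > 0) spec$max_depth else NULL,
      seed = spec$seed, num.threads = 1,
      respect.unordered.factors = TRUE
    )
    # out-of-bag scores for the training sample: a tree votes only on
    # persons outside its bag, so a person's own label does not leak
    # into their propensity (in-sample forest scores overfit and bias
    # the weights)
    oob <- model$predictions[, "1"]
    if (anyNA(oob)) {
      ins <- stats::predict(model, data = xd,
                            num.threads = 1)$predictions[, "1"]
      oob[is.na(oob)] <- ins[is.na(oob)]
    }
    train_scores <- as.numeric(oob)
  }
  structure(list(family = spec$family, model = model, spec = spec,
                 train_cols = colnames(x), train_scores = train_scores),
            class = "propensity_fit")
}

#' Predict propensity scores with positivity clipping
#'
#' Scores are clipped symmetrically into `[eps, 1 - eps]` so that the
#' inverse-probability weights stay bounded (positivity safeguard).
#'
#' With `x = NULL` the scores for the training sample itself are
#' returned: the in-sample fitted values for the logistic family, and
#' the out-of-bag predictions for the random forest (so no person's
#' own label leaks into their weight). This is the form used whenever
#' scores are needed for the same persons the model was fitted on.
#'
#' @param fit A `propensity_fit`.
#' @param x Covariate matrix with the training schema, or `NULL` for
#'   training-sample scores.
#' @param eps Clipping bound, default 0.01.
#' @return Numeric vector of scores in `[eps, 1 - eps]`.
#' @export
predict_propensity <- function(fit, x = NULL, eps = 0.01) {
  stopifnot(inherits(fit, "propensity_fit"), eps > 0, eps < 0.5)
  if (is.null(x)) {
    p <- fit$train_scores
  } else {
    if (!identical(colnames(x), fit$train_cols)) {
      stop("covariate schema does not match the training schema")
    }
    if (fit$family == "lr") {
      p <- as.numeric(stats::predict(fit$model$fit, newx = x,
                                     s = fit$model$s, type = "response"))
    } else {
      xd <- as.data.frame(as.matrix(x))
      colnames(xd) <- make.names(colnames(xd), unique = TRUE)
      pr <- stats::predict(fit$model, data = xd,
                           num.threads = 1)$predictions
      p <- pr[, "1"]
    }
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Inverse-probability-of-treatment weights
#'
#' Unstabilized weights: `1 / p` for treated persons and `1 / (1 - p)`
#' for comparators. Normalization happens inside the weighted (Hajek)
#' estimator, not here.
#'
#' @param scores Propensity scores in (0, 1), already clipped.
#' @param labels 0/1 treatment labels aligned with `scores`.
#' @return Numeric weight vector.
#' @export
compute_weights <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(scores <= 0 | scores >= 1)) {
    stop("propensity scores must lie strictly inside (0, 1); ",
         "clip before weighting")
  }
  ifelse(as.integer(labels) == 1L, 1 / scores, 1 / (1 - scores))
}

#' Covariate balance diagnostics (standardized mean differences)
#'
#' For every covariate, the difference of (optionally weighted) arm
#' means divided by the pooled unweighted standard deviation
#' `sqrt((var_T + var_C) / 2)`. Covariates with zero pooled variance get
#' SMD 0 and a flag. |SMD| < 0.1 is the conventional adequate-balance
#' threshold.
#'
#' @param x Covariate matrix (sparse allowed).
#' @param labels 0/1 treatment labels.
#' @param weights Optional nonnegative weights (default: unweighted).
#' @return Data frame with `covariate`, `smd`, `zero_variance`.
#' @export
balance_diagnostics <- function(x, labels, weights = NULL) {
  labels <- as.integer(labels)
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(nrow(x) == length(labels), length(weights) == length(labels),
            all(weights >= 0))
  tr <- labels == 1L
  wt <- weights * tr
  wc <- weights * !tr
  mean_t <- as.numeric(Matrix::crossprod(x, wt)) / sum(wt)
  mean_c <- as.numeric(Matrix::crossprod(x, wc)) / sum(wc)
  # unweighted per-arm variances (E[x^2] - E[x]^2, small-sample factor ignored)
  m1t <- as.numeric(Matrix::colMeans(x[tr, , drop = FALSE]))
  m1c <- as.numeric(Matrix::colMeans(x[!tr, , drop = FALSE]))
  m2t <- as.numeric(Matrix::colMeans(x[tr, , drop = FALSE]^2))
  m2c <- as.numeric(Matrix::colMeans(x[!tr, , drop = FALSE]^2))
  pooled_sd <- sqrt(pmax(0, (m2t - m1t^2) + (m2c - m1c^2)) / 2)
  zero <- pooled_sd < .Machine$double.eps^0.5
  smd <- ifelse(zero, 0, (mean_t - mean_c) / pooled_sd)
  data.frame(covariate = if (is.null(colnames(x)))
               paste0("x", seq_len(ncol(x))) else colnames(x),
             smd = smd, zero_variance = zero,
             stringsAsFactors = FALSE, row.names = NULL)
}
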