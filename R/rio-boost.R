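# Stochastic gradient-boosted classification trees producing the relative
# index of occurrence (RIO). Binomial deviance loss, depth- and leaf-limited
# regression trees grown by exact greedy search on the gradient, Newton leaf
# steps, shrinkage, and row subsampling without replacement.

#' Fit a boosted-tree occurrence model
#'
#' Gradient boosting for a binary response with binomial deviance loss.
#' The model is the additive ensemble
#' \deqn{F(x) = F_0 + \nu \sum_m T_m(x),\qquad \mathrm{RIO}(x) =
#'   \mathrm{logistic}(F(x)) \in (0,1),}
#' where \eqn{F_0} is the logit of the weighted prevalence and each \eqn{T_m}
#' is a regression tree fit to the current residuals \eqn{r_i = y_i - p_i} on
#' a random subsample of rows. Trees are grown by exact greedy search over all
#' features and midpoints between sorted unique values, maximizing the
#' weighted squared-error reduction; leaf values are Newton steps
#' \eqn{\gamma = \sum w_i r_i / \sum w_i p_i (1 - p_i)} over the leaf's
#' subsample. Split ties go to the lowest feature index, then the lowest
#' threshold, so fits are reproducible.
#'
#' Defaults mirror the emulated modelling setup: 400 trees, maximum depth 10,
#' minimum 2 samples per leaf. Shrinkage 0.01 and subsample fraction 0.5 are
#' this package's defaults for the learning-rate and stochastic-subsampling
#' parameters.
#'
#' @param formula Model formula, e.g. `label ~ canopy_height + dist_trails`.
#' @param data Data.frame containing the response (0/1) and predictors.
#' @param weights Optional per-row case weights (e.g. the class-balancing
#'   `weight` column); defaults to 1.
#' @param n_trees Number of boosting iterations (>= 1).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum (unweighted) samples per leaf.
#' @param shrinkage Learning rate \eqn{\nu} in (0, 1].
#' @param subsample Row-subsampling fraction in (0, 1]; drawn without
#'   replacement each iteration.
#' @param seed Integer seed; the same table, config and seed give an identical
#'   model.
#' @return An object of class `rio_boost` with components `F0`, `trees`,
#'   `shrinkage`, `feature_names`, `config`, `train` (X, y, w, final link
#'   values) and `deviance` (training binomial deviance per iteration,
#'   element 1 = before any tree).
#' @seealso [predict.rio_boost()], [variable_importance()],
#'   [partial_dependence()], [roc_auc()]
#' @export
rio_boost <- function(formula, data, weights = NULL, n_trees = 400,
                      max_depth = 10, min_leaf = 2, shrinkage = 0.01,
                      subsample = 0.5, seed = 1L) {
  if (n_trees < 1 || max_depth < 1 || min_leaf < 1) {
    stop("n_trees, max_depth and min_leaf must all be >= 1")
  }
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- as.numeric(stats::model.response(mf))
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  icpt <- match("(Intercept)", colnames(X))
  if (!is.na(icpt)) X <- X[, -icpt, drop = FALSE]
  if (!all(is.finite(X))) stop("NaN or missing values in predictors")
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response has a single label; need both classes")
  w <- weights
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) != length(y) || any(w <= 0)) stop("weights must be positive, one per row")

  n <- length(y)
  F0 <- qlogis(weighted.mean(y, w))
  Fv <- rep(F0, n)
  n_sub <- max(1L, floor(subsample * n))
  trees <- vector("list", n_trees)
  dev <- numeric(n_trees + 1L)
  wdev <- function(p) -2 * sum(w * (y * log(pmax(p, 1e-15)) +
                                      (1 - y) * log(pmax(1 - p, 1e-15))))
  with_seed(seed, 606L, {
    for (m in seq_len(n_trees)) {
      p <- plogis(Fv)
      dev[m] <- wdev(p)
      r <- y - p
      h <- w * p * (1 - p)
      idx <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
      tr <- .grow_tree_cpp(X, idx - 1L, r, w, h, as.integer(max_depth),
                           as.integer(min_leaf))
      Fv <- Fv + shrinkage * .predict_tree_cpp(tr$feature, tr$threshold,
                                               tr$left, tr$right, tr$value, X)
      trees[[m]] <- tr
    }
  })
  dev[n_trees + 1L] <- wdev(plogis(Fv))

  model <- structure(
    list(F0 = F0, trees = trees, shrinkage = shrinkage,
         feature_names = colnames(X),
         config = list(n_trees = n_trees, max_depth = max_depth,
                       min_leaf = min_leaf, shrinkage = shrinkage,
                       subsample = subsample, seed = as.integer(seed)),
         formula = formula,
         train = list(X = X, y = y, w = w, link = Fv),
         deviance = dev),
    class = "rio_boost"
  )
  model$train_auc <- roc_auc(y, plogis(Fv), w)
  model
}

# sum of shrunken tree contributions (link scale, excluding F0)
tree_link <- function(model, X, n_trees = NULL) {
  total <- rep(0, nrow(X))
  use <- if (is.null(n_trees)) length(model$trees) else n_trees
  for (tr in model$trees[seq_len(use)]) {
    total <- total + model$shrinkage *
      .predict_tree_cpp(tr$feature, tr$threshold, tr$left, tr$right,
                        tr$value, X)
  }
  total
}

model_matrix_for <- function(model, newdata) {
  if (is.matrix(newdata)) {
    miss <- setdiff(model$feature_names, colnames(newdata))
    if (length(miss)) stop("missing feature: ", paste(miss, collapse = ", "))
    return(newdata[, model$feature_names, drop = FALSE])
  }
  miss <- setdiff(model$feature_names, names(newdata))
  if (length(miss)) stop("missing feature: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[model$feature_names])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("NaN or missing values in predictors")
  X
}

#' Predict the relative index of occurrence
#'
#' @param object A fitted [rio_boost()] model.
#' @param newdata Data.frame or matrix carrying every training feature;
#'   defaults to the training rows.
#' @param type `"response"` for RIO in (0, 1), `"link"` for log-odds.
#' @param n_trees Use only the first `n_trees` trees (default all).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.rio_boost <- function(object, newdata = NULL,
                              type = c("response", "link"), n_trees = NULL,
                              ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$train$X else model_matrix_for(object, newdata)
  link <- object$F0 + tree_link(object, X, n_trees)
  if (type == "link") link else plogis(link)
}

#' @export
print.rio_boost <- function(x, ...) {
  cat(sprintf(
    "rio_boost: %d trees, depth <= %d, min leaf %d, shrinkage %g, subsample %g\n",
    length(x$trees), x$config$max_depth, x$config$min_leaf,
    x$config$shrinkage, x$config$subsample))
  cat(sprintf("  %d training rows, %d features; F0 = %.4f\n",
              nrow(x$train$X), length(x$feature_names), x$F0))
  cat(sprintf("  training deviance %.2f -> %.2f, training AUC %.4f\n",
              x$deviance[1], x$deviance[length(x$deviance)], x$train_auc))
  invisible(x)
}

#' @export
summary.rio_boost <- function(object, ...) {
  out <- list(config = object$config, n_rows = nrow(object$train$X),
              deviance_first = object$deviance[1],
              deviance_final = object$deviance[length(object$deviance)],
              train_auc = object$train_auc,
              importance = variable_importance(object))
  class(out) <- "summary.rio_boost"
  out
}

#' @export
print.summary.rio_boost <- function(x, ...) {
  cat(sprintf("Boosted occurrence model (%d trees on %d rows)\n",
              x$config$n_trees, x$n_rows))
  cat(sprintf("Training AUC: %.4f; deviance %.2f -> %.2f\n\n",
              x$train_auc, x$deviance_first, x$deviance_final))
  cat("Predictor importance (max scaled to 100):\n")
  imp <- x$importance
  imp$importance <- sprintf("%.2f", imp$importance)
  print(imp, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.rio_boost <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  p <- plogis(object$train$link)
  y <- object$train$y
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(pmax(0, -2 * (y * log(pmax(p, 1e-15)) +
                                     (1 - y) * log(pmax(1 - p, 1e-15)))))
}

#' @export
simulate.rio_boost <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(object$train$link)
  out <- as.data.frame(replicate(nsim, rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Variable importance of a boosted model
#'
#' Importance of a feature is the sum over all splits on that feature of the
#' split's weighted squared-error reduction, rescaled so the maximum is
#' 100.00. Rows are in descending importance with ties broken by feature
#' name; features never used in a split score 0.
#'
#' @param model A fitted [rio_boost()] model.
#' @return Data.frame with columns `feature` and `importance`.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "rio_boost"))
  imp <- setNames(numeric(length(model$feature_names)), model$feature_names)
  for (tr in model$trees) {
    internal <- which(tr$feature >= 0)
    if (length(internal)) {
      f <- model$feature_names[tr$feature[internal] + 1L]
      for (i in seq_along(internal)) {
        imp[f[i]] <- imp[f[i]] + tr$improvement[internal[i]]
      }
    }
  }
  if (max(imp) > 0) imp <- imp / max(imp) * 100
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Partial dependence of the model on one feature
#'
#' Brute-force partial dependence on the (tree) log-odds scale:
#' `PD(v) = mean over training rows of the ensemble link with the feature
#' forced to v`, centered by subtracting the mean of the curve over the grid
#' (TreeNet-style centering), so only the shape and zero crossings carry
#' meaning.
#'
#' @param model A fitted [rio_boost()] model.
#' @param feature Feature name.
#' @param data Rows over which to average (default: training rows).
#' @param grid Numeric vector of feature values; default `n_grid` equally
#'   spaced values across the observed range.
#' @param n_grid Grid length when `grid` is not given.
#' @param center Subtract the grid mean (default `TRUE`).
#' @return Data.frame with columns `value` and `pd` (centered log-odds).
#' @export
partial_dependence <- function(model, feature, data = NULL, grid = NULL,
                               n_grid = 50, center = TRUE) {
  stopifnot(inherits(model, "rio_boost"))
  if (!feature %in% model$feature_names) {
    stop("unknown feature: ", feature)
  }
  X <- if (is.null(data)) model$train$X else model_matrix_for(model, data)
  if (is.null(grid)) {
    rng <- range(X[, feature])
    grid <- seq(rng[1], rng[2], length.out = n_grid)
  }
  if (length(grid) == 0L) stop("empty partial-dependence grid")
  pd <- vapply(grid, function(v) {
    Xv <- X
    Xv[, feature] <- v
    mean(tree_link(model, Xv))
  }, numeric(1))
  if (center) pd <- pd - mean(pd)
  data.frame(value = grid, pd = pd)
}

#' Plot partial-dependence curves
#'
#' @param x A fitted [rio_boost()] model.
#' @param features Features to plot (default: the top 4 by importance).
#' @param n_grid Grid length per curve.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of partial-dependence data.frames.
#' @export
plot.rio_boost <- function(x, features = NULL, n_grid = 50, ...) {
  if (is.null(features)) {
    features <- utils::head(variable_importance(x)$feature, 4L)
  }
  old <- par(mfrow = c(ceiling(length(features) / 2), min(2, length(features))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  out <- list()
  for (f in features) {
    pd <- partial_dependence(x, f, n_grid = n_grid)
    plot(pd$value, pd$pd, type = "l", col = "steelblue", lwd = 2,
         xlab = f, ylab = "centered log-odds", main = f, ...)
    abline(h = 0, lty = 3)
    out[[f]] <- pd
  }
  invisible(out)
}

#' Weighted area under the ROC curve
#'
#' Weighted Mann-Whitney statistic: the probability that a random presence
#' scores above a random absence, counting ties as one half, with case
#' weights multiplying each pair's contribution.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores.
#' @param weights Optional positive case weights (default 1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(length(labels) == length(scores),
            length(weights) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present to compute AUC")
  }
  ord <- order(scores)
  s <- scores[ord]; l <- labels[ord]; w <- weights[ord]
  W1 <- sum(w[l == 1]); W0 <- sum(w[l == 0])
  total <- 0
  cum0 <- 0
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    grp <- i:j
    w1 <- sum(w[grp][l[grp] == 1])
    w0 <- sum(w[grp][l[grp] == 0])
    total <- total + w1 * cum0 + 0.5 * w1 * w0
    cum0 <- cum0 + w0
    i <- j + 1L
  }
  total / (W1 * W0)
}
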