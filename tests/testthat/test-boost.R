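# The boosted-tree RIO model: fitting, prediction, importance, partial
# dependence and AUC, checked against hand traces and independent oracles.

sim_table <- function(n, seed = 1, noise = 0.5) {
  set.seed(seed)
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = runif(n), d = rnorm(n))
  eta <- 1.2 * X$a - 0.8 * X$b + 2 * (X$c > 0.5) + rnorm(n, 0, noise)
  cbind(label = rbinom(n, 1, plogis(eta)), X)
}

test_that("a separable toy problem reaches AUC 1 within a few trees", {
  toy <- data.frame(x = c(-5:-1, 1:5), label = rep(c(0, 1), each = 5))
  m <- rio_boost(label ~ x, toy, n_trees = 10, max_depth = 2, min_leaf = 1,
                 shrinkage = 0.5, subsample = 1, seed = 1)
  expect_equal(m$train_auc, 1.0)
  # zero trees fall back to the prevalence
  expect_equal(predict(m, toy, n_trees = 0), rep(0.5, 10))
})

test_that("training deviance is non-increasing without subsampling", {
  tab <- sim_table(200, seed = 2)
  m <- rio_boost(label ~ a + b + c + d, tab, n_trees = 60, max_depth = 3,
                 min_leaf = 2, shrinkage = 0.1, subsample = 1, seed = 1)
  expect_true(all(diff(m$deviance) <= 1e-9))
})

test_that("a one-split model reproduces the hand-traced Newton step", {
  # 8 rows, one feature, forced single stump: every quantity derivable by hand
  tab <- data.frame(x = c(1, 2, 3, 4, 10, 11, 12, 13),
                    label = c(0, 0, 0, 1, 1, 1, 1, 1))
  nu <- 0.3
  m <- rio_boost(label ~ x, tab, n_trees = 1, max_depth = 1, min_leaf = 2,
                 shrinkage = nu, subsample = 1, seed = 1)
  F0 <- qlogis(mean(tab$label))
  p0 <- plogis(F0)
  r <- tab$label - p0
  h <- p0 * (1 - p0)
  # the best split separates the labels exactly (between x = 3 and x = 4);
  # leaves take the Newton step sum(r) / sum(h)
  gamma_left <- sum(r[1:3]) / (3 * h)
  gamma_right <- sum(r[4:8]) / (5 * h)
  expect_equal(predict(m, data.frame(x = 2), type = "link"),
               F0 + nu * gamma_left, tolerance = 1e-12)
  expect_equal(predict(m, data.frame(x = 12), type = "link"),
               F0 + nu * gamma_right, tolerance = 1e-12)
  expect_equal(m$trees[[1]]$threshold[1], 3.5)
})

test_that("fits are reproducible per seed and sensitive to it", {
  tab <- sim_table(150, seed = 3)
  m1 <- rio_boost(label ~ a + b + c + d, tab, n_trees = 30, seed = 7)
  m2 <- rio_boost(label ~ a + b + c + d, tab, n_trees = 30, seed = 7)
  expect_identical(predict(m1), predict(m2))
  expect_identical(m1$trees, m2$trees)
  m3 <- rio_boost(label ~ a + b + c + d, tab, n_trees = 30, seed = 8)
  expect_false(identical(predict(m1), predict(m3)))

  expect_error(rio_boost(label ~ a, transform(tab, label = 1)),
               "single label")
  expect_error(rio_boost(label ~ a, transform(tab, a = NA_real_)), "NaN|missing")
})

test_that("training AUC tracks a reference gradient-boosting implementation", {
  tab <- sim_table(500, seed = 42, noise = 2.5)
  X <- as.matrix(tab[c("a", "b", "c", "d")])
  m <- rio_boost(label ~ a + b + c + d, tab, n_trees = 100, max_depth = 4,
                 min_leaf = 5, shrinkage = 0.1, subsample = 1, seed = 1)
  ref <- xgboost::xgboost(x = X, y = factor(tab$label), nrounds = 100,
                          max_depth = 4, learning_rate = 0.1, reg_lambda = 0,
                          min_child_weight = 1, nthreads = 1, verbosity = 0)
  auc_ref <- roc_auc(tab$label, as.numeric(predict(ref, X, type = "response")))
  expect_lt(abs(m$train_auc - auc_ref), 0.02)
})

test_that("importance rescales split improvements and flags unused features", {
  tab <- sim_table(300, seed = 5)
  tab$flat <- 1 # constant feature can never split
  m <- rio_boost(label ~ a + b + c + d + flat, tab, n_trees = 40,
                 max_depth = 3, subsample = 1, seed = 2)
  imp <- variable_importance(m)
  expect_equal(max(imp$importance), 100)
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  expect_equal(imp$feature, imp$feature[order(-imp$importance, imp$feature)])

  # oracle: re-accumulate improvements from the serialized model
  path <- withr::local_tempfile(fileext = ".json")
  write_rio_model(m, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fn <- unlist(obj$feature_names)
  acc <- setNames(numeric(length(fn)), fn)
  for (tr in obj$trees) {
    for (i in seq_along(tr$feature)) {
      f <- tr$feature[[i]]
      if (f >= 0) acc[fn[f + 1]] <- acc[fn[f + 1]] + tr$improvement[[i]]
    }
  }
  acc <- acc / max(acc) * 100
  expect_equal(imp$importance, unname(acc[imp$feature]), tolerance = 1e-9)
})

test_that("partial dependence reproduces single-tree steps and centering", {
  # single stump on one feature: uncentered PD is a two-level step nu*a / nu*b
  tab <- data.frame(x = c(1, 2, 3, 4, 10, 11, 12, 13),
                    label = c(0, 0, 0, 1, 1, 1, 1, 1))
  m <- rio_boost(label ~ x, tab, n_trees = 1, max_depth = 1, min_leaf = 2,
                 shrinkage = 0.3, subsample = 1, seed = 1)
  tr <- m$trees[[1]]
  thr <- tr$threshold[1]
  leaves <- tr$value[tr$feature < 0]
  pd <- partial_dependence(m, "x", grid = c(0, thr - 0.5, thr + 0.5, 14),
                           center = FALSE)
  expect_equal(pd$pd[1:2], rep(0.3 * min(leaves), 2), tolerance = 1e-12)
  expect_equal(pd$pd[3:4], rep(0.3 * max(leaves), 2), tolerance = 1e-12)

  centered <- partial_dependence(m, "x", grid = pd$value)
  expect_equal(mean(centered$pd), 0, tolerance = 1e-12)
  expect_error(partial_dependence(m, "x", grid = numeric(0)), "empty")
  expect_error(partial_dependence(m, "nope"), "unknown feature")
})

test_that("weighted AUC equals the all-pairs oracle and is antisymmetric", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)

  set.seed(17)
  for (k in 1:5) {
    n <- 50
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # many ties
    w <- runif(n, 0.5, 3)
    expect_equal(roc_auc(labels, scores, w), bf_auc(labels, scores, w),
                 tolerance = 1e-12)
    expect_equal(roc_auc(labels, scores, w) + roc_auc(labels, -scores, w), 1,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("model methods: residuals, simulate, summary and serialization", {
  tab <- sim_table(120, seed = 9)
  m <- rio_boost(label ~ a + b + c + d, tab, n_trees = 25, seed = 3)
  expect_equal(residuals(m), tab$label - plogis(m$train$link))
  expect_true(all(abs(residuals(m, type = "deviance")) >= 0))
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_true(all(unlist(sims) %in% 0:1))
  expect_s3_class(summary(m), "summary.rio_boost")

  path <- withr::local_tempfile(fileext = ".json")
  write_rio_model(m, path)
  back <- read_rio_model(path)
  expect_identical(predict(back, tab), predict(m, tab))
  expect_equal(variable_importance(back)$importance,
               variable_importance(m)$importance, tolerance = 1e-12)
})
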