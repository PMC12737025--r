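# shared synthetic training run for the count estimator
count_benchmark <- function(span_dist, seed, hyper = list()) {
  cfg <- zero_noise_config(seed = seed, view_span_distribution = span_dist)
  states <- generate_seedling_state(cfg, 1000)
  bundles <- simulate_detections(states, cfg)
  X <- do.call(rbind, lapply(bundles, function(b)
    flatten_features(consolidate_defects(b$side_leaf))))
  Y <- do.call(rbind, lapply(states, true_defect_counts))
  model <- do.call(train_count_model, c(list(X = X[1:800, ], Y = Y[1:800, ]), hyper))
  pred <- predict_counts(model, X[801:1000, ])
  list(model = model, Y_test = Y[801:1000, ], pred = pred)
}

test_that("the count estimator learns the identity map when spans are one view", {
  # with every defect visible from exactly one view, per-view totals equal
  # the true counts and the regression is exactly learnable
  b <- count_benchmark(list(dist = "constant", value = 1), seed = 61L,
                       hyper = list(kernel = "linear", epsilon = 0.01))
  for (k in 1:7) {
    r2 <- evaluate_regression(b$Y_test[, k], b$pred[, k])$r2
    expect_gte(r2, 0.99)
  }
})

test_that("held-out count recovery reaches R2 >= 0.8 under 1-4 view spans", {
  b <- count_benchmark(list(dist = "categorical", probs = c(.35, .30, .20, .15)),
                       seed = 62L,
                       hyper = list(cost = 100, epsilon = 0.01, gamma = 0.05))
  overall <- evaluate_regression(as.vector(b$Y_test), as.vector(b$pred))$r2
  expect_gte(overall, 0.8)
})

test_that("count predictions are length 7, clipped at 0, with rounded copies", {
  set.seed(3)
  X <- matrix(rpois(50 * 56, 0.3), 50, 56)
  Y <- cbind(X[, 1] + X[, 8], matrix(0, 50, 6))  # category 1 learnable, rest constant
  m <- train_count_model(X, Y)
  expect_identical(m$training_report$degenerate_targets, defect_categories()[-1])
  p <- predict_counts(m, X[1, ])
  expect_length(p, 7)
  expect_true(all(p >= 0))
  expect_equal(attr(p, "rounded"), floor(as.numeric(p) + 0.5),
               ignore_attr = TRUE)
  expect_error(predict_counts(list(), X[1, ]), "not a fitted")
  expect_error(train_count_model(X[1:5, ], Y[1:5, ]), "at least 10")
})

test_that("SVR keeps training points within the epsilon tube", {
  set.seed(12)
  X <- matrix(runif(60 * 56), 60, 56)
  y <- X %*% runif(56, 0, 0.2)
  Y <- cbind(as.numeric(y), matrix(rep(1, 60 * 6), 60, 6))
  m <- train_count_model(X, Y, kernel = "linear", cost = 1000, epsilon = 0.05)
  p <- predict_counts(m, X)
  # allow the solver's termination tolerance on top of the tube width
  expect_lt(max(abs(p[, 1] - Y[, 1])), 0.05 + 1e-3)
})

test_that("the root forest recovers the rule standard on held-out vectors", {
  set.seed(5)
  X <- matrix(sample(0:6, 2000 * 8, replace = TRUE,
                     prob = c(.08, .08, .14, .2, .2, .15, .15)), 2000, 8)
  G <- apply(X, 1, function(r) as.integer(rule_grade(summarize_views(r))))
  expect_gte(length(unique(G)), 3L)
  m <- train_root_model(X[1:1600, ], G[1:1600], ntree = 100, seed = 42)
  acc <- mean(predict_root_grade(m, X[1601:2000, ]) == G[1601:2000])
  expect_gte(acc, 0.95)
  # prediction is the modal tree vote (ties broken toward the worse grade)
  for (i in 1601:1620) {
    votes <- stats::predict(m$fit, orchidgrader:::root_design(matrix(X[i, ], 1)),
                            predict.all = TRUE)$individual
    tally <- table(factor(votes, levels = c("1", "2", "3")))
    modal <- names(tally)[tally == max(tally)][1]
    expect_identical(predict_root_grade(m, X[i, ]), as.integer(modal))
  }
})

test_that("root-forest training is invariant to row permutation at fixed seed", {
  set.seed(6)
  X <- matrix(sample(0:6, 400 * 8, replace = TRUE), 400, 8)
  G <- apply(X, 1, function(r) as.integer(rule_grade(summarize_views(r))))
  perm <- sample(nrow(X))
  m1 <- train_root_model(X, G, seed = 42)
  m2 <- train_root_model(X[perm, ], G[perm], seed = 42)
  probe <- matrix(sample(0:6, 50 * 8, replace = TRUE), 50, 8)
  expect_identical(predict_root_grade(m1, probe), predict_root_grade(m2, probe))
})

test_that("single-class root data is rejected with a pointer to the rules", {
  X <- matrix(5L, 20, 8)
  expect_error(train_root_model(X, rep(3L, 20)), "rule_grade")
})

test_that("the quality classifier separates well-separated synthetic grades", {
  set.seed(30)
  n <- 600
  S <- c(runif(n / 3, 0, 0.003), runif(n / 3, 0.008, 0.025), runif(n / 3, 0.04, 0.1))
  G <- sample(1:3, n, replace = TRUE, prob = c(.05, .15, .8))
  labels <- rule_based_grade(S, G)
  # spread each score over random category areas
  X <- t(sapply(seq_len(n), function(i) {
    w <- runif(7); areas <- S[i] * w / sum(w)
    assemble_feature_vector(list(leaf_damage_present = runif(1) < .2,
                                 leaf_shrinkage_present = runif(1) < .2),
                            rpois(7, 1), areas, score_config(), G[i])
  }))
  tr <- 1:450; te <- 451:600
  m <- train_quality_model(X[tr, ], labels[tr])
  acc <- mean(predict_quality(m, X[te, ]) == labels[te])
  expect_gte(acc, 0.95)
  # standardization contract: training features scale to mean 0, sd 1
  Xd <- orchidgrader:::quality_design(X[tr, ])
  Xs <- sweep(sweep(Xd, 2, m$scaler$center), 2, m$scaler$scale, "/")
  expect_lt(max(abs(colMeans(Xs))), 1e-8)
  nonconst <- apply(Xd, 2, sd) > 0
  expect_equal(apply(Xs[, nonconst], 2, sd), rep(1, sum(nonconst)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("duplicating every training row leaves quality predictions unchanged", {
  # separated score bands: the maximum-margin solution is stable, so
  # rebalanced class weights under duplication give the same classifier
  set.seed(31)
  n <- 120
  S <- c(runif(n / 3, 0, 0.003), runif(n / 3, 0.01, 0.025), runif(n / 3, 0.04, 0.08))
  G <- 3L
  labels <- rule_based_grade(S, G)
  X <- t(sapply(seq_len(n), function(i)
    assemble_feature_vector(list(leaf_damage_present = FALSE,
                                 leaf_shrinkage_present = FALSE),
                            rep(0, 7), rep(S[i] / 7, 7), score_config(), G)))
  m1 <- train_quality_model(X, labels)
  m2 <- train_quality_model(rbind(X, X), c(labels, labels))
  S_probe <- c(runif(60, 0, 0.003), runif(60, 0.01, 0.025), runif(60, 0.04, 0.08))
  probe <- t(sapply(S_probe, function(s)
    assemble_feature_vector(list(leaf_damage_present = FALSE,
                                 leaf_shrinkage_present = FALSE),
                            rep(0, 7), rep(s / 7, 7), score_config(), 3L)))
  expect_identical(predict_quality(m1, probe), predict_quality(m2, probe))
  expect_gte(mean(predict_quality(m1, probe) == rule_based_grade(S_probe, 3L)), 0.95)
})

test_that("quality training demands all classes and enough samples", {
  X <- matrix(runif(40 * 17), 40, 17)
  expect_error(train_quality_model(X, rep(c("A", "B"), 20)), "all three")
  expect_error(train_quality_model(X[1:10, ], rep(c("A", "B", "C"), length.out = 10)),
               "at least 30")
})

test_that("regression metrics match hand-computed values and inequalities", {
  perfect <- evaluate_regression(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(perfect$mae, perfect$rmse, perfect$r2), c(0, 0, 1))
  m <- evaluate_regression(c(0, 2), c(1, 1))
  expect_identical(c(m$mae, m$rmse, m$r2), c(1, 1, 0))
  # constant actuals with residuals: R2 undefined and flagged
  flat <- evaluate_regression(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(flat$r2))
  expect_false(flat$r2_defined)
  set.seed(40)
  for (i in 1:20) {
    y <- rnorm(15); yh <- rnorm(15)
    e <- evaluate_regression(y, yh)
    expect_gte(e$rmse, e$mae)
  }
})

test_that("model bundles persist and restore predictions bit-exactly", {
  set.seed(50)
  X <- matrix(sample(0:6, 200 * 8, replace = TRUE), 200, 8)
  G <- apply(X, 1, function(r) as.integer(rule_grade(summarize_views(r))))
  models <- list(count = "rules", root = train_root_model(X, G, ntree = 25))
  dir <- tempfile()
  save_model_bundle(models, dir)
  back <- load_model_bundle(dir)
  expect_identical(back$count, "rules")
  probe <- matrix(sample(0:6, 80 * 8, replace = TRUE), 80, 8)
  expect_identical(predict_root_grade(back$root, probe),
                   predict_root_grade(models$root, probe))
  expect_error(load_model_bundle(tempfile()), "not a model bundle")
})
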