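feature_scaler <- function(X, standardize) {
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-8] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  list(center = center, scale = scale, standardize = standardize)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

as_feature_matrix <- function(X, width, flatten = identity) {
  if (is.list(X) && !is.data.frame(X)) X <- do.call(rbind, lapply(X, flatten))
  X <- as.matrix(X)
  if (ncol(X) != width) stop("expected ", width, "-column inputs, got ", ncol(X))
  if (any(!is.finite(X))) stop("inputs must be finite")
  X
}

#' Train the per-category defect count estimator
#'
#' Stage-2 count estimation: seven independent support vector regressors,
#' one per defect category, each mapping the 56-d per-view per-category
#' detection count vector to that category's total defect count for the
#' seedling (multi-view duplicates removed). Count features share a
#' common scale, so inputs are passed to the regressors unstandardized by
#' default; the fitted standardization parameters (identity when
#' disabled) are stored with the model. Categories with constant training
#' targets are fitted as constants and flagged in the training report.
#'
#' @param X n x 56 matrix (or list of [consolidate_defects()] matrices).
#' @param Y n x 7 matrix of true per-category counts.
#' @param kernel,cost,epsilon,gamma SVR hyperparameters (radial kernel,
#'   C = 10, epsilon-tube 0.1 by default; `gamma` defaults to 1/56).
#' @param standardize Standardize input columns before fitting.
#' @return An object of class `count_model` with a `training_report`.
#' @export
train_count_model <- function(X, Y, kernel = "radial", cost = 10,
                              epsilon = 0.1, gamma = NULL,
                              standardize = FALSE) {
  X <- as_feature_matrix(X, 56L, flatten_features)
  Y <- as.matrix(Y)
  if (ncol(Y) != 7L) stop("`Y` must have 7 columns")
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (nrow(X) < 10L) stop("need at least 10 training seedlings")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  scaler <- feature_scaler(X, standardize)
  Xs <- apply_scaler(scaler, X)
  fits <- vector("list", 7L)
  degenerate <- logical(7L)
  for (k in seq_len(7L)) {
    if (stats::sd(Y[, k]) == 0) {
      degenerate[k] <- TRUE
      fits[[k]] <- list(constant = Y[1, k])
    } else {
      fits[[k]] <- e1071::svm(x = Xs, y = Y[, k], type = "eps-regression",
                              kernel = kernel, cost = cost, epsilon = epsilon,
                              gamma = gamma, scale = FALSE)
    }
  }
  structure(list(fits = fits, scaler = scaler,
                 hyperparams = list(kernel = kernel, cost = cost,
                                    epsilon = epsilon, gamma = gamma),
                 categories = defect_categories(),
                 training_report = list(n = nrow(X),
                                        degenerate_targets = defect_categories()[degenerate])),
            class = "count_model")
}

#' Predict per-category defect counts
#'
#' Continuous predictions clipped at zero; half-up rounded copies for
#' reporting are attached as the `"rounded"` attribute.
#'
#' @param model A fitted [train_count_model()].
#' @param x One 56-d vector / [consolidate_defects()] matrix, or an
#'   n x 56 matrix.
#' @return Numeric predictions (length-7 vector or n x 7 matrix), >= 0.
#' @export
predict_counts <- function(model, x) {
  if (!inherits(model, "count_model")) stop("`model` is not a fitted count model")
  single <- inherits(x, "defect_feature_matrix") ||
    (is.numeric(x) && is.null(dim(x))) ||
    (is.matrix(x) && nrow(x) == 8L && ncol(x) == 7L)
  if (inherits(x, "defect_feature_matrix") ||
      (is.matrix(x) && nrow(x) == 8L && ncol(x) == 7L)) x <- flatten_features(x)
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  X <- as_feature_matrix(X, 56L)
  Xs <- apply_scaler(model$scaler, X)
  raw <- sapply(seq_len(7L), function(k) {
    f <- model$fits[[k]]
    if (!is.null(f$constant)) rep(f$constant, nrow(Xs))
    else as.numeric(stats::predict(f, Xs))
  })
  if (nrow(Xs) == 1L) raw <- matrix(raw, nrow = 1L)
  out <- pmax(raw, 0)
  colnames(out) <- model$categories
  if (single) out <- out[1L, ]
  attr(out, "rounded") <- floor(out + 0.5)
  out
}

# the grading standard is symmetric across views, so the forest sees the
# per-view counts as descending order statistics
root_design <- function(X) {
  X <- t(apply(X, 1L, sort, decreasing = TRUE))
  colnames(X) <- paste0("rank_", seq_len(8L))
  X
}

#' Train the root grading forest
#'
#' Random forest over the 8-d per-view root count vector; the predicted
#' grade is the majority vote of the trees, with ties broken toward the
#' worse grade so a split forest never upgrades a root system. The rule
#' standard the forest emulates depends only on how many views fall in
#' each count bin — it is symmetric across views — so the forest is fed
#' the counts as descending order statistics, which removes the
#' irrelevant view-permutation degrees of freedom. Training rows are
#' also put in a canonical (lexicographic) order before the seeded
#' bootstrap draws, so permuting the input rows cannot change the
#' fitted forest.
#'
#' @param X n x 8 matrix of per-view root counts (or list of vectors).
#' @param G Root grades in `1:3`.
#' @param ntree Number of trees.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `root_grade_model`.
#' @export
train_root_model <- function(X, G, ntree = 100L, seed = 42L) {
  X <- as_feature_matrix(X, 8L)
  G <- as.integer(G)
  if (length(G) != nrow(X)) stop("X and G lengths differ")
  if (!all(G %in% 1:3)) stop("grades must be in 1:3")
  if (length(unique(G)) < 2L)
    stop("training data contains a single root grade; use rule_grade() instead")
  X <- root_design(X)
  ord <- do.call(order, c(as.data.frame(X), list(G)))
  X <- X[ord, , drop = FALSE]; G <- G[ord]
  set.seed(seed)
  # fit on the observed classes only: rare grades (often grade 1) may be
  # absent from a given training batch and randomForest rejects empty levels
  fit <- randomForest::randomForest(x = X, y = factor(G),
                                    ntree = as.integer(ntree))
  structure(list(fit = fit, ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "root_grade_model")
}

#' @rdname train_root_model
#' @param model Fitted model.
#' @param x 8-d root count vector or n x 8 matrix.
#' @return Integer grade(s) in `1:3` (modal tree vote, ties toward the
#'   worse grade).
#' @export
predict_root_grade <- function(model, x) {
  stopifnot(inherits(model, "root_grade_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  X <- root_design(as_feature_matrix(X, 8L))
  votes <- stats::predict(model$fit, X, predict.all = TRUE)$individual
  out <- apply(matrix(votes, nrow = nrow(X)), 1L, function(v) {
    tally <- table(factor(v, levels = c("1", "2", "3")))
    as.integer(names(tally)[tally == max(tally)][1L])  # tie -> lowest grade
  })
  if (is.null(dim(x))) out[1L] else out
}

# internal design matrix of the quality classifier: the root grade is a
# categorical signal (its override semantics are not linear in 1/2/3), so
# it enters as indicators; the per-category weighted areas additionally
# contribute their total, the weighted defect score S, as an explicit
# column so the score bands align with a single margin direction
quality_design <- function(X) {
  cbind(X[, 1:16, drop = FALSE],
        score_total = rowSums(X[, 10:16, drop = FALSE]),
        root_g1 = as.numeric(X[, 17] == 1),
        root_g2 = as.numeric(X[, 17] == 2),
        root_g3 = as.numeric(X[, 17] == 3))
}

#' Train the whole-seedling quality classifier
#'
#' Stage 3: a linear-kernel maximum-margin classifier over the 17-d
#' seedling feature vector. Internally the categorical root grade is
#' one-hot expanded and the weighted areas also enter through their
#' total (the weighted defect score), which keeps the classifier linear
#' while letting it express the band-plus-override grade structure.
#' Features are standardized with statistics fitted on the training
#' data only, and classes are weighted inversely proportional to their
#' frequencies to counter the strong A/B/C imbalance of commercial
#' batches.
#'
#' @param X n x 17 matrix of [assemble_feature_vector()] rows.
#' @param labels Grades `"A"`, `"B"`, `"C"`; all three must be present.
#' @param cost SVM cost parameter.
#' @return An object of class `quality_model`.
#' @export
train_quality_model <- function(X, labels, cost = 10) {
  X <- as_feature_matrix(X, 17L)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("X and labels lengths differ")
  if (nrow(X) < 30L) stop("need at least 30 training seedlings")
  if (!all(c("A", "B", "C") %in% labels))
    stop("all three quality grades must be present in the training labels")
  Xd <- quality_design(X)
  scaler <- feature_scaler(Xd, standardize = TRUE)
  Xs <- apply_scaler(scaler, Xd)
  tab <- table(factor(labels, levels = c("A", "B", "C")))
  wts <- as.numeric(length(labels) / (3 * tab))
  names(wts) <- names(tab)
  fit <- e1071::svm(x = Xs, y = factor(labels, levels = c("A", "B", "C")),
                    kernel = "linear", cost = cost, class.weights = wts,
                    scale = FALSE)
  structure(list(fit = fit, scaler = scaler, cost = cost, class_weights = wts),
            class = "quality_model")
}

#' @rdname train_quality_model
#' @param model Fitted model.
#' @param x 17-d vector or n x 17 matrix.
#' @return Character grade(s).
#' @export
predict_quality <- function(model, x) {
  stopifnot(inherits(model, "quality_model"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  X <- quality_design(as_feature_matrix(X, 17L))
  out <- as.character(stats::predict(model$fit, apply_scaler(model$scaler, X)))
  if (single) out[1L] else out
}

#' Regression metrics: MAE, RMSE, R-squared
#'
#' MAE = mean |y - yhat|; RMSE = sqrt(mean (y - yhat)^2);
#' R^2 = 1 - SS_res / SS_tot. With constant `y` the R^2 denominator
#' vanishes: the value is returned as `NA` with `r2_defined = FALSE`
#' (unless the fit is also perfect, where R^2 = 1 by convention).
#'
#' @param y Actual values.
#' @param y_hat Predicted values (same length).
#' @return List with `mae`, `rmse`, `r2`, `r2_defined`, `n`.
#' @export
evaluate_regression <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  if (length(y) < 1L) stop("need at least one observation")
  res <- y - y_hat
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(res^2)
  if (ss_tot == 0) {
    if (ss_res == 0) list(mae = mae, rmse = rmse, r2 = 1, r2_defined = TRUE,
                          n = length(y))
    else list(mae = mae, rmse = rmse, r2 = NA_real_, r2_defined = FALSE,
              n = length(y))
  } else {
    list(mae = mae, rmse = rmse, r2 = 1 - ss_res / ss_tot, r2_defined = TRUE,
         n = length(y))
  }
}

#' Persist and restore a trained model bundle
#'
#' Writes the three stage models to a versioned on-disk bundle: one RDS
#' per model plus a JSON manifest recording the format version, the
#' category scheme and the standardization constants. Reloading restores
#' predictions bit-exactly.
#'
#' @param models List with any of `count`, `root`, `quality` (each a
#'   fitted model or the string `"rules"`).
#' @param dir Bundle directory (created if absent).
#' @return `dir`, invisibly (saver); the models list (loader).
#' @export
save_model_bundle <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = 1L, package = "orchidgrader",
               categories = defect_categories(), components = list())
  for (nm in c("count", "root", "quality")) {
    m <- models[[nm]]
    if (is.null(m)) next
    if (identical(m, "rules")) {
      meta$components[[nm]] <- "rules"
    } else {
      saveRDS(m, file.path(dir, paste0(nm, ".rds")))
      meta$components[[nm]] <- paste0(nm, ".rds")
      if (nm == "quality")
        meta$standardization <- list(center = m$scaler$center,
                                     scale = m$scaler$scale)
    }
  }
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  meta_path <- file.path(dir, "bundle.json")
  if (!file.exists(meta_path)) stop("not a model bundle: ", dir)
  meta <- jsonlite::read_json(meta_path)
  models <- list()
  for (nm in names(meta$components)) {
    comp <- meta$components[[nm]]
    models[[nm]] <- if (identical(comp, "rules")) "rules"
    else readRDS(file.path(dir, comp))
  }
  models
}
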