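#' Named view-angle combinations of the ablation study
#'
#' The preset registry of side-view subsets used to measure each angle's
#' contribution: the full set (`"8"`), the eight drop-one combinations
#' (`"7-1"` .. `"7-8"`, where `"7-k"` removes angle (k-1)*45 degrees),
#' and the published 4/5/6-view combinations (`"4-1"` .. `"4-9"`,
#' `"5-1"` .. `"5-3"`, `"6-1"` .. `"6-6"`). Combination `"6-6"` — the
#' best-performing reduced set, excluding 45 and 225 degrees — is the
#' recommended configuration when fewer views must be used.
#'
#' @return Named list of integer angle vectors.
#' @export
view_presets <- function() {
  ang <- function(...) as.integer(c(...))
  presets <- list(
    "8"   = side_view_angles(),
    "4-1" = ang(0, 90, 180, 270),
    "4-2" = ang(45, 135, 225, 315),
    "4-3" = ang(0, 45, 135, 270),
    "4-4" = ang(90, 180, 225, 315),
    "4-5" = ang(0, 90, 135, 270),
    "4-6" = ang(0, 90, 180, 315),
    "4-7" = ang(0, 135, 180, 270),
    "4-8" = ang(0, 135, 180, 315),
    "4-9" = ang(0, 135, 270, 315),
    "5-1" = ang(0, 135, 180, 270, 315),
    "5-2" = ang(0, 135, 180, 225, 315),
    "5-3" = ang(0, 90, 135, 270, 315),
    "6-1" = ang(0, 45, 90, 135, 225, 270),
    "6-2" = ang(0, 45, 135, 180, 270, 315),
    "6-3" = ang(0, 45, 90, 135, 270, 315),
    "6-4" = ang(0, 45, 135, 180, 225, 270),
    "6-5" = ang(0, 135, 180, 225, 270, 315),
    "6-6" = ang(0, 90, 135, 180, 270, 315)
  )
  for (k in 1:8)
    presets[[paste0("7-", k)]] <- setdiff(side_view_angles(),
                                          (k - 1L) * 45L)
  presets
}

#' Resolve a view combination
#'
#' @param name Preset name (see [view_presets()]) or an integer vector
#'   of angles.
#' @return List with `name`, `angles` (included) and `excluded`.
#' @export
view_combination <- function(name) {
  if (is.numeric(name)) {
    angles <- as.integer(name)
    if (!length(angles) || !all(angles %in% side_view_angles()))
      stop("angles must be a nonempty subset of ",
           paste(side_view_angles(), collapse = ", "))
    return(list(name = paste(angles, collapse = "+"), angles = sort(angles),
                excluded = setdiff(side_view_angles(), angles)))
  }
  presets <- view_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  list(name = name, angles = presets[[name]],
       excluded = setdiff(side_view_angles(), presets[[name]]))
}

#' Run the grading pipeline under a view-angle ablation
#'
#' Re-runs the three-stage pipeline using only the included side-view
#' angles and reports grading metrics against ground truth. Two modes:
#' `"zero_pad"` keeps the supplied stage models and lets removed views
#' contribute zero features (cheap, fixed schema), `"retrain"` refits
#' the trainable stage models on the ablated features of a training
#' split before evaluating (the study's protocol). With rule-based stage
#' models the two modes coincide.
#'
#' @param states List of [seedling_state()]s (ground truth).
#' @param bundles Matching detection bundles (see
#'   [simulate_detections()]).
#' @param combination Preset name, angle vector, or [view_combination()].
#' @param cfg A [pipeline_config()].
#' @param models Stage models (`"rules"` strings or fitted models).
#' @param mode `"retrain"` or `"zero_pad"`.
#' @param train_frac Training fraction when retraining.
#' @return List with `combination`, per-seedling `grades`, a
#'   [class_metrics()] `metrics` entry and the confusion matrix.
#' @export
run_view_ablation <- function(states, bundles, combination,
                              cfg = pipeline_config(),
                              models = list(count = "rules", root = "rules",
                                            quality = "rules"),
                              mode = c("retrain", "zero_pad"),
                              train_frac = 0.8) {
  mode <- match.arg(mode)
  if (!is.list(combination) || is.null(combination$angles))
    combination <- view_combination(combination)
  cfg$views <- combination$angles
  trainable <- !all(vapply(models, identical, logical(1), "rules"))
  idx_eval <- seq_along(states)
  if (mode == "retrain" && trainable) {
    n_train <- max(1L, floor(train_frac * length(states)))
    idx_train <- seq_len(n_train)
    idx_eval <- setdiff(seq_along(states), idx_train)
    models <- train_stage_models(states[idx_train], bundles[idx_train], cfg)
  }
  grades <- vapply(idx_eval, function(i) {
    suppressWarnings(grade_three_stage(bundles[[i]], models, cfg)$grade)
  }, character(1))
  truth <- vapply(states[idx_eval], `[[`, character(1), "true_grade")
  cm <- confusion(truth, grades)
  list(combination = combination, grades = grades,
       confusion = cm, metrics = class_metrics(cm),
       n = length(idx_eval))
}

#' Fit all trainable stage models from labelled synthetic data
#'
#' Convenience trainer used by the ablation harness, the CLI and the
#' examples: consolidates the bundles under the configured views, fits
#' the count SVRs against the true per-category counts, the root forest
#' against rule-derived root grades, and the quality classifier against
#' the ground-truth grades using the stage-2 model outputs as features
#' (so training matches the deployment-time feature distribution).
#'
#' @param states Ground-truth [seedling_state()]s.
#' @param bundles Matching detection bundles.
#' @param cfg A [pipeline_config()].
#' @param count_hyperparams,root_hyperparams,quality_hyperparams Optional
#'   argument lists forwarded to the stage trainers.
#' @return List with fitted `count`, `root`, `quality` models.
#' @export
train_stage_models <- function(states, bundles, cfg = pipeline_config(),
                               count_hyperparams = list(),
                               root_hyperparams = list(),
                               quality_hyperparams = list()) {
  keep_view <- function(sets) Filter(function(d) d$view %in% cfg$views, sets)
  mats <- lapply(bundles, function(b) consolidate_defects(keep_view(b$side_leaf)))
  X56 <- do.call(rbind, lapply(mats, flatten_features))
  Y <- do.call(rbind, lapply(states, true_defect_counts))
  count_model <- do.call(train_count_model, c(list(X = X56, Y = Y),
                                              count_hyperparams))
  Xroot <- do.call(rbind, lapply(bundles, function(b)
    root_counts_from_sets(keep_view(b$side_root))))
  Groot <- apply(Xroot, 1, function(r) as.integer(rule_grade(summarize_views(r))))
  root_model <- do.call(train_root_model, c(list(X = Xroot, G = Groot),
                                            root_hyperparams))
  feats <- do.call(rbind, lapply(seq_along(states), function(i) {
    flags <- top_view_flags(bundles[[i]]$top)
    areas <- accumulate_areas(keep_view(bundles[[i]]$side_leaf),
                              units = cfg$area_units)
    counts <- as.numeric(predict_counts(count_model, mats[[i]]))
    G <- predict_root_grade(root_model, Xroot[i, ])
    assemble_feature_vector(flags, counts, areas, cfg$score, G)
  }))
  labels <- vapply(states, `[[`, character(1), "true_grade")
  quality_model <- do.call(train_quality_model,
                           c(list(X = feats, labels = labels),
                             quality_hyperparams))
  list(count = count_model, root = root_model, quality = quality_model)
}

#' Brightness-sensitive top-view lesion detector
#'
#' A deliberately simple pixel detector used by the robustness sweep:
#' lesion blobs are recognised as "brown" pixels whose red channel
#' exceeds the green channel by at least `brown_margin` (leaves are
#' green-dominant, the background white). Linear brightness scaling
#' shrinks that channel gap, so the detector degrades under dim
#' illumination — mirroring how real detectors lose defects at low
#' alpha.
#'
#' @param rgb Rendered top-view image (0-255 array).
#' @param brown_margin Minimum R - G excess in intensity levels.
#' @param min_pixels Minimum blob pixel count to call a detection.
#' @return Logical: lesion detected.
#' @export
detect_top_blobs <- function(rgb, brown_margin = 20, min_pixels = 30L) {
  brown <- (rgb[, , 1] - rgb[, , 2]) >= brown_margin & rgb[, , 1] < 250
  sum(brown) >= min_pixels
}

#' Brightness robustness sweep
#'
#' Renders each seedling's top view, perturbs it with
#' [adjust_brightness()] at each coefficient, re-runs the
#' brightness-sensitive lesion detector, and scores detection of
#' upper-leaf lesions against ground truth per alpha. `alpha = 1` is the
#' unperturbed baseline and reproduces it bit-identically.
#'
#' @param states List of [seedling_state()]s.
#' @param alphas Positive brightness coefficients (the study grid is
#'   `c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75)`).
#' @param brown_margin,min_pixels Detector parameters, see
#'   [detect_top_blobs()].
#' @return `data.frame` with one row per alpha (ascending): `alpha`,
#'   `accuracy`, `precision`, `recall`, `f1`, `n`.
#' @export
run_brightness_sweep <- function(states,
                                 alphas = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75),
                                 brown_margin = 20, min_pixels = 30L) {
  if (any(alphas <= 0)) stop("alphas must be > 0")
  truth <- vapply(states, function(st)
    any(vapply(st$defects, `[[`, logical(1), "on_upper_leaf")), logical(1))
  renders <- lapply(states, function(st) render_top_view(st)$rgb)
  rows <- lapply(sort(alphas), function(a) {
    pred <- vapply(renders, function(img)
      detect_top_blobs(adjust_brightness(img, a), brown_margin, min_pixels),
      logical(1))
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    data.frame(alpha = a, accuracy = mean(pred == truth), precision = P,
               recall = R, f1 = if (P + R > 0) 2 * P * R / (P + R) else 0,
               n = length(states))
  })
  do.call(rbind, rows)
}
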