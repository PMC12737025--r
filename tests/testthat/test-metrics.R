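test_that("confusion matrices tabulate actual rows against predicted columns", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"))
  expect_identical(cm["A", "B"], 1L)
  expect_identical(sum(cm), 3L)
  perfect <- confusion(rep(c("A", "B", "C"), 5), rep(c("A", "B", "C"), 5))
  expect_identical(sum(diag(perfect)), 15L)
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion("A", "D"), "unknown labels")
  expect_error(confusion(c("A", "B"), "A"), "lengths differ")
})

test_that("published error-analysis pairs reconstruct with the right supports", {
  pairs <- labels_from_confusion(three_stage_confusion_counts())
  expect_length(pairs$actual, 153)
  cm <- confusion(pairs$actual, pairs$predicted)
  expect_identical(as.integer(rowSums(cm)), c(21L, 96L, 36L))
  expect_equal(unclass(cm), unclass(three_stage_confusion_counts()),
               ignore_attr = TRUE)
})

test_that("per-class metrics recompute the published grading evaluation", {
  m3 <- class_metrics(confusion_from_counts(three_stage_confusion_counts()))
  expect_equal(round(m3$per_class$precision, 4), c(0.6000, 0.8660, 0.7742))
  expect_equal(round(m3$per_class$recall, 4), c(0.7143, 0.8750, 0.6667))
  expect_equal(round(m3$per_class$f1[2:3], 4), c(0.8705, 0.7164))
  expect_equal(round(unname(m3$overall["f1"]), 4), 0.8043)
  md <- class_metrics(confusion_from_counts(direct_confusion_counts()))
  expect_equal(round(md$per_class$precision, 4), c(0.6800, 0.9674, 0.8333))
  expect_equal(round(md$per_class$recall[c(1, 3)], 4), c(0.8095, 0.8333))
  expect_equal(round(md$per_class$f1[3], 4), 0.8333)
  expect_equal(round(unname(md$overall["f1"]), 4), 0.8916)
})

test_that("overall metrics are support-weighted convex combinations", {
  set.seed(14)
  for (i in 1:15) {
    actual <- sample(c("A", "B", "C"), 60, replace = TRUE)
    predicted <- sample(c("A", "B", "C"), 60, replace = TRUE)
    m <- class_metrics(confusion(actual, predicted))
    for (nm in c("precision", "recall", "f1")) {
      v <- m$per_class[[nm]]
      expect_gte(m$overall[[nm]], min(v) - 1e-12)
      expect_lte(m$overall[[nm]], max(v) + 1e-12)
    }
    w <- m$per_class$support / sum(m$per_class$support)
    expect_equal(unname(m$overall["f1"]), sum(w * m$per_class$f1))
  }
})

test_that("diagonal matrices score perfectly; empty classes are flagged", {
  diag_cm <- confusion(rep(c("A", "B", "C"), 4), rep(c("A", "B", "C"), 4))
  m <- class_metrics(diag_cm)
  expect_true(all(c(m$per_class$precision, m$per_class$recall,
                    m$per_class$f1) == 1))
  expect_identical(unname(m$overall), c(1, 1, 1))
  absent <- confusion(c("A", "A", "B"), c("A", "A", "A"))
  ma <- class_metrics(absent)
  expect_identical(ma$per_class$recall[3], 0)   # no C samples
  expect_true("C" %in% ma$zero_division)
})

test_that("the view preset registry matches the published combinations", {
  expect_identical(view_combination("6-6")$angles,
                   c(0L, 90L, 135L, 180L, 270L, 315L))
  expect_identical(view_combination("6-6")$excluded, c(45L, 225L))
  expect_identical(view_combination("4-1")$angles, c(0L, 90L, 180L, 270L))
  expect_identical(view_combination("4-2")$angles, c(45L, 135L, 225L, 315L))
  expect_identical(view_combination("5-3")$angles, c(0L, 90L, 135L, 270L, 315L))
  expect_identical(view_combination("7-2")$excluded, 45L)
  expect_identical(view_combination("8")$excluded, integer(0))
  expect_length(view_presets(), 27)  # 8, 9 four-view, 3 five-view, 6 six-view, 8 seven-view
  expect_error(view_combination("9-1"), "unknown preset")
  custom <- view_combination(c(0, 180))
  expect_identical(custom$angles, c(0L, 180L))
})

test_that("the full 8-view ablation equals the un-ablated pipeline", {
  cfg <- zero_noise_config(seed = 91L)
  states <- generate_seedling_state(cfg, 40)
  bundles <- simulate_detections(states, cfg)
  pcfg <- pipeline_config()
  full <- run_view_ablation(states, bundles, "8", pcfg)
  baseline <- vapply(bundles, function(b)
    grade_three_stage(b, rules_models(), pcfg)$grade, character(1))
  expect_identical(full$grades, unname(baseline))
  expect_identical(unname(full$metrics$overall["f1"]), 1)
})

test_that("removing views can only lose information under the rule pipeline", {
  cfg <- zero_noise_config(seed = 92L)
  states <- generate_seedling_state(cfg, 80)
  bundles <- simulate_detections(states, cfg)
  pcfg <- pipeline_config()
  res66 <- run_view_ablation(states, bundles, "6-6", pcfg)
  res41 <- run_view_ablation(states, bundles, "4-1", pcfg)
  expect_identical(res66$combination$excluded, c(45L, 225L))
  # fewer views see fewer defects and fewer roots: scores shrink, grades drift
  expect_lte(unname(res41$metrics$overall["f1"]),
             unname(res66$metrics$overall["f1"]) + 1e-9)
  expect_lte(unname(res66$metrics$overall["f1"]), 1)
})

test_that("the brightness sweep is baseline-identical at alpha = 1 and degrades in the dark", {
  cfg <- zero_noise_config(seed = 93L)
  states <- generate_seedling_state(cfg, 25)
  sweep_df <- run_brightness_sweep(states)
  expect_identical(sweep_df$alpha, c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75))
  truth <- vapply(states, function(st)
    any(vapply(st$defects, `[[`, logical(1), "on_upper_leaf")), logical(1))
  baseline_pred <- vapply(states, function(st)
    detect_top_blobs(render_top_view(st)$rgb), logical(1))
  base_acc <- mean(baseline_pred == truth)
  expect_identical(sweep_df$accuracy[sweep_df$alpha == 1], base_acc)
  expect_lt(sweep_df$f1[sweep_df$alpha == 0.25],
            sweep_df$f1[sweep_df$alpha == 1])
})
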