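# shared fixtures, all generated in code

zero_noise_config <- function(seed = 42L, ...) {
  generator_config(detector_miss_rate = 0, detector_false_positive_rate = 0,
                   seed = seed, ...)
}

# a seedling with explicit, hand-checkable ground truth
fixture_state <- function(defects = list(), roots = rep(5L, 8),
                          damage = FALSE, shrink = FALSE, grade = NA) {
  st <- seedling_state(defects, roots, damage, shrink)
  if (is.na(grade)) st$true_grade <- derive_true_grade(st) else st$true_grade <- grade
  st
}

fixture_defect <- function(category = "Disease", size = 0.004,
                           views = c(0L, 45L), upper = FALSE) {
  defect_instance(category, size, views, upper)
}

# random but valid detection set for serialization property tests
random_detection_set <- function(scheme = side_leaf_scheme(), n = NULL,
                                 with_conf = FALSE) {
  if (is.null(n)) n <- sample(0:12, 1)
  if (n == 0) return(detection_set("img", 0L, NULL, c(3038L, 2548L), scheme))
  w <- round(runif(n, 0.01, 0.3), 6)
  h <- round(runif(n, 0.01, 0.3), 6)
  d <- data.frame(
    category = sample(scheme$labels, n, replace = TRUE),
    cx = round(pmin(pmax(runif(n), w / 2), 1 - w / 2), 6),
    cy = round(pmin(pmax(runif(n), h / 2), 1 - h / 2), 6),
    w = w, h = h,
    confidence = if (with_conf) round(runif(n), 6) else NA_real_)
  # rounding cx to 6 dp can push the box edge out by < 5e-7; renormalize
  d$cx <- pmin(pmax(d$cx, d$w / 2), 1 - d$w / 2)
  d$cy <- pmin(pmax(d$cy, d$h / 2), 1 - d$h / 2)
  detection_set("img", sample(side_view_angles(), 1), d, c(3038L, 2548L), scheme)
}

rules_models <- function() list(count = "rules", root = "rules", quality = "rules")

confusion_from_counts <- function(counts) {
  pairs <- labels_from_confusion(counts)
  confusion(pairs$actual, pairs$predicted)
}

# printed confusion matrices of the two grading methods (error analysis)
three_stage_confusion_counts <- function() {
  matrix(c(15L, 4L, 2L, 7L, 84L, 5L, 3L, 9L, 24L), 3, 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

direct_confusion_counts <- function() {
  matrix(c(17L, 1L, 3L, 4L, 89L, 3L, 4L, 2L, 30L), 3, 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}
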