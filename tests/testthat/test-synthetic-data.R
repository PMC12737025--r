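test_that("degenerate distributions give fully determined seedlings", {
  cfg <- generator_config(category_prevalence = rep(0, 7),
                          root_distribution = list(dist = "constant", value = 5))
  states <- generate_seedling_state(cfg, 25)
  expect_length(states, 25)
  for (st in states) {
    expect_length(st$defects, 0)
    expect_identical(st$roots_per_view, rep(5L, 8))
    expect_false(st$top_leaf_damage)
    expect_false(st$top_leaf_shrinkage)
  }
})

test_that("identical configs generate identical states and detections", {
  cfg <- zero_noise_config(seed = 7L)
  a <- generate_seedling_state(cfg, 20)
  b <- generate_seedling_state(cfg, 20)
  expect_identical(a, b)
  expect_identical(simulate_detections(a, cfg), simulate_detections(b, cfg))
})

test_that("defect counts follow the configured distribution", {
  cfg <- generator_config(
    defect_count_distribution = list(dist = "poisson", lambda = 3), seed = 11L)
  states <- generate_seedling_state(cfg, 1000)
  m <- mean(lengths(lapply(states, `[[`, "defects")))
  expect_gt(m, 2.7)
  expect_lt(m, 3.3)
})

test_that("invalid generator configuration names the offending field", {
  expect_error(generator_config(category_prevalence = rep(0.1, 5)),
               "category_prevalence")
  expect_error(generator_config(defect_count_distribution = list(dist = "zeta")),
               "defect_count_distribution")
  expect_error(generator_config(detector_miss_rate = 1.4),
               "detector_miss_rate")
  expect_error(generate_seedling_state(generator_config(), 0), "n")
})

test_that("defect view arcs are validated as contiguous on the view circle", {
  expect_silent(defect_instance("Disease", 0.01, c(315L, 0L, 45L)))
  expect_error(defect_instance("Disease", 0.01, c(0L, 90L)), "contiguous")
  expect_error(defect_instance("Disease", 0.01, integer()), "nonempty")
  expect_error(defect_instance("Rust", 0.01, 0L), "unknown category")
})

test_that("top view renders at the sensor resolution with layered depth", {
  st <- fixture_state()
  r <- render_top_view(st)
  expect_identical(dim(r$rgb), c(480L, 640L, 3L))
  expect_identical(dim(r$depth), c(480L, 640L))
  # upper leaves are rendered nearer than lower leaves
  upper <- r$rgb[, , 2] == 150
  lower <- r$rgb[, , 2] == 110
  expect_true(all(r$depth[upper] < min(r$depth[lower])))
})

test_that("leaf shrinkage renders upper leaves shorter than lower leaves", {
  st <- fixture_state(shrink = TRUE)
  r <- render_top_view(st)
  cx <- 640 / 2; cy <- 480 / 2
  dist_from_center <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    max(sqrt((idx[, 2] - cx)^2 + (idx[, 1] - cy)^2))
  }
  upper <- r$rgb[, , 2] == 150
  lower <- r$rgb[, , 2] == 110
  expect_lt(dist_from_center(upper), dist_from_center(lower))
})

test_that("defect-free seedlings render only leaf-colored plant pixels", {
  r <- render_top_view(fixture_state())
  plant <- r$rgb[, , 1] < 250  # non-white
  g <- r$rgb[, , 2][plant]
  expect_true(all(g %in% c(110, 150)))
  # a seedling with an upper-leaf lesion does show blob pixels
  st2 <- fixture_state(list(fixture_defect(upper = TRUE)))
  r2 <- render_top_view(st2)
  expect_gt(sum(r2$rgb[, , 1] == 120 & r2$rgb[, , 2] == 80), 0)
})

test_that("zero-noise detections appear exactly in the visible views", {
  cfg <- zero_noise_config()
  st <- fixture_state(list(fixture_defect(views = c(0L, 45L))))
  expect_identical(nrow(emit_detections(st, 0L, cfg)$detections), 1L)
  expect_identical(nrow(emit_detections(st, 45L, cfg)$detections), 1L)
  expect_identical(nrow(emit_detections(st, 90L, cfg)$detections), 0L)
  # root sets carry one detection per visible root
  expect_identical(nrow(emit_detections(st, 90L, cfg, role = "side_root")$detections), 5L)
  # the detected box area equals the instance's normalized lesion area
  d0 <- emit_detections(st, 0L, cfg)
  expect_equal(detection_areas(d0), 0.004, tolerance = 1e-12)
})

test_that("detector noise rates behave as Bernoulli/Poisson draws", {
  st_many <- fixture_state(lapply(1:125, function(i)
    fixture_defect(views = side_view_angles())))
  miss_all <- generator_config(detector_miss_rate = 1)
  expect_identical(nrow(emit_detections(st_many, 0L, miss_all)$detections), 0L)
  miss_some <- generator_config(detector_miss_rate = 0.2)
  set.seed(123)
  kept <- sum(vapply(side_view_angles(), function(v)
    nrow(emit_detections(st_many, v, miss_some)$detections), integer(1)))
  expect_gt(kept / 1000, 0.76)
  expect_lt(kept / 1000, 0.84)
  fp <- generator_config(detector_false_positive_rate = 3)
  set.seed(5)
  n_fp <- mean(replicate(200, nrow(emit_detections(fixture_state(), 0L, fp)$detections)))
  expect_gt(n_fp, 2.5); expect_lt(n_fp, 3.5)
})

test_that("ground-truth grades follow the scoring rules", {
  # flawless seedling with vigorous roots in all views
  expect_identical(derive_true_grade(fixture_state()), "A")
  # huge total defect area pushes the score past the C threshold
  big <- fixture_state(list(fixture_defect(size = 0.2, views = side_view_angles())))
  expect_identical(derive_true_grade(big), "C")
  # S exactly at the A threshold falls in the half-open B band
  th <- grade_thresholds()
  boundary <- fixture_state(list(fixture_defect(size = th$t_a, views = 0L)))
  expect_identical(derive_true_grade(boundary), "B")
  # poor roots cap the grade regardless of a clean score
  weak_roots <- fixture_state(roots = c(0L, 1L, rep(5L, 6)))
  expect_identical(derive_true_grade(weak_roots), "C")
})

test_that("true counts and view-integrated areas aggregate instances", {
  st <- fixture_state(list(
    fixture_defect("Disease", 0.01, c(0L, 45L, 90L)),
    fixture_defect("Disease", 0.02, 180L),
    fixture_defect("Variation", 0.005, c(270L, 315L))))
  counts <- true_defect_counts(st)
  expect_identical(unname(counts[c("Disease", "Variation")]), c(2L, 1L))
  areas <- true_area_vector(st)
  expect_equal(unname(areas["Disease"]), 0.01 * 3 + 0.02)
  expect_equal(unname(areas["Variation"]), 0.005 * 2)
})
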