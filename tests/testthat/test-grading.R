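test_that("score bands and root mapping combine by worse-of severity", {
  th <- grade_thresholds(10, 30)
  expect_identical(rule_based_grade(5, 3, th), "A")
  expect_identical(rule_based_grade(5, 2, th), "B")   # roots cap a clean score
  expect_identical(rule_based_grade(5, 1, th), "C")
  expect_identical(rule_based_grade(10, 2, th), "B")  # S = T_A: half-open B band
  expect_identical(rule_based_grade(35, 3, th), "C")  # bad score beats good roots
  expect_identical(rule_based_grade(29.999, 3, th), "B")
  expect_identical(rule_based_grade(30, 3, th), "C")  # S = T_C enters C
  # alternative policies let one signal win
  expect_identical(rule_based_grade(35, 3, th, policy = "root_priority"), "A")
  expect_identical(rule_based_grade(5, 1, th, policy = "score_priority"), "A")
  expect_error(rule_based_grade(-1, 3, th), ">= 0")
  expect_error(grade_thresholds(30, 10), "t_a < t_c")
})

test_that("the combined grade is monotone in S and never better than either signal", {
  th <- grade_thresholds(10, 30)
  sev <- function(g) match(g, c("A", "B", "C"))
  grid_S <- c(0, 5, 9.999, 10, 20, 29.999, 30, 50)
  for (G in 1:3) {
    grades <- rule_based_grade(grid_S, rep(G, length(grid_S)), th)
    expect_true(all(diff(sev(grades)) >= 0))
    for (i in seq_along(grid_S)) {
      expect_gte(sev(grades[i]), sev(rule_based_grade(grid_S[i], 3, th)))
      expect_gte(sev(grades[i]), sev(c("C", "B", "A")[G]))
    }
  }
})

test_that("the three-stage pipeline reproduces ground truth at zero noise", {
  cfg <- zero_noise_config(seed = 77L)
  states <- generate_seedling_state(cfg, 60)
  bundles <- simulate_detections(states, cfg)
  pcfg <- pipeline_config()
  for (i in seq_along(states)) {
    res <- grade_three_stage(bundles[[i]], rules_models(), pcfg)
    expect_identical(res$grade, states[[i]]$true_grade)
    # provenance score equals an independent recomputation
    expect_equal(res$provenance$S,
                 weighted_score(accumulate_areas(bundles[[i]]$side_leaf),
                                pcfg$score))
  }
})

test_that("a defect-free vigorous seedling grades A; a giant lesion grades C", {
  cfg <- zero_noise_config()
  pcfg <- pipeline_config()
  clean <- fixture_state()
  b <- simulate_detections(list(clean), cfg)[[1]]
  expect_identical(grade_three_stage(b, rules_models(), pcfg)$grade, "A")
  lesioned <- fixture_state(list(fixture_defect(size = 0.1,
                                                views = side_view_angles())))
  b2 <- simulate_detections(list(lesioned), cfg)[[1]]
  res <- grade_three_stage(b2, rules_models(), pcfg)
  expect_identical(res$grade, "C")
  expect_gte(res$provenance$S, pcfg$thresholds$t_c)
})

test_that("the pipeline requires a top view and warns on missing side views", {
  cfg <- zero_noise_config()
  b <- simulate_detections(list(fixture_state()), cfg)[[1]]
  expect_error(grade_three_stage(list(side_leaf = b$side_leaf,
                                      side_root = b$side_root)),
               "top view")
  b$side_leaf <- b$side_leaf[1:3]
  expect_warning(grade_three_stage(b, rules_models(), pipeline_config()),
                 "zero-padded")
})

test_that("threshold calibration recovers separated score bands", {
  set.seed(9)
  n <- 600
  band <- sample(1:3, n, replace = TRUE, prob = c(.3, .4, .3))
  S <- ifelse(band == 1, runif(n, 0, 8),
              ifelse(band == 2, runif(n, 12, 27), runif(n, 33, 60)))
  G <- sample(1:3, n, replace = TRUE, prob = c(.05, .2, .75))
  labels <- rule_based_grade(S, G, grade_thresholds(10, 30))
  th <- calibrate_thresholds(S[1:400], G[1:400], labels[1:400], seed = 1L)
  pred <- rule_based_grade(S[401:600], G[401:600], th)
  f1 <- class_metrics(confusion(labels[401:600], pred))$overall["f1"]
  expect_gte(unname(f1), 0.95)
  # the recovered cut points respect the generating band gaps loosely
  expect_lt(th$t_a, 12); expect_gt(th$t_c, 20)
})

test_that("calibration is order-invariant and honours an explicit grid", {
  set.seed(10)
  n <- 90
  S <- runif(n, 0, 50)
  G <- sample(1:3, n, replace = TRUE)
  labels <- rule_based_grade(S, G, grade_thresholds(10, 30))
  th1 <- calibrate_thresholds(S, G, labels, seed = 3L)
  perm <- sample(n)
  th2 <- calibrate_thresholds(S[perm], G[perm], labels[perm], seed = 3L)
  expect_identical(th1, th2)
  single <- data.frame(t_a = 11, t_c = 29)
  th3 <- calibrate_thresholds(S, G, labels, grid = single)
  expect_identical(c(th3$t_a, th3$t_c), c(11, 29))
  expect_error(calibrate_thresholds(S, G, labels,
                                    grid = data.frame(t_a = 30, t_c = 10)),
               "no achievable")
})

test_that("direct grading takes the modal vote with ties toward the worse grade", {
  expect_identical(grade_direct("A", rep("A", 8))$grade, "A")
  expect_identical(grade_direct("B", c(rep("B", 4), rep("A", 4)))$grade, "B")
  tie <- grade_direct(NULL, c(rep("A", 4), rep("C", 4)))
  expect_identical(tie$grade, "C")
  expect_true(tie$provenance$tie)
  expect_identical(grade_direct("B", c("A", "C"))$grade, "C")  # 3-way tie
  expect_error(grade_direct(NULL, character()), "at least one vote")
  expect_error(grade_direct("D"), "A, B or C")
})

test_that("direct-method votes are permutation invariant", {
  set.seed(13)
  for (i in 1:20) {
    votes <- sample(c("A", "B", "C"), 9, replace = TRUE)
    g1 <- grade_direct(votes[1], votes[-1])$grade
    perm <- sample(votes)
    expect_identical(grade_direct(perm[1], perm[-1])$grade, g1)
  }
})

test_that("synthetic per-image votes drive the direct method sensibly", {
  cfg <- zero_noise_config(seed = 88L)
  pcfg <- pipeline_config()
  states <- generate_seedling_state(cfg, 40)
  res <- vapply(states, function(st) {
    v <- oracle_view_votes(st, pcfg)
    grade_direct(v$top_vote, v$side_votes)$grade
  }, character(1))
  truth <- vapply(states, `[[`, character(1), "true_grade")
  expect_gte(mean(res == truth), 0.6)  # voting is coarser than three-stage
  expect_length(oracle_view_votes(states[[1]], pcfg)$side_votes, 8)
})
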