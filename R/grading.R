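#' Score thresholds of the A/B/C bands
#'
#' The calibrated cut points partitioning the weighted defect score S:
#' S < T_A is the A band, T_A <= S < T_C the B band, S >= T_C the C
#' band (half-open at both boundaries). Defaults are expressed in
#' normalized view-integrated area units and sized to the synthetic
#' generator's lesion scale; production deployments calibrate them
#' against expert records with [calibrate_thresholds()].
#'
#' @param t_a,t_c Score thresholds with `0 <= t_a < t_c`.
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(t_a = 0.005, t_c = 0.03) {
  if (!is.numeric(t_a) || !is.numeric(t_c) || t_a < 0 || t_a >= t_c)
    stop("need 0 <= t_a < t_c")
  structure(list(t_a = t_a, t_c = t_c), class = "grade_thresholds")
}

GRADE_LEVELS <- c("A", "B", "C")  # severity increases rightwards

score_band_grade <- function(S, th) {
  ifelse(S < th$t_a, "A", ifelse(S < th$t_c, "B", "C"))
}

root_grade_to_quality <- function(G) {
  c("C", "B", "A")[as.integer(G)]
}

#' Combine score and root grade into the final quality grade
#'
#' Maps the weighted defect score S to its band grade and the root grade
#' G to a quality grade (G = 3 -> A, 2 -> B, 1 -> C), then combines the
#' two. The grading standard states the clauses as alternatives, which
#' can conflict (e.g. a spotless plant with a poor root system); the
#' default resolution takes the WORSE of the two grades, matching the
#' commercial risk posture in which shipping a poor seedling as Grade A
#' is the costliest error. `score_priority` and `root_priority` let one
#' signal win outright instead.
#'
#' @param S Weighted defect score(s), >= 0 (vectorized).
#' @param G Root grade(s) in `1:3` (vectorized, recycled).
#' @param th A [grade_thresholds()].
#' @param policy Conflict resolution between the score band and the root
#'   grade.
#' @return Character grade(s) `"A"`, `"B"` or `"C"`.
#' @export
rule_based_grade <- function(S, G, th = grade_thresholds(),
                             policy = c("worse_of", "score_priority",
                                        "root_priority")) {
  policy <- match.arg(policy)
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be finite and >= 0")
  G <- as.integer(G)
  if (any(!G %in% 1:3)) stop("G must be in 1:3")
  sg <- score_band_grade(S, th)
  rg <- root_grade_to_quality(G)
  switch(policy,
         worse_of = GRADE_LEVELS[pmax(match(sg, GRADE_LEVELS),
                                      match(rg, GRADE_LEVELS))],
         score_priority = sg,
         root_priority = rg)
}

#' Run the three-stage grading pipeline on one seedling
#'
#' Stage 1 consumes per-image detections (the `bundle`): a top-view set
#' plus per-angle side-view leaf and root sets. Stage 2 consolidates the
#' side views into the 56-d count features and the 8-d root count
#' vector, estimates per-category defect counts (trained SVR, or the raw
#' multi-view totals in rules mode) and the root grade (trained forest,
#' or the rule standard). Stage 3 assembles the 17-d feature vector and
#' predicts the final grade (trained classifier, or the score/root-grade
#' combination rules). Full per-stage provenance is recorded.
#'
#' @param bundle List with `top` (top-view [detection_set()], required),
#'   `side_leaf` and `side_root` (lists of side-view sets; missing views
#'   are zero-padded with a warning).
#' @param models List with `count`, `root`, `quality`: each a fitted
#'   stage model or `"rules"`.
#' @param cfg A [pipeline_config()].
#' @return An object of class `grade_result`: `grade` plus `provenance`
#'   (flags, count matrix, counts, areas, S, root counts, root grade and
#'   its rule source, method).
#' @export
grade_three_stage <- function(bundle, models = list(count = "rules",
                                                    root = "rules",
                                                    quality = "rules"),
                              cfg = pipeline_config()) {
  if (is.null(bundle$top))
    stop("the three-stage method requires a top view")
  keep_view <- function(sets) Filter(function(d) d$view %in% cfg$views, sets)
  side_leaf <- keep_view(bundle$side_leaf %||% list())
  side_root <- keep_view(bundle$side_root %||% list())
  if (length(side_leaf) < length(cfg$views))
    warning("only ", length(side_leaf), " of ", length(cfg$views),
            " configured side views present; missing views zero-padded")
  flags <- top_view_flags(bundle$top)
  mat <- consolidate_defects(side_leaf)
  areas <- accumulate_areas(side_leaf, units = cfg$area_units)
  S <- weighted_score(areas, cfg$score)
  root_counts <- root_counts_from_sets(side_root)
  if (identical(models$root, "rules")) {
    g <- rule_grade(summarize_views(root_counts), cfg$root_rules)
    G <- as.integer(g)
    root_source <- attr(g, "source")
  } else {
    G <- predict_root_grade(models$root, root_counts)
    root_source <- "random_forest"
  }
  counts <- if (identical(models$count, "rules")) {
    as.numeric(colSums(unclass(mat)))  # raw multi-view totals
  } else {
    as.numeric(predict_counts(models$count, mat))
  }
  fv <- assemble_feature_vector(flags, counts, areas, cfg$score, G)
  grade <- if (identical(models$quality, "rules")) {
    rule_based_grade(S, G, cfg$thresholds, policy = cfg$policy)
  } else {
    predict_quality(models$quality, fv)
  }
  structure(list(
    grade = grade,
    provenance = list(method = "three_stage", top_flags = flags,
                      count_matrix = mat, counts = counts, areas = areas,
                      S = S, root_counts = root_counts, root_grade = G,
                      root_grade_source = root_source,
                      feature_vector = fv, votes = NULL,
                      models = vapply(models, function(m)
                        if (identical(m, "rules")) "rules" else class(m)[1],
                        character(1)))),
    class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  p <- x$provenance
  cat("<grade_result>", x$grade, "via", p$method, "\n")
  if (!is.null(p$S)) cat(sprintf("  S = %.5f, root grade = %d (%s)\n",
                                 p$S, p$root_grade, p$root_grade_source))
  if (!is.null(p$votes)) {
    cat("  votes:", paste(names(p$votes), p$votes, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Calibrate the A/B/C score thresholds
#'
#' Grid search over pairs of score quantiles, maximizing the mean
#' cross-validated support-weighted F1 of [rule_based_grade()] against
#' expert labels. Ties break toward the larger A band (larger T_A, then
#' larger T_C). Samples are put in canonical order before the seeded
#' fold assignment so input permutations cannot change the result.
#'
#' @param scores Weighted defect scores S.
#' @param root_grades Root grades in `1:3`.
#' @param labels Expert quality grades `"A"/"B"/"C"`.
#' @param folds Number of cross-validation folds.
#' @param grid_probs Quantile probabilities generating candidate
#'   thresholds.
#' @param grid Optional explicit candidate grid, a `data.frame` with
#'   columns `t_a`, `t_c` (rows with `t_a >= t_c` are skipped). A single
#'   valid grid point is returned verbatim.
#' @param policy Passed to [rule_based_grade()].
#' @param seed Fold-assignment seed.
#' @return A [grade_thresholds()] with attribute `cv_f1`.
#' @export
calibrate_thresholds <- function(scores, root_grades, labels, folds = 5L,
                                 grid_probs = seq(0.05, 0.95, by = 0.05),
                                 grid = NULL, policy = "worse_of", seed = 42L) {
  n <- length(scores)
  if (n < 30L) stop("need at least 30 labelled samples")
  if (length(root_grades) != n || length(labels) != n)
    stop("scores, root_grades and labels must have equal length")
  if (!all(GRADE_LEVELS %in% labels)) stop("all three grades must be present")
  ord <- order(scores, root_grades, labels)
  scores <- scores[ord]; root_grades <- root_grades[ord]; labels <- labels[ord]
  if (is.null(grid)) {
    qs <- sort(unique(stats::quantile(scores, grid_probs, names = FALSE)))
    grid <- expand.grid(t_a = qs, t_c = qs)
  }
  grid <- grid[grid$t_a < grid$t_c & grid$t_a >= 0, , drop = FALSE]
  if (!nrow(grid)) stop("no achievable (t_a, t_c) ordering on the grid")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = n))
  cv_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    th <- grade_thresholds(grid$t_a[i], grid$t_c[i])
    mean(vapply(seq_len(folds), function(f) {
      hold <- fold_of == f
      pred <- rule_based_grade(scores[hold], root_grades[hold], th, policy)
      cm <- confusion(labels[hold], pred)
      unname(class_metrics(cm)$overall["f1"])
    }, numeric(1)))
  }, numeric(1))
  best <- which(cv_f1 == max(cv_f1))
  best <- best[order(-grid$t_a[best], -grid$t_c[best])][1L]
  structure(grade_thresholds(grid$t_a[best], grid$t_c[best]),
            cv_f1 = cv_f1[best])
}

#' Direct grading by majority vote over per-image grades
#'
#' The fast single-stage method: every image (the top view and up to
#' eight side views) contributes one quality-grade vote; the final grade
#' is the modal vote, with ties broken toward the worse grade (so a
#' split decision never upgrades a seedling). The vote tally is recorded
#' in the provenance.
#'
#' @param top_vote Grade voted by the top-view model (`"A"/"B"/"C"`), or
#'   `NULL` if unavailable.
#' @param side_votes Character vector of up to 8 side-view votes.
#' @return A `grade_result` with vote provenance.
#' @export
grade_direct <- function(top_vote, side_votes = character()) {
  votes <- c(top_vote, side_votes)
  if (!length(votes)) stop("at least one vote is required")
  if (!all(votes %in% GRADE_LEVELS)) stop("votes must be A, B or C")
  tally <- table(factor(votes, levels = GRADE_LEVELS))
  winners <- names(tally)[tally == max(tally)]
  grade <- winners[which.max(match(winners, GRADE_LEVELS))]  # tie -> worse
  structure(list(grade = grade,
                 provenance = list(method = "direct", votes = tally,
                                   n_votes = length(votes),
                                   tie = length(winners) > 1L)),
            class = "grade_result")
}

#' Synthetic per-image grade votes for the direct method
#'
#' A stand-in for the per-image grading models of the direct method,
#' built from ground truth: each side view votes from what it can see
#' (its visible defect areas, scaled up by the number of configured
#' views to the whole-seedling score scale, and its own root count
#' binned to a root grade), and the top view votes from the upper-leaf
#' flags. Used to exercise the voting combiner on synthetic data.
#'
#' @param state A [seedling_state()].
#' @param cfg A [pipeline_config()].
#' @return List with `top_vote` and `side_votes` (one per configured
#'   view).
#' @export
oracle_view_votes <- function(state, cfg = pipeline_config()) {
  side_votes <- vapply(cfg$views, function(v) {
    S_v <- 0
    for (d in state$defects) if (v %in% d$visible_views)
      S_v <- S_v + cfg$score$weights[[d$category]] * d$size
    S_v <- S_v * length(cfg$views)
    n_root <- state$roots_per_view[match(v, side_view_angles())]
    G_v <- if (n_root >= 3L) 3L else if (n_root == 2L) 2L else 1L
    rule_based_grade(S_v, G_v, cfg$thresholds, policy = cfg$policy)
  }, character(1))
  top_vote <- if (state$top_leaf_damage || state$top_leaf_shrinkage) "B" else "A"
  list(top_vote = top_vote, side_votes = unname(side_votes))
}
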