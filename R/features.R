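#' Consolidate per-view leaf-defect detections into the 8 x 7 count matrix
#'
#' Builds the view-by-category detection count matrix that feeds the
#' defect count estimator. Entry (v, c) is the number of category-c
#' detections in side view v; the same physical defect re-detected from
#' adjacent angles contributes once per view, so matrix totals can exceed
#' the true instance count. Views without a supplied detection set (e.g.
#' removed under ablation) contribute zero rows, keeping the flattened
#' length fixed at 56.
#'
#' @param per_view_sets List of side-view [detection_set()]s under the
#'   `side_leaf` scheme; at most one per angle.
#' @return Integer matrix, 8 rows (angles `0..315`) x 7 columns
#'   ([defect_categories()]), class `defect_feature_matrix`.
#' @export
consolidate_defects <- function(per_view_sets) {
  angles <- side_view_angles()
  cats <- defect_categories()
  m <- matrix(0L, nrow = 8L, ncol = 7L,
              dimnames = list(paste0("view_", angles), cats))
  seen <- integer(0)
  for (dset in per_view_sets) {
    stopifnot(inherits(dset, "detection_set"))
    if (identical(dset$view, "top") || dset$scheme$name != "side_leaf")
      stop("consolidate_defects expects side_leaf side-view sets")
    if (dset$view %in% seen) stop("duplicate view ", dset$view)
    seen <- c(seen, dset$view)
    m[match(dset$view, angles), ] <- count_by_category(dset)
  }
  structure(m, class = c("defect_feature_matrix", class(m)))
}

#' Flatten the count matrix to the 56-d stage-2 input
#'
#' View-major order: the 7 category counts of view 0, then view 45, and
#' so on.
#'
#' @param matrix A [consolidate_defects()] matrix.
#' @return Numeric vector of length 56.
#' @export
flatten_features <- function(matrix) {
  stopifnot(nrow(matrix) == 8L, ncol(matrix) == 7L)
  as.vector(t(unclass(matrix)))
}

#' Per-category any-view presence
#'
#' A seedling exhibits a defect category if any one of the eight
#' perspectives detects it — the multi-view aggregation rule that lifts
#' weak per-view recall.
#'
#' @param matrix A [consolidate_defects()] matrix.
#' @return Named logical vector of length 7.
#' @export
any_view_presence <- function(matrix) {
  stopifnot(nrow(matrix) == 8L, ncol(matrix) == 7L)
  colSums(unclass(matrix)) > 0
}

#' Accumulate per-category defect areas across views
#'
#' Total predicted box area per defect category, integrated across the
#' supplied side views (the A_i of the weighted defect score). Areas are
#' normalized box areas by default; pixel^2 is available when image
#' dimensions matter.
#'
#' @inheritParams consolidate_defects
#' @param units `"normalized"` (fraction of image area, default) or
#'   `"pixel"`.
#' @return Named nonnegative numeric vector of length 7.
#' @export
accumulate_areas <- function(per_view_sets, units = c("normalized", "pixel")) {
  units <- match.arg(units)
  cats <- defect_categories()
  areas <- stats::setNames(numeric(7), cats)
  seen <- integer(0)
  for (dset in per_view_sets) {
    stopifnot(inherits(dset, "detection_set"))
    if (dset$view %in% seen) stop("duplicate view ", dset$view)
    seen <- c(seen, dset$view)
    d <- dset$detections
    keep <- d$category %in% cats
    if (!any(keep)) next
    a <- detection_areas(dset, units)[keep]
    sums <- tapply(a, factor(d$category[keep], levels = cats), sum)
    sums[is.na(sums)] <- 0
    areas <- areas + as.numeric(sums)
  }
  areas
}

#' Expert weighting of defect severities
#'
#' Holds the positive per-category weights w_i of the weighted defect
#' score S = sum_i w_i * A_i. The expert-assigned weights of the original
#' grading guideline are not published; the default is unit weights, and
#' deployments supply their own.
#'
#' @param weights Positive numeric vector of length 7, optionally named by
#'   [defect_categories()].
#' @return An object of class `score_config` with fields `weights` and
#'   `k = 7`.
#' @export
score_config <- function(weights = rep(1, 7)) {
  if (length(weights) != 7L || any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be 7 positive finite values")
  names(weights) <- defect_categories()
  structure(list(weights = weights, k = 7L), class = "score_config")
}

#' Weighted defect score
#'
#' S = sum_i w_i * A_i over the 7 defect categories: the scalar severity
#' score whose calibrated bands define the A/B/C score grade.
#'
#' @param areas Per-category area vector (see [accumulate_areas()]).
#' @param cfg A [score_config()].
#' @return Nonnegative scalar S.
#' @export
weighted_score <- function(areas, cfg = score_config()) {
  stopifnot(inherits(cfg, "score_config"))
  if (length(areas) != cfg$k) stop("`areas` must have length ", cfg$k)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be finite and nonnegative")
  sum(cfg$weights * areas)
}

#' Top-view defect flags
#'
#' Presence of leaf damage and leaf shrinkage on the upper leaves, derived
#' solely from the top-view detection set (the two defects that the
#' side views resolve poorly).
#'
#' @param dset Top-view [detection_set()] under the `top` scheme.
#' @return List with logical fields `leaf_damage_present`,
#'   `leaf_shrinkage_present`.
#' @export
top_view_flags <- function(dset) {
  stopifnot(inherits(dset, "detection_set"))
  if (dset$scheme$name != "top") stop("expected a top-scheme detection set")
  cats <- dset$detections$category
  list(leaf_damage_present = "Leaf damage" %in% cats,
       leaf_shrinkage_present = "Leaf shrinkage" %in% cats)
}

#' Assemble the 17-d whole-seedling feature vector
#'
#' Fixed layout consumed by the stage-3 quality classifier:
#' `[leaf damage flag, shrinkage flag | 7 predicted counts |
#' 7 weighted areas w_i * A_i | root grade]`. The weighted areas are kept
#' per category (their sum is the score S).
#'
#' @param flags [top_view_flags()] result.
#' @param counts Predicted per-category defect counts (length 7).
#' @param areas Per-category areas A_i (length 7).
#' @param cfg A [score_config()].
#' @param root_grade Root grade in `1:3`.
#' @return Named numeric vector of length 17.
#' @export
assemble_feature_vector <- function(flags, counts, areas, cfg = score_config(),
                                    root_grade) {
  if (length(counts) != 7L) stop("`counts` must have length 7")
  if (length(areas) != 7L) stop("`areas` must have length 7")
  root_grade <- as.integer(root_grade)
  if (!root_grade %in% 1:3) stop("`root_grade` must be 1, 2 or 3")
  v <- c(as.numeric(isTRUE(flags$leaf_damage_present)),
         as.numeric(isTRUE(flags$leaf_shrinkage_present)),
         as.numeric(counts),
         as.numeric(cfg$weights * areas),
         root_grade)
  names(v) <- c("leaf_damage", "leaf_shrinkage",
                paste0("count_", seq_len(7)),
                paste0("warea_", seq_len(7)),
                "root_grade")
  v
}

#' Per-view root counts from root-scheme detection sets
#'
#' The per-view root quantity is the raw number of root detections in
#' that view. Views without a supplied set count zero.
#'
#' @param per_view_sets List of side-view [detection_set()]s under the
#'   `side_root` scheme.
#' @return Integer vector of length 8 in angle order.
#' @export
root_counts_from_sets <- function(per_view_sets) {
  angles <- side_view_angles()
  counts <- stats::setNames(integer(8), paste0("view_", angles))
  seen <- integer(0)
  for (dset in per_view_sets) {
    stopifnot(inherits(dset, "detection_set"))
    if (dset$scheme$name != "side_root")
      stop("expected side_root detection sets")
    if (dset$view %in% seen) stop("duplicate view ", dset$view)
    seen <- c(seen, dset$view)
    counts[match(dset$view, angles)] <- nrow(dset$detections)
  }
  counts
}

#' Export a feature table
#'
#' Writes one row per seedling (the 17-d feature vector plus id and label
#' columns) as CSV.
#'
#' @param features Matrix or data.frame of 17-d feature rows.
#' @param labels Optional grade labels.
#' @param path Output CSV path.
#' @param ids Optional seedling ids.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, labels = NULL, ids = NULL) {
  df <- as.data.frame(features)
  if (!is.null(ids)) df <- cbind(seedling_id = ids, df)
  if (!is.null(labels)) df$grade <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
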