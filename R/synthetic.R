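#' Configuration of the synthetic seedling generator
#'
#' The generator emulates the study conditions of a commercial
#' 2.5-inch Phalaenopsis batch: each seedling bears zero or more defect
#' instances drawn over 7 categories, every instance is visible from a
#' contiguous arc of the 8 side views (so the same defect is re-detected
#' from adjacent angles), roots are partially occluded per view, and
#' upper-leaf damage/shrinkage shows in the top view. Defaults give
#' roughly one-fifth defect-free seedlings, matching the published
#' dataset composition.
#'
#' Distributions are small declarative lists: `list(dist = "poisson",
#' lambda = ...)`, `list(dist = "constant", value = ...)`, or (for the
#' view span) `list(dist = "categorical", probs = ...)` over spans 1..8.
#'
#' @param category_prevalence 7 nonnegative weights over
#'   [defect_categories()]; all-zero means no defects are generated.
#' @param defect_count_distribution Distribution of defect instances per
#'   seedling.
#' @param view_span_distribution Distribution over the number of
#'   consecutive side views an instance is visible from (1..8).
#' @param size_distribution Lognormal parameters (`meanlog`, `sdlog`) of
#'   the lesion area in normalized image-area units.
#' @param root_distribution Distribution of visible roots per side view.
#' @param upper_leaf_prob Probability a defect sits on an upper leaf
#'   (hence may show in the top view).
#' @param detector_miss_rate Probability in \[0,1\] that the synthetic
#'   detector drops a true instance in a given view.
#' @param detector_false_positive_rate Expected spurious detections per
#'   image (Poisson).
#' @param score [score_config()] used when deriving ground-truth grades.
#' @param thresholds [grade_thresholds()] used when deriving ground-truth
#'   grades.
#' @param seed Integer seed; identical configs generate identical data.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(category_prevalence = c(0.10, 0.08, 0.10, 0.22,
                                                     0.15, 0.15, 0.20),
                             defect_count_distribution = list(dist = "poisson", lambda = 1.5),
                             view_span_distribution = list(dist = "categorical",
                                                           probs = c(0.35, 0.30, 0.20, 0.15)),
                             size_distribution = list(meanlog = log(0.004), sdlog = 0.6),
                             root_distribution = list(dist = "poisson", lambda = 6),
                             upper_leaf_prob = 0.5,
                             detector_miss_rate = 0,
                             detector_false_positive_rate = 0,
                             score = score_config(),
                             thresholds = grade_thresholds(),
                             seed = 42L) {
  if (length(category_prevalence) != 7L || any(category_prevalence < 0) ||
      any(!is.finite(category_prevalence)))
    stop("configuration error in `category_prevalence`: need 7 nonnegative weights")
  validate_distribution(defect_count_distribution, "defect_count_distribution",
                        kinds = c("poisson", "constant"))
  validate_distribution(view_span_distribution, "view_span_distribution",
                        kinds = c("categorical", "constant"))
  validate_distribution(root_distribution, "root_distribution",
                        kinds = c("poisson", "constant"))
  if (!is.numeric(size_distribution$meanlog) || !is.numeric(size_distribution$sdlog) ||
      size_distribution$sdlog < 0)
    stop("configuration error in `size_distribution`: need meanlog and sdlog >= 0")
  for (nm in c("detector_miss_rate", "upper_leaf_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error in `", nm, "`: must lie in [0, 1]")
  }
  if (detector_false_positive_rate < 0)
    stop("configuration error in `detector_false_positive_rate`: must be >= 0")
  stopifnot(inherits(score, "score_config"), inherits(thresholds, "grade_thresholds"))
  structure(list(category_prevalence = category_prevalence,
                 defect_count_distribution = defect_count_distribution,
                 view_span_distribution = view_span_distribution,
                 size_distribution = size_distribution,
                 root_distribution = root_distribution,
                 upper_leaf_prob = upper_leaf_prob,
                 detector_miss_rate = detector_miss_rate,
                 detector_false_positive_rate = detector_false_positive_rate,
                 score = score, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "generator_config")
}

validate_distribution <- function(d, field, kinds) {
  ok <- is.list(d) && !is.null(d$dist) && d$dist %in% kinds
  if (ok) {
    ok <- switch(d$dist,
      poisson = is.numeric(d$lambda) && length(d$lambda) == 1L && d$lambda >= 0,
      constant = is.numeric(d$value) && length(d$value) == 1L && d$value >= 0,
      categorical = is.numeric(d$probs) && length(d$probs) >= 1L &&
        length(d$probs) <= 8L && all(d$probs >= 0) && sum(d$probs) > 0)
  }
  if (!ok)
    stop("configuration error in `", field, "`: unsupported or incomplete ",
         "distribution (allowed: ", paste(kinds, collapse = ", "), ")")
  invisible(d)
}

draw_from <- function(d, n = 1L) {
  switch(d$dist,
         poisson = stats::rpois(n, d$lambda),
         constant = rep(as.integer(round(d$value)), n),
         categorical = sample(seq_along(d$probs), n, replace = TRUE,
                              prob = d$probs))
}

#' One defect instance on a seedling
#'
#' @param category One of [defect_categories()].
#' @param size Lesion area in normalized image-area units (> 0).
#' @param visible_views Nonempty contiguous arc of side-view angles the
#'   instance is detectable from.
#' @param on_upper_leaf Whether the instance sits on an upper leaf.
#' @return An object of class `defect_instance`.
#' @export
defect_instance <- function(category, size, visible_views, on_upper_leaf = FALSE) {
  if (!category %in% defect_categories()) stop("unknown category: ", category)
  if (!is.numeric(size) || size <= 0) stop("`size` must be > 0")
  visible_views <- as.integer(visible_views)
  if (!length(visible_views) || !all(visible_views %in% side_view_angles()) ||
      anyDuplicated(visible_views))
    stop("`visible_views` must be a nonempty subset of the side-view angles")
  if (!is_contiguous_arc(visible_views))
    stop("`visible_views` must be contiguous on the 8-view circle")
  structure(list(category = category, size = size,
                 visible_views = sort(visible_views),
                 on_upper_leaf = isTRUE(on_upper_leaf)),
            class = "defect_instance")
}

is_contiguous_arc <- function(views) {
  if (length(views) >= 8L) return(length(views) == 8L)
  idx <- sort(match(views, side_view_angles())) - 1L
  n <- length(idx)
  # some rotation of the arc must be a run of consecutive positions mod 8
  any(vapply(idx, function(start) {
    all(((start + seq_len(n) - 1L) %% 8L) %in% idx)
  }, logical(1)))
}

contiguous_arc <- function(start_angle, span) {
  angles <- side_view_angles()
  start <- match(start_angle, angles) - 1L
  angles[((start + seq_len(span) - 1L) %% 8L) + 1L]
}

#' Ground-truth description of one synthetic seedling
#'
#' @param defects List of [defect_instance()]s.
#' @param roots_per_view 8 nonnegative integers, visible roots per side
#'   view in angle order.
#' @param top_leaf_damage,top_leaf_shrinkage Upper-leaf flags visible in
#'   the top view.
#' @param true_grade `"A"`, `"B"` or `"C"` (normally derived with
#'   [derive_true_grade()]).
#' @return An object of class `seedling_state`.
#' @export
seedling_state <- function(defects, roots_per_view, top_leaf_damage,
                           top_leaf_shrinkage, true_grade = NA_character_) {
  roots_per_view <- as.integer(roots_per_view)
  if (length(roots_per_view) != 8L || anyNA(roots_per_view) ||
      any(roots_per_view < 0))
    stop("`roots_per_view` must be 8 nonnegative integers")
  stopifnot(all(vapply(defects, inherits, logical(1), "defect_instance")))
  if (!is.na(true_grade) && !true_grade %in% c("A", "B", "C"))
    stop("`true_grade` must be A, B or C")
  structure(list(defects = defects, roots_per_view = roots_per_view,
                 top_leaf_damage = isTRUE(top_leaf_damage),
                 top_leaf_shrinkage = isTRUE(top_leaf_shrinkage),
                 true_grade = true_grade),
            class = "seedling_state")
}

#' Generate ground-truthed synthetic seedlings
#'
#' Draws `n` seedling states from a [generator_config()]. Each state is
#' fully labelled: defect instances with sizes and contiguous view arcs,
#' per-view root counts, top-view flags, and the ground-truth grade
#' derived from the scoring rules under the config's score weights and
#' thresholds. Reproducible: identical configs produce identical states.
#'
#' @param config A [generator_config()].
#' @param n Number of seedlings (>= 1).
#' @return List of `n` [seedling_state()] objects.
#' @export
generate_seedling_state <- function(config, n) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  set.seed(config$seed)
  lapply(seq_len(n), function(i) random_seedling(config))
}

random_seedling <- function(config) {
  prev <- config$category_prevalence
  n_def <- if (sum(prev) == 0) 0L else draw_from(config$defect_count_distribution)
  defects <- lapply(seq_len(n_def), function(j) {
    span <- draw_from(config$view_span_distribution)
    defect_instance(
      category = sample(defect_categories(), 1L, prob = prev),
      size = stats::rlnorm(1, config$size_distribution$meanlog,
                           config$size_distribution$sdlog),
      visible_views = contiguous_arc(sample(side_view_angles(), 1L), span),
      on_upper_leaf = stats::runif(1) < config$upper_leaf_prob)
  })
  roots <- draw_from(config$root_distribution, 8L)
  damage <- any(vapply(defects, function(d)
    d$category == "Leaf damage" && d$on_upper_leaf, logical(1)))
  shrink <- any(vapply(defects, function(d)
    d$category == "Leaf shrinkage", logical(1)))
  st <- seedling_state(defects, roots, damage, shrink)
  st$true_grade <- derive_true_grade(st, config$score, config$thresholds)
  st
}

#' Ground-truth grade of a synthetic seedling
#'
#' Applies the same rules the pipeline learns to reproduce: the
#' weighted defect score over the view-integrated true areas (instance
#' size times the number of views it is visible from, mirroring how
#' detected areas accumulate over the eight views), the rule-based root
#' grade from the per-view root counts, and the worse-of score/root
#' combination.
#'
#' @param state A [seedling_state()].
#' @param score_cfg A [score_config()].
#' @param thresholds A [grade_thresholds()].
#' @return `"A"`, `"B"` or `"C"`.
#' @export
derive_true_grade <- function(state, score_cfg = score_config(),
                              thresholds = grade_thresholds()) {
  stopifnot(inherits(state, "seedling_state"))
  S <- weighted_score(true_area_vector(state), score_cfg)
  G <- rule_grade(summarize_views(state$roots_per_view))
  rule_based_grade(S, as.integer(G), thresholds, policy = "worse_of")
}

#' True per-category defect counts and view-integrated areas
#'
#' `true_defect_counts()` counts instances per category (multi-view
#' duplication removed); `true_area_vector()` integrates each instance's
#' area over the views it is visible from, the quantity the detected-area
#' accumulation estimates.
#'
#' @param state A [seedling_state()].
#' @return Named numeric vector of length 7.
#' @export
true_defect_counts <- function(state) {
  cats <- vapply(state$defects, `[[`, character(1), "category")
  out <- table(factor(cats, levels = defect_categories()))
  stats::setNames(as.integer(out), defect_categories())
}

#' @rdname true_defect_counts
#' @export
true_area_vector <- function(state) {
  areas <- stats::setNames(numeric(7), defect_categories())
  for (d in state$defects)
    areas[d$category] <- areas[d$category] + d$size * length(d$visible_views)
  areas
}

defect_box <- function(d, index) {
  side <- min(sqrt(d$size), 0.4)
  frac <- ((index * 0.6180339887498949) %% 1)
  cx <- 0.15 + 0.7 * frac
  cy <- 0.15 + 0.7 * ((frac + 0.37) %% 1)
  cx <- min(max(cx, side / 2), 1 - side / 2)
  cy <- min(max(cy, side / 2), 1 - side / 2)
  data.frame(category = d$category, cx = cx, cy = cy, w = side, h = side,
             confidence = NA_real_)
}

root_box <- function(j, n) {
  data.frame(category = "Root", cx = 0.1 + 0.8 * j / (n + 1), cy = 0.82,
             w = 0.02, h = 0.15, confidence = NA_real_)
}

top_flag_box <- function(category) {
  cx <- if (category == "Leaf damage") 0.35 else 0.65
  data.frame(category = category, cx = cx, cy = 0.4, w = 0.12, h = 0.12,
             confidence = NA_real_)
}

#' Synthetic detector output for one image
#'
#' Stands in for the stage-1 detectors. With zero noise the output
#' contains exactly one detection per defect instance visible from the
#' requested view (role `"side_leaf"`), one per visible root
#' (`"side_root"`), or one box per raised upper-leaf flag (`"top"`). The
#' box area of a leaf-defect detection equals the instance's normalized
#' lesion area. With nonzero rates, true detections are dropped by
#' independent Bernoulli(miss rate) draws and Poisson(false-positive
#' rate) spurious boxes are added. Uses the ambient RNG stream; seed the
#' session (or use [simulate_detections()]) for reproducibility.
#'
#' @param state A [seedling_state()].
#' @param view Side-view angle or `"top"`.
#' @param config A [generator_config()] (noise rates).
#' @param role Detector role; defaults to `"top"` for the top view and
#'   `"side_leaf"` otherwise.
#' @return A [detection_set()].
#' @export
emit_detections <- function(state, view, config,
                            role = if (identical(view, "top")) "top" else "side_leaf") {
  stopifnot(inherits(state, "seedling_state"), inherits(config, "generator_config"))
  view <- validate_view(view)
  role <- match.arg(role, c("side_leaf", "side_root", "top"))
  if (identical(view, "top") != (role == "top"))
    stop("role '", role, "' is inconsistent with view ", as.character(view))
  scheme <- switch(role, side_leaf = side_leaf_scheme(),
                   side_root = side_root_scheme(), top = top_scheme())
  dims <- if (role == "top") c(640L, 480L) else c(3038L, 2548L)
  boxes <- switch(role,
    side_leaf = {
      vis <- which(vapply(state$defects, function(d) view %in% d$visible_views,
                          logical(1)))
      if (length(vis)) do.call(rbind, lapply(vis, function(i)
        defect_box(state$defects[[i]], i))) else NULL
    },
    side_root = {
      nroot <- state$roots_per_view[match(view, side_view_angles())]
      if (nroot > 0) do.call(rbind, lapply(seq_len(nroot), root_box, n = nroot)) else NULL
    },
    top = {
      flags <- c(if (state$top_leaf_damage) "Leaf damage",
                 if (state$top_leaf_shrinkage) "Leaf shrinkage")
      if (length(flags)) do.call(rbind, lapply(flags, top_flag_box)) else NULL
    })
  if (!is.null(boxes) && config$detector_miss_rate > 0) {
    keep <- stats::runif(nrow(boxes)) >= config$detector_miss_rate
    boxes <- boxes[keep, , drop = FALSE]
  }
  if (config$detector_false_positive_rate > 0) {
    n_fp <- stats::rpois(1, config$detector_false_positive_rate)
    if (n_fp > 0) {
      side <- stats::runif(n_fp, 0.01, 0.08)
      fp <- data.frame(category = sample(scheme$labels, n_fp, replace = TRUE),
                       cx = stats::runif(n_fp, 0.04, 0.96),
                       cy = stats::runif(n_fp, 0.04, 0.96),
                       w = side, h = side, confidence = NA_real_)
      fp$cx <- pmin(pmax(fp$cx, fp$w / 2), 1 - fp$w / 2)
      fp$cy <- pmin(pmax(fp$cy, fp$h / 2), 1 - fp$h / 2)
      boxes <- rbind(boxes, fp)
    }
  }
  id <- sprintf("synthetic_%s_%s", role, as.character(view))
  detection_set(id, view, boxes, dims, scheme)
}

#' All detector outputs for a batch of seedlings
#'
#' Convenience wrapper producing, for each state, the full detection
#' bundle the pipeline consumes: one top-view set, eight side-view leaf
#' sets and eight side-view root sets. Seeded once so results are
#' reproducible.
#'
#' @param states List of [seedling_state()]s.
#' @param config A [generator_config()].
#' @param seed Seed for the detector noise stream (defaults to the
#'   config's seed plus one so detection noise is decoupled from state
#'   generation).
#' @return List of bundles: each `list(top =, side_leaf =, side_root =)`.
#' @export
simulate_detections <- function(states, config, seed = config$seed + 1L) {
  set.seed(seed)
  lapply(states, function(st) {
    list(top = emit_detections(st, "top", config),
         side_leaf = lapply(side_view_angles(), function(v)
           emit_detections(st, v, config, role = "side_leaf")),
         side_root = lapply(side_view_angles(), function(v)
           emit_detections(st, v, config, role = "side_root")))
  })
}

# ---- procedural top-view rendering ----------------------------------------

TOP_W <- 640L
TOP_H <- 480L
COL_BG <- c(255, 255, 255)
COL_LOWER <- c(40, 110, 40)
COL_UPPER <- c(60, 150, 60)
COL_BLOB <- c(120, 80, 40)
DEPTH_BG <- 255
DEPTH_LOWER <- 180
DEPTH_UPPER <- 120

ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), w), h, w) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

paint <- function(canvas, mask, color) {
  for (ch in 1:3) {
    plane <- canvas[, , ch]
    plane[mask] <- color[ch]
    canvas[, , ch] <- plane
  }
  canvas
}

#' Procedurally render the top view of a seedling
#'
#' Draws a schematic 640 x 480 top view: four lower leaves as dark-green
#' ellipses on the diagonals and two upper leaves as lighter ellipses on
#' the horizontal axis, all radiating from the pot center on a white
#' background. The depth image encodes leaf layering (upper leaves
#' nearer, i.e. smaller depth values). Leaf shrinkage is rendered as
#' upper-leaf ellipses shorter than the lower ones; upper-leaf defect
#' instances appear as brown lesion blobs sized to their true area. The
#' rendering is schematic by design — the acceptance surface of this
#' package is pipeline logic, not detector training.
#'
#' @param state A [seedling_state()].
#' @return List with `rgb` (480 x 640 x 3 array, 0-255) and `depth`
#'   (480 x 640 matrix, 0-255; smaller is nearer).
#' @export
render_top_view <- function(state) {
  stopifnot(inherits(state, "seedling_state"))
  h <- TOP_H; w <- TOP_W
  cx0 <- w / 2; cy0 <- h / 2
  rgb <- array(COL_BG[1], dim = c(h, w, 3))
  depth <- matrix(DEPTH_BG, h, w)
  a_low <- 150; b_low <- 50
  a_up <- if (state$top_leaf_shrinkage) 90 else 150
  b_up <- 45
  for (ang in c(45, 135, 225, 315) * pi / 180) {
    m <- ellipse_mask(h, w, cx0 + a_low * cos(ang), cy0 + a_low * sin(ang),
                      a_low, b_low, ang)
    rgb <- paint(rgb, m, COL_LOWER)
    depth[m] <- DEPTH_LOWER
  }
  for (ang in c(0, 180) * pi / 180) {
    m <- ellipse_mask(h, w, cx0 + a_up * cos(ang), cy0 + a_up * sin(ang),
                      a_up, b_up, ang)
    rgb <- paint(rgb, m, COL_UPPER)
    depth[m] <- DEPTH_UPPER
  }
  upper <- which(vapply(state$defects, `[[`, logical(1), "on_upper_leaf"))
  for (k in seq_along(upper)) {
    d <- state$defects[[upper[k]]]
    r <- sqrt(d$size * w * h / pi)
    dist <- 40 + (k * 37) %% 100
    side <- if (k %% 2 == 0) 1 else -1
    m <- ellipse_mask(h, w, cx0 + side * dist, cy0 + ((k * 13) %% 21) - 10,
                      r, r, 0)
    rgb <- paint(rgb, m, COL_BLOB)
    depth[m] <- DEPTH_UPPER
  }
  list(rgb = rgb, depth = depth)
}
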