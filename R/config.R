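#' Pipeline configuration
#'
#' Bundles everything the grading pipeline needs beyond its inputs: the
#' expert defect weights, the calibrated score thresholds, the side
#' views in use, the score/root conflict policy, the area unit
#' convention, the root rule standard, the detector confidence floor and
#' the master seed. Every run can log [config_fingerprint()] of the
#' resolved configuration for reproducibility.
#'
#' @param score A [score_config()].
#' @param thresholds A [grade_thresholds()].
#' @param views Included side-view angles (subset of
#'   [side_view_angles()]).
#' @param policy Grade combination policy, see [rule_based_grade()].
#' @param area_units `"normalized"` or `"pixel"` for defect areas.
#' @param root_rules Root rule set, see [default_root_rules()].
#' @param confidence_threshold Detector confidence floor for adapters.
#' @param seed Master seed; per-module seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(score = score_config(),
                            thresholds = grade_thresholds(),
                            views = side_view_angles(),
                            policy = "worse_of",
                            area_units = "normalized",
                            root_rules = default_root_rules(),
                            confidence_threshold = 0.25,
                            seed = 42L) {
  stopifnot(inherits(score, "score_config"),
            inherits(thresholds, "grade_thresholds"))
  views <- as.integer(views)
  if (!length(views) || !all(views %in% side_view_angles()) ||
      anyDuplicated(views))
    stop("`views` must be a nonempty duplicate-free subset of the side-view angles")
  policy <- match.arg(policy, c("worse_of", "score_priority", "root_priority"))
  area_units <- match.arg(area_units, c("normalized", "pixel"))
  if (confidence_threshold < 0 || confidence_threshold > 1)
    stop("`confidence_threshold` must lie in [0, 1]")
  structure(list(score = score, thresholds = thresholds, views = sort(views),
                 policy = policy, area_units = area_units,
                 root_rules = root_rules,
                 confidence_threshold = confidence_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `weights`, `t_a`, `t_c`, `views`, `policy`,
#' `area_units`, `root_rules_file`, `confidence_threshold`, `seed`.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("weights", "t_a", "t_c", "views", "policy", "area_units",
             "root_rules_file", "confidence_threshold", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults <- pipeline_config()
  pipeline_config(
    score = if (!is.null(raw$weights)) score_config(unlist(raw$weights))
            else defaults$score,
    thresholds = grade_thresholds(raw$t_a %||% defaults$thresholds$t_a,
                                  raw$t_c %||% defaults$thresholds$t_c),
    views = unlist(raw$views) %||% defaults$views,
    policy = raw$policy %||% defaults$policy,
    area_units = raw$area_units %||% defaults$area_units,
    root_rules = if (!is.null(raw$root_rules_file))
      root_rules_from_yaml(raw$root_rules_file) else defaults$root_rules,
    confidence_threshold = raw$confidence_threshold %||%
      defaults$confidence_threshold,
    seed = raw$seed %||% defaults$seed)
}

#' Fingerprint of a resolved configuration
#'
#' Stable 32-bit polynomial hash of the deparsed configuration, printed
#' as 8 hex digits. Logged by the command-line tools so every result can
#' be tied to the exact configuration that produced it.
#'
#' @param cfg Any R object (normally a [pipeline_config()]).
#' @return Character scalar, e.g. `"a1b2c3d4"`.
#' @export
config_fingerprint <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296  # exact: h * 33 < 2^53
  sprintf("%08x", as.integer(h %% 2147483648) )
}

#' Derive a per-module seed from the master seed
#'
#' Deterministic fan-out keeping derived seeds within the 32-bit integer
#' range.
#'
#' @param seed Master seed.
#' @param offset Module offset.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}

#' Write a synthetic dataset to disk
#'
#' Materialises `n` generated seedlings: the rendered top-view RGB (PNG)
#' and depth (16-bit TIFF) images, YOLO-txt detection files for the top
#' view and for each side view (leaf and root schemes), a ground-truth
#' JSON sidecar per seedling, and a manifest recording the seed and all
#' files. Side views are emitted as detection annotations (the pipeline
#' consumes detections; only the top view has a procedural renderer).
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory; must be empty unless `force`.
#' @param n Number of seedlings (>= 1).
#' @param force Overwrite into a non-empty directory.
#' @param write_images Render and write top-view images (disable for
#'   detection-only datasets).
#' @return The manifest list, invisibly.
#' @export
simulate_dataset <- function(config, out_dir, n, force = FALSE,
                             write_images = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- generate_seedling_state(config, n)
  bundles <- simulate_detections(states, config)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("seedling_%04d", i)
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    files <- list()
    if (write_images) {
      render <- render_top_view(states[[i]])
      write_image(render$rgb, file.path(sdir, "top_rgb.png"))
      write_depth(render$depth, file.path(sdir, "top_depth.tif"), max_value = 255)
      files$top_image <- file.path(id, "top_rgb.png")
      files$top_depth <- file.path(id, "top_depth.tif")
    }
    write_yolo_annotations(bundles[[i]]$top, file.path(sdir, "top.txt"))
    files$top_detections <- file.path(id, "top.txt")
    files$side_views <- lapply(seq_along(side_view_angles()), function(k) {
      v <- side_view_angles()[k]
      leaf <- sprintf("side_%03d_leaf.txt", v)
      root <- sprintf("side_%03d_root.txt", v)
      write_yolo_annotations(bundles[[i]]$side_leaf[[k]], file.path(sdir, leaf))
      write_yolo_annotations(bundles[[i]]$side_root[[k]], file.path(sdir, root))
      list(angle = v, leaf = file.path(id, leaf), root = file.path(id, root))
    })
    jsonlite::write_json(state_to_json(states[[i]]),
                         file.path(sdir, "state.json"),
                         auto_unbox = TRUE, digits = NA)
    files$ground_truth <- file.path(id, "state.json")
    entries[[i]] <- c(list(id = id), files)
  }
  manifest <- list(package = "orchidgrader", seed = config$seed, n = n,
                   config_fingerprint = config_fingerprint(config),
                   seedlings = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

state_to_json <- function(st) {
  list(defects = lapply(st$defects, function(d)
    list(category = d$category, size = d$size,
         visible_views = d$visible_views, on_upper_leaf = d$on_upper_leaf)),
    roots_per_view = st$roots_per_view,
    top_leaf_damage = st$top_leaf_damage,
    top_leaf_shrinkage = st$top_leaf_shrinkage,
    true_grade = st$true_grade)
}

#' Read a simulated dataset back from disk
#'
#' Restores the ground-truth states and detection bundles written by
#' [simulate_dataset()].
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return List with `states`, `bundles`, `manifest`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  dims_side <- c(3038L, 2548L)
  states <- list(); bundles <- list()
  for (e in manifest$seedlings) {
    raw <- jsonlite::read_json(file.path(dir, e$ground_truth))
    defects <- lapply(raw$defects, function(d)
      defect_instance(d$category, d$size, unlist(d$visible_views),
                      isTRUE(d$on_upper_leaf)))
    st <- seedling_state(defects, unlist(raw$roots_per_view),
                         isTRUE(raw$top_leaf_damage),
                         isTRUE(raw$top_leaf_shrinkage), raw$true_grade)
    top <- read_yolo_annotations(file.path(dir, e$top_detections),
                                 top_scheme(), c(640L, 480L),
                                 image_id = e$id, view = "top")
    side_leaf <- lapply(e$side_views, function(sv)
      read_yolo_annotations(file.path(dir, sv$leaf), side_leaf_scheme(),
                            dims_side, image_id = e$id, view = sv$angle))
    side_root <- lapply(e$side_views, function(sv)
      read_yolo_annotations(file.path(dir, sv$root), side_root_scheme(),
                            dims_side, image_id = e$id, view = sv$angle))
    states[[e$id]] <- st
    bundles[[e$id]] <- list(top = top, side_leaf = side_leaf,
                            side_root = side_root)
  }
  list(states = unname(states), bundles = unname(bundles),
       manifest = manifest)
}
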