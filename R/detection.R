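#' Defect categories recognised on side-view leaf imagery
#'
#' The seven leaf-surface defect categories used throughout the grading
#' pipeline, in the fixed index order assumed by annotation files
#' (class index 0 = Disease, ..., 6 = Lower-leaf yellowing). An optional
#' eighth "Flawless" class may appear in detector output but never
#' contributes to defect features.
#'
#' @return Character vector of the 7 category labels, in index order.
#' @export
defect_categories <- function() {
  c("Disease", "Pest damage", "Pesticide damage", "Leaf damage",
    "Leaf shrinkage", "Variation", "Lower-leaf yellowing")
}

#' Side-view angles of the turntable imaging rig
#'
#' @return Integer vector `c(0, 45, ..., 315)`, the eight side-view angles
#'   in degrees, clockwise from the orientation of greatest upper-leaf
#'   spread.
#' @export
side_view_angles <- function() {
  seq(0L, 315L, by = 45L)
}

#' Category schemes for the three detector roles
#'
#' A category scheme names the ordered label set a detector emits. Three
#' schemes are used: `side_leaf` (the 7 defect categories, optionally with
#' a trailing "Flawless" class that is excluded from all defect features),
#' `side_root` (a single "Root" label; the per-view root quantity is the
#' number of root detections), and `top` (presence of "Leaf damage" and
#' "Leaf shrinkage" on the upper leaves).
#'
#' @param name Scheme name.
#' @param labels Ordered character vector; class index `i` in annotation
#'   files maps to `labels[i + 1]`.
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(name, labels) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(labels), length(labels) >= 1L,
            !anyDuplicated(labels))
  structure(list(name = name, labels = labels), class = "category_scheme")
}

#' @rdname category_scheme
#' @param include_flawless Append the "Flawless" class (detector output
#'   only; never counted as a defect).
#' @export
side_leaf_scheme <- function(include_flawless = FALSE) {
  labels <- defect_categories()
  if (include_flawless) labels <- c(labels, "Flawless")
  category_scheme("side_leaf", labels)
}

#' @rdname category_scheme
#' @export
side_root_scheme <- function() {
  category_scheme("side_root", "Root")
}

#' @rdname category_scheme
#' @export
top_scheme <- function() {
  category_scheme("top", c("Leaf damage", "Leaf shrinkage"))
}

#' Detections for one image
#'
#' Container for all detector output on a single image: normalized
#' center-format boxes with category labels and optional confidences.
#'
#' @param image_id Identifier of the source image.
#' @param view Side-view angle in degrees (one of [side_view_angles()]) or
#'   `"top"`.
#' @param detections `data.frame` with columns `category` (character, a
#'   label of `scheme`), `cx`, `cy`, `w`, `h` (normalized, box inside the
#'   unit square) and optionally `confidence` in \[0, 1\] (`NA` allowed).
#'   May have zero rows.
#' @param image_dims `c(width, height)` of the image in pixels.
#' @param scheme A [category_scheme()].
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(image_id, view, detections, image_dims, scheme) {
  view <- validate_view(view)
  stopifnot(inherits(scheme, "category_scheme"),
            is.numeric(image_dims), length(image_dims) == 2L,
            all(image_dims > 0))
  detections <- validate_detections(detections, scheme)
  structure(
    list(image_id = as.character(image_id), view = view,
         detections = detections, image_dims = as.integer(image_dims),
         scheme = scheme),
    class = "detection_set")
}

validate_view <- function(view) {
  if (identical(view, "top")) return("top")
  view <- as.integer(view)
  if (length(view) != 1L || !view %in% side_view_angles())
    stop("`view` must be \"top\" or one of ", paste(side_view_angles(), collapse = ", "))
  view
}

validate_detections <- function(detections, scheme) {
  cols <- c("category", "cx", "cy", "w", "h")
  if (is.null(detections) || nrow(as.data.frame(detections)) == 0L) {
    return(data.frame(category = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric()))
  }
  detections <- as.data.frame(detections)
  missing <- setdiff(cols, names(detections))
  if (length(missing))
    stop("detections lack columns: ", paste(missing, collapse = ", "))
  if (!"confidence" %in% names(detections)) detections$confidence <- NA_real_
  detections <- detections[c(cols, "confidence")]
  bad <- !detections$category %in% scheme$labels
  if (any(bad))
    stop("unknown categories for scheme '", scheme$name, "': ",
         paste(unique(detections$category[bad]), collapse = ", "))
  with(detections, {
    # tolerance matches the 6-decimal annotation serialization precision
    eps <- 1e-6
    if (any(w <= 0 | h <= 0)) stop("detection boxes must have positive size")
    if (any(cx - w / 2 < -eps | cx + w / 2 > 1 + eps |
            cy - h / 2 < -eps | cy + h / 2 > 1 + eps))
      stop("detection boxes must lie inside the unit square")
  })
  rownames(detections) <- NULL
  detections
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> image '%s', view %s, scheme '%s': %d detection(s)\n",
              x$image_id, as.character(x$view), x$scheme$name, nrow(x$detections)))
  invisible(x)
}

#' Read YOLO-style annotations
#'
#' Parses a whitespace-separated annotation file with one detection per
#' line: `class cx cy w h [confidence]`, all box fields normalized to
#' \[0, 1\] and `class` a 0-based index into the scheme labels. Malformed
#' lines are rejected with their line numbers.
#'
#' @param path Annotation file. An empty (or absent-content) file yields an
#'   empty [detection_set()].
#' @param scheme [category_scheme()] defining the class index order.
#' @param image_dims `c(width, height)` in pixels.
#' @param image_id,view Metadata for the resulting set.
#' @return A [detection_set()].
#' @export
read_yolo_annotations <- function(path, scheme, image_dims,
                                  image_id = basename(path), view = "top") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(detection_set(image_id, view, NULL, image_dims, scheme))
  parsed <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (!length(tok) %in% c(5L, 6L))
      stop("line ", i, ": expected 5 or 6 fields, got ", length(tok))
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num)) stop("line ", i, ": non-numeric field")
    idx <- num[1]
    if (idx != round(idx) || idx < 0 || idx >= length(scheme$labels))
      stop("line ", i, ": class index ", idx, " unknown in scheme '",
           scheme$name, "' (", length(scheme$labels), " classes)")
    if (any(num[2:5] < 0 | num[2:5] > 1))
      stop("line ", i, ": box fields outside [0, 1]")
    data.frame(category = scheme$labels[idx + 1L],
               cx = num[2], cy = num[3], w = num[4], h = num[5],
               confidence = if (length(tok) == 6L) num[6] else NA_real_)
  })
  detection_set(image_id, view, do.call(rbind, parsed), image_dims, scheme)
}

#' Write YOLO-style annotations
#'
#' One line per detection, `class cx cy w h [confidence]` at 6 decimal
#' places, ordered by (class index, cx, cy). The confidence column is
#' written only when every detection carries one; sets with all-missing
#' confidences produce 5-column files, and mixed sets are rejected.
#'
#' @param dset A [detection_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_yolo_annotations <- function(dset, path) {
  stopifnot(inherits(dset, "detection_set"))
  d <- dset$detections
  if (nrow(d) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  n_na <- sum(is.na(d$confidence))
  if (n_na > 0L && n_na < nrow(d))
    stop("mixed present/absent confidences cannot be serialized")
  idx <- match(d$category, dset$scheme$labels) - 1L
  d <- d[order(idx, d$cx, d$cy), ]
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   match(d$category, dset$scheme$labels) - 1L,
                   d$cx, d$cy, d$w, d$h)
  if (n_na == 0L) lines <- paste(lines, sprintf("%.6f", d$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' Count detections per category
#'
#' Tallies detections by category in the documented label order. For the
#' side-view leaf scheme the "Flawless" class (when present) is excluded,
#' so the result is always the 7-dimensional defect count vector.
#'
#' @param dset A [detection_set()].
#' @param scheme Scheme defining the counting order; must match the set's.
#' @return Named integer vector, one entry per countable label.
#' @export
count_by_category <- function(dset, scheme = dset$scheme) {
  stopifnot(inherits(dset, "detection_set"), inherits(scheme, "category_scheme"))
  if (!identical(scheme$name, dset$scheme$name))
    stop("scheme mismatch: set has '", dset$scheme$name, "', asked for '",
         scheme$name, "'")
  labels <- setdiff(scheme$labels, "Flawless")
  cat_ <- dset$detections$category
  out <- table(factor(cat_[cat_ != "Flawless"], levels = labels))
  stats::setNames(as.integer(out), labels)
}

#' Detection box areas
#'
#' Box area per detection, either normalized (`w * h`, fraction of image
#' area) or in pixels squared (`w * h * width * height`). How Eq.-style
#' defect areas are measured from boxes is a declared convention; the
#' pipeline default is normalized units.
#'
#' @param dset A [detection_set()].
#' @param units `"normalized"` or `"pixel"`.
#' @return Numeric vector of areas (length `nrow(dset$detections)`).
#' @export
detection_areas <- function(dset, units = c("normalized", "pixel")) {
  units <- match.arg(units)
  a <- dset$detections$w * dset$detections$h
  if (units == "pixel") a <- a * prod(as.numeric(dset$image_dims))
  a
}

#' Detector contract
#'
#' A detector is any object pairing a [category_scheme()] with a predict
#' function mapping an input (an image array, or any backend-specific
#' descriptor such as the synthetic generator's `(state, view)` pair) to a
#' [detection_set()]. Real YOLO models plug in behind this contract; the
#' shipped implementations are the synthetic oracle ([oracle_detector()])
#' and a YOLO-txt file adapter ([yolo_txt_detector()]).
#'
#' @param scheme The [category_scheme()] the detector emits.
#' @param predict_fn `function(input) -> detection_set`.
#' @param name Human-readable backend name.
#' @return An object of class `sg_detector`.
#' @export
detector <- function(scheme, predict_fn, name = "custom") {
  stopifnot(inherits(scheme, "category_scheme"), is.function(predict_fn))
  structure(list(scheme = scheme, predict = predict_fn, name = name),
            class = "sg_detector")
}

#' Run a detector on one input
#'
#' @param input Backend-specific input (image array, file id, or
#'   `(state, view)` descriptor).
#' @param model An [detector()] object.
#' @param expected_scheme Optional scheme the calling pipeline stage
#'   requires; a mismatch with the model's scheme is an error.
#' @return A [detection_set()].
#' @export
detect <- function(input, model, expected_scheme = NULL) {
  stopifnot(inherits(model, "sg_detector"))
  if (!is.null(expected_scheme) &&
      !identical(expected_scheme$name, model$scheme$name))
    stop("detector emits scheme '", model$scheme$name,
         "' but this stage requires '", expected_scheme$name, "'")
  out <- model$predict(input)
  if (!inherits(out, "detection_set"))
    stop("detector '", model$name, "' did not return a detection_set")
  out
}

#' Synthetic-oracle detector
#'
#' Detector backed by the synthetic generator: its input is a list
#' `list(state = <seedling_state>, view = <angle or "top">)` and its output
#' is [emit_detections()] for the matching scheme. With a zero-noise
#' [generator_config()] it reproduces ground truth exactly.
#'
#' @param config A [generator_config()] providing the noise rates.
#' @param role One of `"side_leaf"`, `"side_root"`, `"top"`.
#' @return An [detector()].
#' @export
oracle_detector <- function(config, role = c("side_leaf", "side_root", "top")) {
  role <- match.arg(role)
  scheme <- switch(role, side_leaf = side_leaf_scheme(),
                   side_root = side_root_scheme(), top = top_scheme())
  detector(scheme, function(input) {
    emit_detections(input$state, input$view, config, role = role)
  }, name = paste0("oracle-", role))
}

#' YOLO-txt file adapter detector
#'
#' Adapter satisfying the detector contract by reading pre-computed
#' YOLO-style annotation files (e.g. exported by an external YOLO model).
#' Input is a list `list(path = <file>, view = <angle or "top">,
#' image_id = <id>)`.
#'
#' @param scheme The [category_scheme()] the files were written under.
#' @param image_dims `c(width, height)` of the source images.
#' @param confidence_threshold Detections below this confidence are
#'   dropped; detections without confidence are kept.
#' @return An [detector()].
#' @export
yolo_txt_detector <- function(scheme, image_dims, confidence_threshold = 0.25) {
  detector(scheme, function(input) {
    dset <- read_yolo_annotations(input$path, scheme, image_dims,
                                  image_id = input$image_id %||% basename(input$path),
                                  view = input$view %||% "top")
    keep <- is.na(dset$detections$confidence) |
      dset$detections$confidence >= confidence_threshold
    detection_set(dset$image_id, dset$view, dset$detections[keep, ],
                  dset$image_dims, scheme)
  }, name = "yolo-txt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
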