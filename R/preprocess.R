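#' Image conventions
#'
#' Images are plain numeric arrays in the 0-255 range: `[row, col]` for
#' single-channel (gray/depth/mask) and `[row, col, channel]` for RGB or
#' RGB-D. Coordinates are 0-based `(x = column, y = row)` in all stated
#' pixel conventions; crop intervals are half-open.
#'
#' @name image-conventions
NULL

assert_rgb <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a 3-channel [row, col, 3] image")
  invisible(img)
}

assert_single_channel <- function(img) {
  if (length(dim(img)) != 2L)
    stop("expected a single-channel [row, col] image")
  invisible(img)
}

#' Register a depth image to its RGB image by pixel offset
#'
#' The RGB and depth sensors are physically separate, so the depth image
#' is translated by a per-rig calibration offset `(dx, dy)` before
#' fusion. Exposed borders are filled with 0 (no depth). The calibration
#' values are rig-specific config inputs; the default offset is `(0, 0)`.
#'
#' @param depth Single-channel matrix.
#' @param dx,dy Signed pixel shifts (positive moves content right/down);
#'   must be smaller than the image size.
#' @param fill Border fill value.
#' @return Shifted matrix of identical dimensions.
#' @export
align_depth <- function(depth, dx = 0L, dy = 0L, fill = 0) {
  assert_single_channel(depth)
  h <- nrow(depth); w <- ncol(depth)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= w || abs(dy) >= h)
    stop("offset (", dx, ", ", dy, ") exceeds image size ", w, " x ", h)
  out <- matrix(fill, h, w)
  src_rows <- seq_len(h) - dy
  src_cols <- seq_len(w) - dx
  ok_r <- src_rows >= 1L & src_rows <= h
  ok_c <- src_cols >= 1L & src_cols <= w
  out[which(ok_r), which(ok_c)] <- depth[src_rows[ok_r], src_cols[ok_c]]
  out
}

# OpenCV-style automatic sigma for a given odd Gaussian kernel size
auto_sigma <- function(ksize) 0.3 * ((ksize - 1) / 2 - 1) + 0.8

#' Extract the plant mask from a top-view RGB image
#'
#' The top-view masking chain: grayscale, Gaussian blur, Otsu
#' binarization (plant darker than the white background), retention of
#' the largest connected foreground component, morphological closing and
#' hole filling to refine the outline. A blank image (no foreground)
#' yields an empty mask with a warning rather than an error.
#'
#' @param rgb 3-channel image array.
#' @param blur_kernel Odd Gaussian kernel size in pixels (sigma derived
#'   automatically).
#' @param close_kernel Odd diameter of the elliptical closing element.
#' @return Binary integer matrix (1 = plant).
#' @export
plant_mask <- function(rgb, blur_kernel = 5L, close_kernel = 7L) {
  assert_rgb(rgb)
  gray <- (0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]) / 255
  g <- EBImage::gblur(t(gray), sigma = auto_sigma(blur_kernel))
  g <- pmin(pmax(g, 0), 1)
  th <- EBImage::otsu(g, range = c(0, 1))
  fg <- g < th
  if (!any(fg)) {
    warning("no foreground contour found; returning empty mask")
    return(matrix(0L, nrow(gray), ncol(gray)))
  }
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  m <- lab == which.max(areas)
  m <- EBImage::closing(m, EBImage::makeBrush(as.integer(close_kernel), "disc"))
  m <- EBImage::fillHull(m)
  mat <- t(matrix(as.integer(m > 0), nrow = nrow(m)))
  storage.mode(mat) <- "integer"
  mat
}

#' Overlay a mask on an image
#'
#' Sets pixels outside the mask to the background value, producing the
#' masked-object image of the preprocessing chain.
#'
#' @param img Image array (any channel count).
#' @param mask Binary matrix from [plant_mask()].
#' @param background Fill value for out-of-mask pixels.
#' @return Masked image, same dimensions.
#' @export
apply_mask <- function(img, mask, background = 255) {
  if (length(dim(img)) == 2L) {
    img[mask == 0] <- background
    return(img)
  }
  for (ch in seq_len(dim(img)[3])) {
    plane <- img[, , ch]
    plane[mask == 0] <- background
    img[, , ch] <- plane
  }
  img
}

#' Mask and denoise a depth image
#'
#' Depth cleanup before fusion: out-of-mask pixels are zeroed, in-mask
#' values outside the given percentile band are clipped (the
#' extreme-value removal step), and the result is min-max rescaled to
#' 0-255. A constant in-mask depth rescales to 0 by convention; an empty
#' mask yields an all-zero image with a warning. Percentiles use R's
#' default (type-7) quantile definition.
#'
#' @param depth Single-channel matrix.
#' @param mask Binary matrix of identical dimensions.
#' @param low_pct,high_pct Clipping percentiles (0-100).
#' @return Integer matrix in 0-255, zero outside the mask.
#' @export
clean_depth <- function(depth, mask, low_pct = 1, high_pct = 99) {
  assert_single_channel(depth)
  if (!all(dim(depth) == dim(mask))) stop("depth and mask dimensions differ")
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  out <- matrix(0L, nrow(depth), ncol(depth))
  inside <- mask != 0
  if (!any(inside)) {
    warning("empty mask; returning all-zero depth")
    return(out)
  }
  v <- depth[inside]
  q <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE)
  v <- pmin(pmax(v, q[1]), q[2])
  rng <- q[2] - q[1]
  scaled <- if (rng <= 0) rep(0, length(v)) else (v - q[1]) / rng * 255
  out[inside] <- as.integer(round(scaled))
  out
}

#' Fuse RGB and cleaned depth into a four-channel RGB-D image
#'
#' @param rgb 3-channel array.
#' @param depth_clean Single-channel matrix of identical width/height.
#' @return `[row, col, 4]` array with channel order R, G, B, D.
#' @export
fuse_rgbd <- function(rgb, depth_clean) {
  assert_rgb(rgb)
  assert_single_channel(depth_clean)
  if (!all(dim(rgb)[1:2] == dim(depth_clean)))
    stop("dimension mismatch: rgb is ", paste(dim(rgb)[1:2], collapse = " x "),
         ", depth is ", paste(dim(depth_clean), collapse = " x "))
  array(c(rgb, depth_clean), dim = c(dim(rgb)[1:2], 4L))
}

#' @rdname fuse_rgbd
#' @param rgbd 4-channel array.
#' @return For `split_rgbd()`, a list with `rgb` and `depth`.
#' @export
split_rgbd <- function(rgbd) {
  if (length(dim(rgbd)) != 3L || dim(rgbd)[3] != 4L)
    stop("expected a 4-channel RGB-D array")
  list(rgb = rgbd[, , 1:3, drop = FALSE], depth = rgbd[, , 4])
}

#' Fixed-offset crop specification for side-view images
#'
#' Pixel counts to remove from each edge. The default spec — 600 px from
#' the left, 650 from the right, 300 from the top — reduces the rig's
#' 4288 x 2848 side views to 3038 x 2548 while keeping the whole leaf
#' and root region, exploiting the fixed camera/turntable geometry.
#'
#' @param left,right,top,bottom Nonnegative pixel offsets to remove.
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(left = 600L, right = 650L, top = 300L, bottom = 0L) {
  v <- as.integer(c(left, right, top, bottom))
  if (anyNA(v) || any(v < 0)) stop("crop offsets must be nonnegative")
  structure(list(left = v[1], right = v[2], top = v[3], bottom = v[4]),
            class = "crop_spec")
}

#' Crop a side-view image by fixed offsets
#'
#' Pure cropping (no resampling). Cropped pixel (0, 0) is original pixel
#' `(left, top)` under the 0-based `(x = col, y = row)` convention.
#'
#' @param img Image array.
#' @param spec A [crop_spec()]; the default implements the rig's
#'   standard side-view crop.
#' @return Cropped image.
#' @export
crop_side_view <- function(img, spec = crop_spec()) {
  stopifnot(inherits(spec, "crop_spec"))
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (spec$left + spec$right >= w || spec$top + spec$bottom >= h)
    stop("crop spec (", spec$left, ",", spec$right, ",", spec$top, ",",
         spec$bottom, ") leaves no pixels of a ", w, " x ", h, " image")
  rows <- (spec$top + 1L):(h - spec$bottom)
  cols <- (spec$left + 1L):(w - spec$right)
  if (length(d) == 2L) img[rows, cols] else img[rows, cols, , drop = FALSE]
}

#' Resize an image to the detector input resolution
#'
#' Bilinear resize to 640 x 640, the standard YOLO input size; channel
#' count is preserved.
#'
#' @param img Image array (any channel count).
#' @param size Output side length in pixels.
#' @return Resized image.
#' @export
resize_for_detector <- function(img, size = 640L) {
  size <- as.integer(size)
  if (length(dim(img)) == 2L) {
    return(t(EBImage::resize(t(img), w = size, h = size, filter = "bilinear")))
  }
  n_ch <- dim(img)[3]
  out <- array(0, dim = c(size, size, n_ch))
  for (ch in seq_len(n_ch))
    out[, , ch] <- t(EBImage::resize(t(img[, , ch]), w = size, h = size,
                                     filter = "bilinear"))
  out
}

#' Linear brightness perturbation
#'
#' The illumination robustness model `B_alpha(x, y) = alpha * I(x, y)`:
#' every pixel is scaled by the brightness coefficient, rounded, and
#' clipped to the 8-bit range (the linear model alone would leave the
#' image invalid for alpha > 1). `alpha = 1` returns the image
#' unchanged.
#'
#' @param img Image array, 0-255.
#' @param alpha Positive scaling coefficient.
#' @return Perturbed image of identical shape.
#' @export
adjust_brightness <- function(img, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a positive scalar")
  if (alpha == 1) return(img)
  out <- round(img * alpha)
  out[out > 255] <- 255
  out[out < 0] <- 0
  out
}

# ---- image file I/O -------------------------------------------------------

#' Read and write images
#'
#' PNG for 8-bit RGB/gray images and TIFF for 16-bit depth images.
#' `write_image()` expects 0-255 values; `write_depth()` stores values
#' scaled by `max_value` into a 16-bit TIFF so integer depths round-trip
#' exactly.
#'
#' @param img Image array, 0-255.
#' @param path File path; extension selects the codec (.png or
#'   .tif/.tiff).
#' @return The written path (writers, invisibly) or an image array
#'   (readers).
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  img * 255
}

#' @rdname write_image
#' @param depth Single-channel depth matrix.
#' @param max_value Full-scale depth value mapped to the 16-bit maximum.
#' @export
write_depth <- function(depth, path, max_value = 65535) {
  assert_single_channel(depth)
  tiff::writeTIFF(depth / max_value, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image
#' @export
read_depth <- function(path, max_value = 65535) {
  tiff::readTIFF(path) * max_value
}
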