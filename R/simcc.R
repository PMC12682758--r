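#' Encode a sub-pixel coordinate as a SimCC classification vector
#'
#' SimCC turns coordinate regression into classification over sub-pixel
#' bins: an axis of `extent` pixels is split into
#' `round(extent * ratio)` bins (`ratio` bins per pixel) and the target is
#' a Gaussian bump of width `sigma_bins` centered at `coord * ratio`,
#' truncated at the borders and renormalized to sum 1. Bin `b` represents
#' the coordinate `b / ratio`.
#'
#' @param coord coordinate in pixels, `0 <= coord < extent`.
#' @param extent axis length in pixels.
#' @param ratio splitting ratio (bins per pixel, default 2).
#' @param sigma_bins Gaussian width in bins (default 6).
#' @return numeric weight vector summing to 1.
#' @export
simcc_encode <- function(coord, extent, ratio = 2, sigma_bins = 6) {
  if (coord < 0 || coord >= extent) {
    stop("coord ", coord, " outside [0, ", extent, ")")
  }
  n <- round(extent * ratio)
  b <- seq_len(n) - 1
  w <- exp(-(b - coord * ratio)^2 / (2 * sigma_bins^2))
  w / sum(w)
}

#' Decode a SimCC vector to a sub-pixel coordinate
#'
#' By default the normalized expectation of bin centers (`sum(b * w) /
#' sum(w) / ratio`), which preserves sub-pixel information; `"argmax"`
#' returns the peak bin's coordinate.
#'
#' @param vector non-negative weights with positive sum.
#' @param ratio splitting ratio used at encoding.
#' @param method `"expectation"` (default) or `"argmax"`.
#' @return coordinate in pixels.
#' @export
simcc_decode <- function(vector, ratio = 2,
                         method = c("expectation", "argmax")) {
  method <- match.arg(method)
  if (any(vector < 0)) stop("weights must be non-negative")
  s <- sum(vector)
  if (s <= 0) stop("all-zero weight vector cannot be decoded")
  b <- seq_along(vector) - 1
  if (method == "argmax") return(b[which.max(vector)] / ratio)
  sum(b * vector) / s / ratio
}

#' Kullback-Leibler divergence between two SimCC label vectors
#'
#' `sum(target * log(target / pred))` after flooring both distributions at
#' `epsilon` and renormalizing; non-negative and zero iff the inputs are
#' equal — the training objective associated with SimCC heads.
#'
#' @param pred,target equal-length non-negative weight vectors.
#' @param epsilon smoothing floor (default 1e-12).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(pred, target, epsilon = 1e-12) {
  if (length(pred) != length(target)) stop("vector lengths differ")
  p <- pmax(pred, epsilon); p <- p / sum(p)
  t <- pmax(target, epsilon); t <- t / sum(t)
  sum(t * log(t / p))
}

#' Axis-aligned bounding box
#'
#' Half-open pixel box `[x_min, x_max) x [y_min, y_max)`.
#'
#' @param x_min,y_min,x_max,y_max box edges in pixels; max must exceed min.
#' @return list of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  if (x_max <= x_min || y_max <= y_min) stop("degenerate bounding box")
  structure(list(x_min = x_min, y_min = y_min,
                 x_max = x_max, y_max = y_max),
            class = "bounding_box")
}

#' Affine transform from a bounding box to a model input window
#'
#' Expands the box about its center by `padding`, grows the shorter side
#' to the output aspect ratio, and maps it to a `out_size = c(w, h)` window
#' with a uniform scale — the standard top-down crop. Both directions of
#' the affine are exposed; `inverse o forward` is the identity.
#'
#' @param bbox a [bounding_box()].
#' @param padding box expansion factor (default 1.25).
#' @param out_size `c(width, height)` of the model input in pixels
#'   (default 192 x 256).
#' @return list of class `roi_transform` with 3 x 3 `forward` and
#'   `inverse` matrices, `out_size`, `padding`.
#' @export
roi_transform <- function(bbox, padding = 1.25, out_size = c(192, 256)) {
  stopifnot(inherits(bbox, "bounding_box"), padding >= 1,
            length(out_size) == 2, all(out_size >= 1))
  cx <- (bbox$x_min + bbox$x_max) / 2
  cy <- (bbox$y_min + bbox$y_max) / 2
  bw <- (bbox$x_max - bbox$x_min) * padding
  bh <- (bbox$y_max - bbox$y_min) * padding
  aspect <- out_size[1] / out_size[2]
  if (bw / bh < aspect) bw <- bh * aspect else bh <- bw / aspect
  s <- out_size[1] / bw
  # p_roi = (p - center) * s + out_size / 2; row-vector convention
  # (points multiply on the left), so translations sit in the third row
  forward <- matrix(c(s, 0, out_size[1] / 2 - s * cx,
                      0, s, out_size[2] / 2 - s * cy,
                      0, 0, 1), 3, 3)
  inverse <- matrix(c(1 / s, 0, cx - out_size[1] / (2 * s),
                      0, 1 / s, cy - out_size[2] / (2 * s),
                      0, 0, 1), 3, 3)
  structure(list(forward = forward, inverse = inverse,
                 out_size = out_size, padding = padding),
            class = "roi_transform")
}

#' Apply an ROI transform to 2-D points
#'
#' @param tf a [roi_transform()].
#' @param xy n x 2 matrix (or length-2 vector) of 0-based points.
#' @param inverse map from ROI back to image coordinates.
#' @return n x 2 matrix of transformed points.
#' @export
apply_roi_transform <- function(tf, xy, inverse = FALSE) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  m <- if (inverse) tf$inverse else tf$forward
  out <- cbind(xy, 1) %*% m
  out[, 1:2, drop = FALSE]
}

#' Warp an image into an ROI input window
#'
#' Bilinearly samples the image through the inverse affine of the
#' transform, producing the `out_size` crop the localizer consumes.
#'
#' @param pixels H x W x 3 array in \[0,255\].
#' @param tf a [roi_transform()].
#' @return out_h x out_w x 3 array.
#' @export
warp_roi <- function(pixels, tf) {
  ow <- tf$out_size[1]; oh <- tf$out_size[2]
  xo <- rep(seq_len(ow) - 1, each = oh)
  yo <- rep(seq_len(oh) - 1, times = ow)
  src <- apply_roi_transform(tf, cbind(xo, yo), inverse = TRUE)
  samp <- bilinear_sample(pixels, src[, 1], src[, 2])
  array(samp, c(oh, ow, 3))
}

#' Run the two-stage detection harness
#'
#' Top-down composition: the detector proposes the body-region bounding
#' box, the box is expanded and warped into a fixed-size ROI, the
#' localizer predicts keypoints in ROI coordinates, and the predictions
#' are mapped back to image coordinates through the inverse affine.
#' Keypoints the localizer places outside the ROI window are marked
#' invisible. Network inference is out of scope: detectors and localizers
#' are injected functions (see [oracle_detector()], [oracle_localizer()],
#' [noisy_localizer()]).
#'
#' @param image an [annotated_image()] (or plain H x W x 3 array).
#' @param detector function `image -> bounding_box` (NULL return raises a
#'   detector error distinct from localizer failure).
#' @param localizer function `(roi_pixels, roi_transform) -> keypoint_set`
#'   in ROI coordinates.
#' @param padding box expansion factor (default 1.25).
#' @param out_size ROI window `c(w, h)` (default 192 x 256).
#' @return a [keypoint_set()] in image coordinates.
#' @export
run_pipeline <- function(image, detector, localizer, padding = 1.25,
                         out_size = c(192, 256)) {
  pixels <- if (inherits(image, "annotated_image")) image$pixels else image
  box <- detector(image)
  if (is.null(box)) {
    stop(structure(class = c("acukit_detector_error", "error", "condition"),
                   list(message = "detector returned no bounding box",
                        call = sys.call())))
  }
  tf <- roi_transform(box, padding, out_size)
  roi <- warp_roi(pixels, tf)
  kp <- localizer(roi, tf)
  kp <- as_keypoint_set(kp)
  inside <- kp$x >= 0 & kp$x < out_size[1] & kp$y >= 0 & kp$y < out_size[2]
  back <- apply_roi_transform(tf, cbind(kp$x, kp$y), inverse = TRUE)
  kp$x <- back[, 1]; kp$y <- back[, 2]
  kp$visible <- kp$visible & inside
  kp
}

#' Oracle detector: the fixture's true marker extent
#'
#' Returns the bounding box of the visible ground-truth keypoints expanded
#' by `margin_px` — a perfect first stage for harness tests.
#'
#' @param margin_px padding around the keypoint extent (default 20).
#' @return a detector function for [run_pipeline()].
#' @export
oracle_detector <- function(margin_px = 20) {
  function(image) {
    stopifnot(inherits(image, "annotated_image"))
    kp <- image$keypoints[image$keypoints$visible, ]
    if (nrow(kp) == 0) return(NULL)
    bounding_box(min(kp$x) - margin_px, min(kp$y) - margin_px,
                 max(kp$x) + margin_px, max(kp$y) + margin_px)
  }
}

#' Oracle localizer: ground truth expressed in ROI coordinates
#'
#' @param truth a [keypoint_set()] in image coordinates.
#' @return a localizer function for [run_pipeline()].
#' @export
oracle_localizer <- function(truth) {
  truth <- as_keypoint_set(truth)
  function(roi, tf) {
    p <- apply_roi_transform(tf, cbind(truth$x, truth$y))
    keypoint_set(truth$label, p[, 1], p[, 2], truth$visible)
  }
}

#' Noisy localizer: ground truth plus Gaussian image-space error
#'
#' Displaces the ground truth by isotropic Gaussian noise of `sigma`
#' pixels (in image space, so the error survives the back-mapping
#' unchanged) before expressing it in ROI coordinates.
#'
#' @param truth a [keypoint_set()] in image coordinates.
#' @param sigma per-axis noise sd in image pixels.
#' @param seed integer RNG seed.
#' @return a localizer function for [run_pipeline()].
#' @export
noisy_localizer <- function(truth, sigma, seed = 1) {
  noisy <- mock_predictions(truth, sigma = sigma, miss_rate = 0, seed = seed)
  oracle_localizer(noisy)
}
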