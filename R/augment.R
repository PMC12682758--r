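#' Default left/right label swap map for horizontal flips
#'
#' Mirrors anatomical sides: `L_i <-> R_i` for `i = 1..n_side`; midline
#' labels (`M*`) are fixed points. The map is an involution.
#'
#' @param n_side number of left/right pairs (default 14).
#' @return named character vector mapping old labels to new.
#' @export
default_swap_map <- function(n_side = 14) {
  l <- paste0("L", seq_len(n_side)); r <- paste0("R", seq_len(n_side))
  stats::setNames(c(r, l), c(l, r))
}

apply_swap <- function(labels, swap_map) {
  if (is.null(swap_map) || length(swap_map) == 0) return(labels)
  # involution check: applying the map twice must be the identity
  targets <- unname(swap_map)
  back <- swap_map[targets]
  missing_back <- is.na(back) & !(targets %in% names(swap_map))
  if (any(missing_back) ||
      any(!is.na(back) & back != names(swap_map))) {
    stop("swap_map is not an involution")
  }
  hit <- labels %in% names(swap_map)
  labels[hit] <- unname(swap_map[labels[hit]])
  labels
}

#' Scale an annotated image
#'
#' Resamples the raster bilinearly to `round(size * factor)`, keypoints map
#' as `(x, y) -> (x * factor, y * factor)`, and the marker mask is
#' resampled by nearest neighbor.
#'
#' @param img an [annotated_image()].
#' @param factor scale ratio (> 0).
#' @return the scaled [annotated_image()].
#' @export
aug_scale <- function(img, factor) {
  stopifnot(inherits(img, "annotated_image"), factor > 0)
  h <- image_height(img); w <- image_width(img)
  nh <- round(h * factor); nw <- round(w * factor)
  if (nh < 1 || nw < 1) stop("scaled image would be smaller than 1 px")
  # center-aligned source coordinates for each output pixel center
  xo <- ((seq_len(nw) - 1) + 0.5) / factor - 0.5
  yo <- ((seq_len(nh) - 1) + 0.5) / factor - 0.5
  xs <- rep(xo, each = nh); ys <- rep(yo, times = nw)
  samp <- bilinear_sample(img$pixels, xs, ys)
  pixels <- array(samp, c(nh, nw, 3))
  mask <- NULL
  if (!is.null(img$mask)) {
    mask <- matrix(nearest_sample(img$mask, xs, ys), nh, nw)
  }
  kp <- img$keypoints
  kp$x <- kp$x * factor; kp$y <- kp$y * factor
  annotated_image(clamp(pixels, 0, 255), kp, mask)
}

#' Crop an annotated image
#'
#' The crop window (0-based origin, `c(width, height)` size) is clamped to
#' the image bounds; keypoints shift by the clamped origin and points
#' falling outside the window are marked invisible with their shifted
#' coordinates retained for audit.
#'
#' @param img an [annotated_image()].
#' @param origin length-2 `c(x, y)` window origin in pixels.
#' @param size length-2 `c(w, h)` window size in pixels.
#' @return the cropped [annotated_image()].
#' @export
aug_crop <- function(img, origin, size) {
  stopifnot(inherits(img, "annotated_image"),
            length(origin) == 2, length(size) == 2, all(size >= 1))
  h <- image_height(img); w <- image_width(img)
  x0 <- max(0, floor(origin[1])); y0 <- max(0, floor(origin[2]))
  x1 <- min(w - 1, floor(origin[1]) + size[1] - 1)
  y1 <- min(h - 1, floor(origin[2]) + size[2] - 1)
  if (x0 > x1 || y0 > y1) stop("crop window does not intersect the image")
  rows <- (y0:y1) + 1; cols <- (x0:x1) + 1
  pixels <- img$pixels[rows, cols, , drop = FALSE]
  mask <- if (is.null(img$mask)) NULL else img$mask[rows, cols, drop = FALSE]
  kp <- img$keypoints
  kp$x <- kp$x - x0; kp$y <- kp$y - y0
  inside <- kp$x >= 0 & kp$x <= (x1 - x0) & kp$y >= 0 & kp$y <= (y1 - y0)
  kp$visible <- kp$visible & inside
  annotated_image(pixels, kp, mask)
}

#' Horizontally flip an annotated image with left/right label swapping
#'
#' Mirrors pixels about the vertical axis (`x -> W - 1 - x` under the
#' 0-based pixel-center convention) and renames keypoint labels through the
#' involutive `swap_map` so anatomical sides stay correct.
#'
#' @param img an [annotated_image()].
#' @param swap_map named character vector as from [default_swap_map()];
#'   `NULL` keeps labels unchanged.
#' @return the flipped [annotated_image()].
#' @export
aug_hflip <- function(img, swap_map = default_swap_map()) {
  stopifnot(inherits(img, "annotated_image"))
  w <- image_width(img)
  pixels <- img$pixels[, w:1, , drop = FALSE]
  mask <- if (is.null(img$mask)) NULL else img$mask[, w:1, drop = FALSE]
  kp <- img$keypoints
  kp$x <- (w - 1) - kp$x
  kp$label <- apply_swap(kp$label, swap_map)
  annotated_image(pixels, kp, mask)
}

#' Configuration for the random augmentation pipeline
#'
#' @param scale_range `c(lo, hi)` uniform scale factor range
#'   (default `c(0.7, 1.3)`).
#' @param crop_size `c(w, h)` crop window in pixels of the scaled image;
#'   `NULL` crops to 80 percent of each side.
#' @param min_visible_fraction minimum fraction of previously-visible
#'   keypoints the crop must retain (default 0.5; resampled up to 10
#'   times).
#' @param flip_prob probability of a horizontal flip (default 0.5).
#' @param swap_map label swap map for flips.
#' @param seed integer RNG seed.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(scale_range = c(0.7, 1.3), crop_size = NULL,
                           min_visible_fraction = 0.5, flip_prob = 0.5,
                           swap_map = default_swap_map(), seed = 1) {
  stopifnot(length(scale_range) == 2, scale_range[1] > 0,
            scale_range[1] <= scale_range[2],
            min_visible_fraction >= 0, min_visible_fraction <= 1,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(scale_range = scale_range, crop_size = crop_size,
                 min_visible_fraction = min_visible_fraction,
                 flip_prob = flip_prob, swap_map = swap_map,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Apply a seeded random scale/crop/flip pipeline
#'
#' Samples a scale factor, a crop origin (resampled until the window keeps
#' at least `min_visible_fraction` of the visible keypoints, at most 10
#' tries) and a flip decision, then applies
#' [aug_scale()], [aug_crop()], [aug_hflip()] in that order. A fixed seed
#' reproduces the output byte for byte.
#'
#' @param img an [annotated_image()].
#' @param config an [augment_config()].
#' @return an [annotated_image()], with attribute `params` recording the
#'   sampled factor, origin and flip flag.
#' @export
augment_random <- function(img, config = augment_config()) {
  stopifnot(inherits(img, "annotated_image"))
  with_seed(config$seed, {
    factor <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    scaled <- aug_scale(img, factor)
    sw <- image_width(scaled); sh <- image_height(scaled)
    size <- config$crop_size
    if (is.null(size)) size <- c(max(1, round(0.8 * sw)),
                                 max(1, round(0.8 * sh)))
    size <- pmin(size, c(sw, sh))
    n_vis <- sum(scaled$keypoints$visible)
    cropped <- NULL; origin <- c(0, 0)
    for (try in 1:10) {
      origin <- c(floor(stats::runif(1, 0, sw - size[1] + 1)),
                  floor(stats::runif(1, 0, sh - size[2] + 1)))
      cand <- aug_crop(scaled, origin, size)
      keep <- if (n_vis == 0) 1 else sum(cand$keypoints$visible) / n_vis
      cropped <- cand
      if (keep >= config$min_visible_fraction) break
    }
    flipped <- stats::runif(1) < config$flip_prob
    out <- if (flipped) aug_hflip(cropped, config$swap_map) else cropped
    attr(out, "params") <- list(factor = factor, origin = origin,
                                flip = flipped)
    out
  })
}
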