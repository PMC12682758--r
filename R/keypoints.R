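#' Construct a keypoint set
#'
#' A keypoint set holds named 2-D points in pixel units with visibility
#' flags. Coordinates are 0-based with x increasing rightward and y
#' increasing downward (the convention of Labelme point annotations);
#' sub-pixel values are allowed.
#'
#' @param label character vector of unique labels (e.g. `"M1"`, `"L3"`).
#' @param x,y numeric coordinates in pixels, same length as `label`.
#' @param visible logical visibility flags, recycled to length of `label`.
#' @return A data frame of class `keypoint_set` with columns
#'   `label`, `x`, `y`, `visible`.
#' @examples
#' keypoint_set(c("M1", "L1"), x = c(320, 200), y = c(100, 120))
#' @export
keypoint_set <- function(label = character(), x = numeric(),
                         y = numeric(), visible = TRUE) {
  label <- as.character(label)
  stopifnot(length(x) == length(label), length(y) == length(label))
  if (anyDuplicated(label)) {
    stop("keypoint labels must be unique: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  visible <- rep_len(as.logical(visible), length(label))
  if (any(visible & (!is.finite(x) | !is.finite(y)))) {
    stop("visible keypoints must have finite coordinates")
  }
  out <- data.frame(label = label, x = as.numeric(x), y = as.numeric(y),
                    visible = visible, stringsAsFactors = FALSE)
  class(out) <- c("keypoint_set", "data.frame")
  out
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %d points, %d visible>\n",
              nrow(x), sum(x$visible)))
  print.data.frame(x, ...)
  invisible(x)
}

is_keypoint_set <- function(x) inherits(x, "keypoint_set")

as_keypoint_set <- function(x) {
  if (is_keypoint_set(x)) return(x)
  stopifnot(is.data.frame(x), all(c("label", "x", "y") %in% names(x)))
  keypoint_set(x$label, x$x, x$y,
               if ("visible" %in% names(x)) x$visible else TRUE)
}

# Match two keypoint sets by label; returns index pairs for labels present
# (and, when visible_only, visible) in both.
match_keypoints <- function(pred, truth, visible_only = TRUE) {
  pred <- as_keypoint_set(pred); truth <- as_keypoint_set(truth)
  common <- intersect(pred$label, truth$label)
  ip <- match(common, pred$label)
  it <- match(common, truth$label)
  if (visible_only) {
    keep <- pred$visible[ip] & truth$visible[it]
    ip <- ip[keep]; it <- it[keep]
  }
  list(pred = ip, truth = it, labels = pred$label[ip])
}

#' Construct an annotated image
#'
#' The unit flowing through de-labeling, augmentation and evaluation: an
#' 8-bit RGB raster plus named keypoints and an optional binary marker mask.
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 255\].
#' @param keypoints a [keypoint_set()].
#' @param mask optional H x W logical matrix marking marker pixels.
#' @return A list of class `annotated_image` with elements `pixels`,
#'   `keypoints`, `mask`.
#' @export
annotated_image <- function(pixels, keypoints = keypoint_set(), mask = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  keypoints <- as_keypoint_set(keypoints)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (!identical(dim(mask), dim(pixels)[1:2])) {
      stop("mask shape must equal image shape")
    }
  }
  structure(list(pixels = pixels, keypoints = keypoints, mask = mask),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image: %d x %d, %d keypoints, mask: %s>\n",
              d[2], d[1], nrow(x$keypoints),
              if (is.null(x$mask)) "none" else sprintf("%d px", sum(x$mask))))
  invisible(x)
}

image_width <- function(img) dim(img$pixels)[2]
image_height <- function(img) dim(img$pixels)[1]

# Rec.601 luma from an RGB array (rows x cols matrix out).
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}
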