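#' Write keypoints as a Labelme-style point-annotation JSON file
#'
#' Emits the minimal Labelme schema used for point annotations: top-level
#' `imageHeight`, `imageWidth` and a `shapes` list of
#' `{label, points: [[x, y]], shape_type: "point"}` entries. Coordinates are
#' 0-based, x rightward, y downward; sub-pixel floats are preserved.
#' Invisible keypoints are written with a `"visible": false` flag so a
#' round trip is lossless.
#'
#' @param keypoints a [keypoint_set()].
#' @param path output file path.
#' @param width,height dimensions of the annotated image in pixels.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(keypoints, path, width, height) {
  keypoints <- as_keypoint_set(keypoints)
  shapes <- lapply(seq_len(nrow(keypoints)), function(i) {
    s <- list(
      label = keypoints$label[i],
      points = list(c(keypoints$x[i], keypoints$y[i])),
      shape_type = "point"
    )
    if (!keypoints$visible[i]) s$visible <- FALSE
    s
  })
  obj <- list(imageHeight = as.integer(height),
              imageWidth = as.integer(width),
              shapes = shapes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Labelme-style point-annotation JSON file
#'
#' @param path file written by [write_labelme()] or by the Labelme tool
#'   (point shapes only; other shape types are skipped with a warning).
#' @return list with `keypoints` (a [keypoint_set()]), `width`, `height`.
#' @export
read_labelme <- function(path) {
  obj <- jsonlite::read_json(path)
  shapes <- obj$shapes %||% list()
  pts <- lapply(shapes, function(s) {
    if (!identical(s$shape_type, "point")) return(NULL)
    p <- unlist(s$points[[1]])
    list(label = s$label, x = as.numeric(p[1]), y = as.numeric(p[2]),
         visible = !isFALSE(s$visible))
  })
  skipped <- sum(vapply(pts, is.null, logical(1)))
  if (skipped > 0) warning(skipped, " non-point shapes skipped")
  pts <- Filter(Negate(is.null), pts)
  kp <- keypoint_set(
    vapply(pts, `[[`, character(1), "label"),
    vapply(pts, `[[`, numeric(1), "x"),
    vapply(pts, `[[`, numeric(1), "y"),
    vapply(pts, `[[`, logical(1), "visible")
  )
  list(keypoints = kp,
       width = as.integer(obj$imageWidth),
       height = as.integer(obj$imageHeight))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image or depth raster as plain-text PNM
#'
#' Color H x W x 3 arrays are written as plain PPM (`P3`, maxval 255);
#' single-channel matrices (e.g. 16-bit depth in millimeters) as plain PGM
#' (`P2`) with `maxval` 65535 by default. Plain PNM keeps every artifact of
#' the pipeline a text file; [write_image()] writes PNG when the optional
#' `png` package is installed.
#'
#' @param x H x W x 3 array in \[0,255\] or an H x W numeric matrix.
#' @param path output path.
#' @param maxval maximum sample value for matrices (default 65535).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(x, path, maxval = 65535) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(x)) {
    vals <- as.vector(round(t(x)))  # row-major raster order
    stopifnot(min(vals) >= 0, max(vals) <= maxval)
    writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
    write(as.integer(vals), con, ncolumns = 16)
  } else {
    stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
    h <- dim(x)[1]; w <- dim(x)[2]
    vals <- round(aperm(x, c(3, 2, 1)))  # channel fastest, then col, then row
    stopifnot(min(vals) >= 0, max(vals) <= 255)
    writeLines(c("P3", paste(w, h), "255"), con)
    write(as.integer(vals), con, ncolumns = 15)
  }
  invisible(path)
}

#' Read a plain-text PNM (P2/P3) raster
#'
#' @param path file written by [write_pnm()] or any plain PGM/PPM.
#' @return an H x W numeric matrix (P2) or H x W x 3 array (P3).
#' @export
read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  dims <- as.integer(toks[2:4])  # width height maxval
  w <- dims[1]; h <- dims[2]
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    stopifnot(length(vals) == w * h)
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    stopifnot(length(vals) == 3 * w * h)
    a <- array(vals, dim = c(3, w, h))
    aperm(a, c(3, 2, 1))
  } else {
    stop("unsupported PNM magic: ", magic)
  }
}

#' Write an 8-bit color image to PNG or PNM by extension
#'
#' `.png` requires the optional `png` package; any other extension is
#' written as plain PPM via [write_pnm()].
#'
#' @param pixels H x W x 3 array in \[0,255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG output needs the 'png' package; use a .ppm path instead")
    }
    png::writePNG(pixels / 255, path)
  } else {
    write_pnm(pixels, path)
  }
  invisible(path)
}

#' Read an 8-bit color image (PNG or PNM)
#'
#' @param path image path; `.png` requires the optional `png` package.
#' @return H x W x 3 numeric array in \[0,255\].
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG input needs the 'png' package")
    }
    px <- png::readPNG(path) * 255
    if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
    if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
    px
  } else {
    px <- read_pnm(path)
    if (is.matrix(px)) px <- array(rep(px, 3), c(dim(px), 3))
    px
  }
}

#' Read camera intrinsics from JSON
#'
#' Accepts either `{f_mm, rho_w_mm, rho_h_mm, u0, v0}` (physical focal
#' length and pixel pitch) or `{fx_px, fy_px, u0, v0}` (focal lengths in
#' pixel units).
#'
#' @param path JSON file path.
#' @return a [camera_model()].
#' @export
read_intrinsics <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!is.null(obj$f_mm)) {
    camera_model(f = obj$f_mm, rho_w = obj$rho_w_mm, rho_h = obj$rho_h_mm,
                 u0 = obj$u0, v0 = obj$v0)
  } else {
    camera_model_px(fx = obj$fx_px, fy = obj$fy_px,
                    u0 = obj$u0, v0 = obj$v0)
  }
}

#' Read a camera-to-base rigid transform from JSON
#'
#' The file holds a 4 x 4 homogeneous matrix as a row-major nested array.
#'
#' @param path JSON file path.
#' @return a [rigid_transform()].
#' @export
read_extrinsics <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(unname(as.matrix(m)))
}
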