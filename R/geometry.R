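#' Central-perspective camera model
#'
#' Intrinsics of the color camera: focal length `f` (mm), pixel pitch
#' `rho_w`, `rho_h` (mm per pixel) and principal point `(u0, v0)`
#' (pixels). The intrinsic matrix is
#' `K = [[f/rho_w, 0, u0], [0, f/rho_h, v0], [0, 0, 1]]`.
#'
#' @param f focal length in millimeters (> 0).
#' @param rho_w,rho_h pixel width and height in millimeters (> 0).
#' @param u0,v0 principal point in pixels.
#' @return list of class `camera_model` with the parameters and `K`.
#' @export
camera_model <- function(f, rho_w, rho_h, u0, v0) {
  stopifnot(f > 0, rho_w > 0, rho_h > 0)
  K <- matrix(c(f / rho_w, 0, 0,
                0, f / rho_h, 0,
                u0, v0, 1), 3, 3)
  structure(list(f = f, rho_w = rho_w, rho_h = rho_h,
                 u0 = u0, v0 = v0, K = K),
            class = "camera_model")
}

#' Camera model from pixel-unit focal lengths
#'
#' Convenience constructor when calibration reports `fx`, `fy` in pixels
#' (`fx = f / rho_w`): uses a unit focal length and derives the pitches.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param u0,v0 principal point in pixels.
#' @return a [camera_model()].
#' @export
camera_model_px <- function(fx, fy, u0, v0) {
  stopifnot(fx > 0, fy > 0)
  camera_model(f = 1, rho_w = 1 / fx, rho_h = 1 / fy, u0 = u0, v0 = v0)
}

#' Rigid camera-to-base transform
#'
#' A 4 x 4 homogeneous matrix whose rotation block must be orthonormal
#' with determinant +1 and whose last row is `(0, 0, 0, 1)`.
#'
#' @param T 4 x 4 numeric matrix.
#' @param tol orthonormality tolerance (default 1e-8).
#' @return matrix of class `rigid_transform`.
#' @export
rigid_transform <- function(T, tol = 1e-8) {
  T <- as.matrix(T)
  stopifnot(identical(dim(T), c(4L, 4L)))
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > tol) {
    stop("last row must be (0, 0, 0, 1)")
  }
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("rotation block is not a proper rotation")
  }
  structure(T, class = "rigid_transform")
}

#' Rigid transform from a rotation and a translation
#'
#' @param R 3 x 3 rotation matrix (default identity).
#' @param t length-3 translation in millimeters (default zero).
#' @return a [rigid_transform()].
#' @export
make_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  rigid_transform(T)
}

#' Look up the registered depth for a color-image pixel
#'
#' Color and depth rasters differ in resolution; the color pixel `(u, v)`
#' maps to the depth pixel `(u * s_w, v * s_h)` (rounded to the nearest
#' depth pixel, or bilinearly interpolated). A depth of 0 encodes "no
#' return" and yields `NA` as the invalid-depth signal.
#'
#' @param u,v 0-based color-image pixel coordinates (must be in bounds).
#' @param frame a `depth_frame` (see [make_depth_frame()]).
#' @param interp `"nearest"` (default) or `"bilinear"`.
#' @return depth in millimeters, or `NA_real_` for an invalid return.
#' @export
register_depth <- function(u, v, frame, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(frame, "depth_frame"))
  hd <- nrow(frame$depth); wd <- ncol(frame$depth)
  w_color <- wd / frame$s_w; h_color <- hd / frame$s_h
  if (u < 0 || v < 0 || u >= w_color || v >= h_color) {
    stop("pixel (", u, ", ", v, ") outside the color image bounds")
  }
  ud <- u * frame$s_w; vd <- v * frame$s_h
  if (interp == "nearest") {
    ui <- clamp(round(ud), 0, wd - 1); vi <- clamp(round(vd), 0, hd - 1)
    z <- frame$depth[vi + 1, ui + 1]
  } else {
    u0 <- clamp(floor(ud), 0, wd - 1); v0 <- clamp(floor(vd), 0, hd - 1)
    u1 <- min(u0 + 1, wd - 1); v1 <- min(v0 + 1, hd - 1)
    fu <- ud - u0; fv <- vd - v0
    z <- (1 - fv) * ((1 - fu) * frame$depth[v0 + 1, u0 + 1] +
                       fu * frame$depth[v0 + 1, u1 + 1]) +
      fv * ((1 - fu) * frame$depth[v1 + 1, u0 + 1] +
              fu * frame$depth[v1 + 1, u1 + 1])
  }
  if (is.na(z) || z == 0) return(NA_real_)
  z
}

#' Back-project a pixel to camera-frame coordinates
#'
#' Central perspective model:
#' `x_c = (u - u0) * rho_w * z / f`, `y_c = (v - v0) * rho_h * z / f`,
#' `z_c = z`.
#'
#' @param u,v 0-based pixel coordinates.
#' @param z depth along the optical axis in millimeters (> 0).
#' @param cam a [camera_model()].
#' @return length-3 numeric `c(x_c, y_c, z_c)` in millimeters, frame tag
#'   `"camera"` in attribute `frame`.
#' @export
pixel_to_camera <- function(u, v, z, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (z <= 0) stop("depth must be positive")
  p <- c((u - cam$u0) * cam$rho_w * z / cam$f,
         (v - cam$v0) * cam$rho_h * z / cam$f,
         z)
  attr(p, "frame") <- "camera"
  p
}

#' Project a camera-frame point to pixel coordinates
#'
#' Forward model (`u = x_c * f / (rho_w * z_c) + u0` and likewise for v),
#' the algebraic inverse of [pixel_to_camera()].
#'
#' @param p length-3 camera-frame point in millimeters, `z > 0`.
#' @param cam a [camera_model()].
#' @return length-2 `c(u, v)` in pixels.
#' @export
camera_to_pixel <- function(p, cam) {
  stopifnot(inherits(cam, "camera_model"), p[3] > 0)
  c(p[1] * cam$f / (cam$rho_w * p[3]) + cam$u0,
    p[2] * cam$f / (cam$rho_h * p[3]) + cam$v0)
}

#' Transform a camera-frame point to the robot base frame
#'
#' Homogeneous multiply `P_base = T_cb %*% P_camera`.
#'
#' @param p length-3 camera-frame point (mm).
#' @param T a [rigid_transform()].
#' @return length-3 base-frame point, frame tag `"base"`.
#' @export
camera_to_base <- function(p, T) {
  stopifnot(inherits(T, "rigid_transform"))
  if (!is.null(attr(p, "frame")) && attr(p, "frame") != "camera") {
    stop("point is not in the camera frame")
  }
  out <- as.numeric(unclass(T) %*% c(p[1:3], 1))[1:3]
  attr(out, "frame") <- "base"
  out
}

#' Localize keypoints in the robot base frame
#'
#' Chains depth registration, pinhole back-projection and the rigid
#' camera-to-base transform for every visible keypoint. Keypoints over an
#' invalid depth return (depth 0) are reported with `valid = FALSE` and
#' `NA` coordinates rather than silently dropped.
#'
#' @param kps a [keypoint_set()] in color-image pixels.
#' @param frame a `depth_frame`.
#' @param cam a [camera_model()].
#' @param T a [rigid_transform()] (camera to base).
#' @param interp depth lookup mode passed to [register_depth()].
#' @return data frame with columns `label`, `x_b`, `y_b`, `z_b`, `valid`.
#' @export
localize_keypoints <- function(kps, frame, cam, T,
                               interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  kps <- as_keypoint_set(kps)
  kps <- kps[kps$visible, , drop = FALSE]
  n <- nrow(kps)
  out <- data.frame(label = kps$label,
                    x_b = rep(NA_real_, n), y_b = rep(NA_real_, n),
                    z_b = rep(NA_real_, n), valid = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    z <- register_depth(kps$x[i], kps$y[i], frame, interp)
    if (is.na(z)) next
    pc <- pixel_to_camera(kps$x[i], kps$y[i], z, cam)
    pb <- camera_to_base(pc, T)
    out$x_b[i] <- pb[1]; out$y_b[i] <- pb[2]; out$z_b[i] <- pb[3]
    out$valid[i] <- TRUE
  }
  out
}
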