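d435 <- function() camera_model(f = 2, rho_w = 0.002, rho_h = 0.002,
                                u0 = 320, v0 = 240)

test_that("depth registration maps color pixels to depth pixels", {
  spec <- fixture_spec(width = 8, height = 6, keypoints = list())
  fr <- make_depth_frame(spec, c(1, 1), plane_depth = 500)
  fr$depth[] <- seq_len(48)  # distinctive values
  expect_equal(register_depth(3, 2, fr), fr$depth[3, 4])

  half <- make_depth_frame(spec, c(0.5, 0.5), plane_depth = 500)
  half$depth[] <- 100 + seq_len(length(half$depth))
  # u = 6 reads depth column 6 * 0.5 = 3 (0-based)
  expect_equal(register_depth(6, 2, half), half$depth[2, 4])

  flat <- make_depth_frame(spec, c(1, 1), plane_depth = 800)
  for (u in c(0, 3, 7)) expect_equal(register_depth(u, 1, flat), 800)

  hole <- fr; hole$depth[1, 1] <- 0
  expect_true(is.na(register_depth(0, 0, hole)))
  expect_error(register_depth(8, 0, fr), "outside")
  expect_error(register_depth(0, -1, fr), "outside")
})

test_that("back-projection follows the central perspective model", {
  cam <- d435()
  p <- pixel_to_camera(320, 240, 750, cam)
  expect_equal(as.numeric(p), c(0, 0, 750))

  # f/rho = 1000 px: 100 px off-axis at 1 m is 100 mm
  p2 <- pixel_to_camera(420, 240, 1000, cam)
  expect_equal(p2[1], 100)
  expect_equal(p2[2], 0)

  expect_error(pixel_to_camera(10, 10, 0, cam), "positive")

  # algebraic inverse: project-then-backproject on random interior points
  set.seed(12)
  for (i in 1:1000) {
    uvz <- c(runif(1, 0, 639), runif(1, 0, 479), runif(1, 300, 2000))
    pc <- pixel_to_camera(uvz[1], uvz[2], uvz[3], cam)
    uv <- camera_to_pixel(pc, cam)
    expect_lt(max(abs(uv - uvz[1:2])), 1e-9)
  }
})

test_that("rigid transforms are validated isometries", {
  p <- structure(c(1, 2, 3), frame = "camera")
  expect_equal(as.numeric(camera_to_base(p, rigid_transform(diag(4)))),
               c(1, 2, 3))
  expect_equal(attr(camera_to_base(p, rigid_transform(diag(4))), "frame"),
               "base")

  tr <- make_transform(t = c(10, 0, 0))
  expect_equal(as.numeric(camera_to_base(p, tr)), c(11, 2, 3))

  # random rotation via QR; distances preserved on a random triple
  set.seed(14)
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  T <- make_transform(qr_R, rnorm(3, sd = 100))
  pts <- matrix(rnorm(9, sd = 50), 3)
  tpts <- apply(pts, 2, function(v) {
    as.numeric(camera_to_base(structure(v, frame = "camera"), T))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sqrt(sum((tpts[, i] - tpts[, j])^2)),
                 sqrt(sum((pts[, i] - pts[, j])^2)), tolerance = 1e-9)
  }

  # composing with the inverse transform is the identity
  Tinv <- rigid_transform(solve(unclass(T)))
  round_trip <- camera_to_base(
    structure(as.numeric(camera_to_base(p, T)), frame = "camera"), Tinv)
  expect_equal(as.numeric(round_trip), c(1, 2, 3), tolerance = 1e-9)

  bad <- diag(4); bad[1, 1] <- 2
  expect_error(rigid_transform(bad), "rotation")
  bad2 <- diag(4); bad2[4, 1] <- 1
  expect_error(rigid_transform(bad2), "last row")
})

test_that("keypoint localization chains depth, camera and base frames", {
  cam <- d435()
  spec <- fixture_spec(width = 640, height = 480, keypoints = list())
  flat <- make_depth_frame(spec, c(0.5, 0.5), plane_depth = 800)

  empty <- localize_keypoints(keypoint_set(), flat, cam,
                              rigid_transform(diag(4)))
  expect_equal(nrow(empty), 0)

  kps <- keypoint_set(c("M1", "M2", "M3"), c(320, 320, 320),
                      c(100, 240, 380))
  out <- localize_keypoints(kps, flat, cam, rigid_transform(diag(4)))
  expect_true(all(out$valid))
  expect_equal(out$z_b, rep(800, 3))

  # generated colinear: localized base points are colinear too
  d01 <- c(out$x_b[2] - out$x_b[1], out$y_b[2] - out$y_b[1],
           out$z_b[2] - out$z_b[1])
  d02 <- c(out$x_b[3] - out$x_b[1], out$y_b[3] - out$y_b[1],
           out$z_b[3] - out$z_b[1])
  cross <- c(d01[2] * d02[3] - d01[3] * d02[2],
             d01[3] * d02[1] - d01[1] * d02[3],
             d01[1] * d02[2] - d01[2] * d02[1])
  expect_lt(max(abs(cross)), 1e-9)

  # a zero-depth hole is reported invalid, not dropped
  hole <- flat
  hole$depth[round(100 * 0.5) + 1, round(320 * 0.5) + 1] <- 0
  out2 <- localize_keypoints(kps, hole, cam, rigid_transform(diag(4)))
  expect_equal(nrow(out2), 3)
  expect_false(out2$valid[out2$label == "M1"])
  expect_true(is.na(out2$x_b[out2$label == "M1"]))
  expect_true(all(out2$valid[out2$label != "M1"]))
})

test_that("intrinsics and extrinsics round-trip through config files", {
  f1 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(f_mm = 2, rho_w_mm = 0.002, rho_h_mm = 0.0021,
                            u0 = 321.5, v0 = 239.5),
                       f1, auto_unbox = TRUE, digits = NA)
  cam <- read_intrinsics(f1)
  expect_equal(cam$K[1, 1], 1000)
  expect_equal(cam$K[2, 2], 2 / 0.0021)
  expect_equal(cam$K[1, 3], 321.5)

  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(fx_px = 600, fy_px = 610, u0 = 320, v0 = 240),
                       f2, auto_unbox = TRUE, digits = NA)
  cam2 <- read_intrinsics(f2)
  expect_equal(cam2$K[1, 1], 600)
  expect_equal(cam2$K[2, 2], 610)

  T <- make_transform(t = c(5, -3, 12))
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(apply(unclass(T), 1, identity, simplify = FALSE),
                       f3, digits = NA)
  T2 <- read_extrinsics(f3)
  expect_equal(unclass(T2), unclass(T))
})
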