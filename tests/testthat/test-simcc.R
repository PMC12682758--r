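test_that("SimCC encoding is a normalized, centered, symmetric Gaussian", {
  for (coord in c(0, 10.25, 63.999)) {
    v <- simcc_encode(coord, extent = 64, ratio = 2, sigma_bins = 6)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(length(v), 128)
  }
  v <- simcc_encode(32, extent = 64, ratio = 2, sigma_bins = 6)
  expect_equal(which.max(v) - 1, round(32 * 2))

  # interior coordinate: weights symmetric about the peak, and equal to a
  # directly evaluated Gaussian
  v2 <- simcc_encode(30.5, 64, 2, 6)
  b <- 0:127
  direct <- exp(-(b - 61)^2 / (2 * 36)); direct <- direct / sum(direct)
  expect_equal(v2, direct, tolerance = 1e-12)
  peak <- 62  # index of bin 61
  for (k in 1:20) {
    expect_equal(v2[peak - k], v2[peak + k], tolerance = 1e-12)
  }

  expect_error(simcc_encode(-1, 64), "outside")
  expect_error(simcc_encode(64, 64), "outside")
})

test_that("SimCC decoding inverts encoding to sub-pixel accuracy", {
  expect_equal(simcc_decode(c(0, 0, 1, 0), ratio = 2), 2 / 2)
  expect_equal(simcc_decode(rep(1, 128), ratio = 2), mean(0:127) / 2)
  expect_error(simcc_decode(rep(0, 8)), "all-zero")
  expect_error(simcc_decode(c(-1, 2)), "non-negative")

  # round-trip sweep, interior coords at least 3 sigma from the borders
  for (ratio in c(1, 2, 3)) {
    lo <- 3 * 6 / ratio; hi <- 64 - lo
    coords <- seq(lo, hi, length.out = 200)
    err <- vapply(coords, function(x) {
      abs(simcc_decode(simcc_encode(x, 64, ratio, 6), ratio) - x)
    }, numeric(1))
    expect_lt(max(err), 1 / (2 * ratio))
  }
})

test_that("the KL objective is a proper divergence on label vectors", {
  t <- simcc_encode(20, 64, 2, 6)
  expect_equal(kl_divergence(t, t), 0, tolerance = 1e-9)

  n <- 64
  onehot <- c(1, rep(0, n - 1))
  expect_equal(kl_divergence(rep(1 / n, n), onehot), log(n),
               tolerance = 1e-6)

  set.seed(17)
  for (i in 1:25) {
    p <- runif(32); q <- runif(32)
    expect_gte(kl_divergence(p / sum(p), q / sum(q)), 0)
  }
  expect_error(kl_divergence(1:3 / 6, 1:4 / 10), "lengths differ")
})

test_that("ROI transforms expand, aspect-fit and invert exactly", {
  bb <- bounding_box(100, 50, 200, 250)  # 100 x 200 box
  tf <- roi_transform(bb, padding = 1.25, out_size = c(192, 256))
  # padded size 125 x 250; aspect 192/256 = 0.75 forces width to 187.5
  expect_equal(tf$forward[1, 1], 192 / 187.5, tolerance = 1e-12)
  center <- apply_roi_transform(tf, c(150, 150))
  expect_equal(as.numeric(center), c(96, 128), tolerance = 1e-9)

  set.seed(23)
  pts <- cbind(runif(100, -50, 700), runif(100, -50, 700))
  back <- apply_roi_transform(tf, apply_roi_transform(tf, pts),
                              inverse = TRUE)
  expect_equal(back, pts, tolerance = 1e-9)

  expect_error(bounding_box(10, 10, 10, 20), "degenerate")
})

test_that("the two-stage harness composes detector, crop and localizer", {
  spec <- fixture_spec(width = 160, height = 120,
                       keypoints = list(M1 = c(80, 30), L1 = c(50, 60),
                                        R1 = c(110, 60), M2 = c(80, 90)),
                       marker_radius = 4, seed = 6)
  img <- make_back_image(spec)

  # oracle detector + oracle localizer = identity composition
  out <- run_pipeline(img, oracle_detector(10),
                      oracle_localizer(img$keypoints))
  expect_equal(out$x, img$keypoints$x, tolerance = 1e-6)
  expect_equal(out$y, img$keypoints$y, tolerance = 1e-6)
  expect_true(all(out$visible))

  # a shrunken detector box pushes M2 out of the ROI: reported invisible
  small_box <- function(image) bounding_box(45, 25, 115, 55)
  out2 <- run_pipeline(img, small_box, oracle_localizer(img$keypoints),
                       padding = 1)
  expect_false(out2$visible[out2$label == "M2"])
  expect_true(out2$visible[out2$label == "M1"])

  # detector failure is distinct from localizer failure
  expect_error(run_pipeline(img, function(image) NULL,
                            oracle_localizer(img$keypoints)),
               class = "acukit_detector_error")
})

test_that("pipeline output is equivariant to integer translation", {
  base_kp <- keypoint_set(c("A", "B", "C"), c(40, 80, 60), c(30, 40, 70))
  mk <- function(dx, dy) {
    kp <- base_kp; kp$x <- kp$x + dx; kp$y <- kp$y + dy
    annotated_image(array(128, c(160, 200, 3)), kp)
  }
  run <- function(img) {
    run_pipeline(img, oracle_detector(15), oracle_localizer(img$keypoints))
  }
  a <- run(mk(0, 0)); b <- run(mk(17, -5))
  expect_equal(b$x - a$x, rep(17, 3), tolerance = 1e-9)
  expect_equal(b$y - a$y, rep(-5, 3), tolerance = 1e-9)
})

test_that("noisy mock localizers reach near-perfect recall at 2 px error", {
  spec <- fixture_spec(width = 320, height = 240,
                       keypoints = default_acupoint_layout(320, 240),
                       marker_radius = 4, seed = 8)
  img <- make_back_image(spec)
  reports <- lapply(1:40, function(i) {
    pred <- run_pipeline(img, oracle_detector(12),
                         noisy_localizer(img$keypoints, sigma = 2,
                                         seed = 300 + i))
    classify_hits(pred, img$keypoints)
  })
  rec <- kp_recall(reports)
  # Rayleigh tail: P(R < (10/1.3) px) at sigma 2 is ~ 99.94%
  p_hit <- 1 - exp(-(10 / 1.3)^2 / (2 * 2^2))
  expect_gte(rec, 99)
  expect_equal(rec, 100 * p_hit, tolerance = 0.01)
})
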