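make_toy <- function(seed = 1, w = 20, h = 20) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

test_that("extract_front finds unknown pixels bordering the known region", {
  rem <- matrix(FALSE, 8, 8)
  expect_equal(nrow(extract_front(rem)), 0)

  rem[4, 5] <- TRUE  # single pixel at x = 4, y = 3
  expect_equal(unname(extract_front(rem)), matrix(c(4L, 3L), 1))

  rem <- matrix(FALSE, 9, 9)
  rem[4:6, 4:6] <- TRUE
  front <- extract_front(rem)
  # oracle: enumerate 4-neighbors of each block pixel
  expected <- NULL
  for (r in 4:6) for (c in 4:6) {
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    if (any(!rem[nb])) expected <- rbind(expected, c(c - 1, r - 1))
  }
  expect_equal(nrow(front), 8)  # center pixel has no known neighbor
  expect_setequal(paste(front[, 1], front[, 2]),
                  paste(expected[, 1], expected[, 2]))
})

test_that("priority terms clamp confidence and handle flat images", {
  img <- array(128, c(12, 12, 3))  # constant color: zero gradient
  mask <- matrix(FALSE, 12, 12)
  mask[5:8, 5:8] <- TRUE
  st <- fill_state(mask, patch_radius = 2)
  front <- extract_front(mask)
  p <- c(front[1, 1], front[1, 2])

  pt <- priority_terms(img, st, p, inpaint_params(mode = "improved"))
  expect_equal(pt$D, 0)
  expect_gte(pt$C, 0.2)
  expect_equal(pt$P, exp(pt$C + pt$D))

  # force the clamp branch: zero confidence everywhere
  st$confidence[] <- 0
  pt0 <- priority_terms(img, st, p, inpaint_params(mode = "improved"))
  expect_equal(pt0$C, 0.2)
  expect_equal(pt0$P, exp(0.2), tolerance = 1e-12)

  ptb <- priority_terms(img, st, p, inpaint_params(mode = "baseline"))
  expect_equal(ptb$P, ptb$C * ptb$D)

  expect_error(priority_terms(img, st, c(0, 0), inpaint_params()),
               "not on the fill front")
})

test_that("improved priority stays positive where the product form dies", {
  img <- array(128, c(12, 12, 3))
  mask <- matrix(FALSE, 12, 12)
  mask[5:8, 5:8] <- TRUE
  st <- fill_state(mask, patch_radius = 2)
  st$confidence[] <- 0  # fully decayed confidence, flat image: C*D = 0
  front <- extract_front(mask)
  p <- c(front[1, 1], front[1, 2])
  base <- priority_terms(img, st, p, inpaint_params(mode = "baseline"))
  imp <- priority_terms(img, st, p, inpaint_params(mode = "improved"))
  expect_equal(base$P, 0)
  expect_gt(imp$P, 0)
})

test_that("elliptic_region matches brute-force moments and partitions", {
  mask <- matrix(FALSE, 40, 40)
  d <- sqrt(outer((0:39 - 20)^2, (0:39 - 20)^2, `+`))
  mask[d <= 6] <- TRUE
  reg <- elliptic_region(mask, margin = 2.5)

  # oracle: second moments of the rasterized disc, computed directly
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  cv <- cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs) + diag(2) / 12
  expected_axes <- 2 * sqrt(sort(eigen(cv)$values, decreasing = TRUE))
  expect_equal(unname(reg$axes), expected_axes, tolerance = 1e-9)
  expect_equal(unname(reg$center), c(20, 20), tolerance = 1e-9)

  # quadrants partition the band exactly
  q <- reg$quadrants
  expect_false(any((q[[1]] & q[[2]]) | (q[[1]] & q[[3]]) | (q[[1]] & q[[4]]) |
                     (q[[2]] & q[[3]]) | (q[[2]] & q[[4]]) | (q[[3]] & q[[4]])))
  expect_identical(q[[1]] | q[[2]] | q[[3]] | q[[4]], reg$band)
  expect_false(any(reg$band & mask))

  # margin 1: the fitted ellipse barely exceeds the disc itself
  reg1 <- elliptic_region(mask, margin = 1)
  expect_lt(sum(reg1$band), sum(mask) * 0.25)

  expect_error(elliptic_region(matrix(FALSE, 5, 5)), "empty")
})

test_that("match_patch returns the exact duplicate and honors tie-breaks", {
  img <- array(100, c(20, 20, 3))
  # paint a distinctive texture around p and duplicate it at q*
  tex <- array(seq_len(5 * 5 * 3), c(5, 5, 3))
  img[2:6, 2:6, ] <- tex      # known context of p = (3, 3) (0-based)
  img[12:16, 12:16, ] <- tex  # exact duplicate centered at (13, 13)
  rem <- matrix(FALSE, 20, 20)
  rem[3:5, 3:5] <- TRUE  # unknown core; p's known ring remains
  st <- fill_state(rem, patch_radius = 2)
  q <- match_patch(img, st, c(3, 3))
  expect_equal(attr(q, "ssd"), 0)
  expect_equal(as.numeric(q), c(13, 13))

  # two zero-SSD candidates: uniform image, nearest candidate wins
  img2 <- array(7, c(15, 15, 3))
  rem2 <- matrix(FALSE, 15, 15)
  rem2[7:9, 7:9] <- TRUE
  st2 <- fill_state(rem2, patch_radius = 1)
  q2 <- match_patch(img2, st2, c(7, 7))
  b2 <- brute_match(img2, rem2, c(7, 7), 1)
  expect_equal(as.numeric(q2), b2)
})

test_that("match_patch agrees with the exhaustive SSD oracle", {
  img <- make_toy(seed = 4)
  rem <- matrix(FALSE, 20, 20)
  rem[9:12, 8:11] <- TRUE
  st <- fill_state(rem, patch_radius = 1)
  front <- extract_front(rem)
  for (i in seq_len(nrow(front))) {
    p <- c(front[i, 1], front[i, 2])
    expect_equal(as.numeric(match_patch(img, st, p)),
                 brute_match(img, rem, p, 1),
                 info = paste("front pixel", i))
  }
})

test_that("inpaint_image fills everything, touches nothing else, terminates", {
  spec <- tiny_spec(seed = 9, n = 2)
  img <- make_back_image(spec)

  empty <- inpaint_image(img$pixels, matrix(FALSE, 64, 64))
  expect_identical(empty$image, img$pixels)
  expect_equal(nrow(empty$log), 0)

  res <- inpaint_image(img$pixels, img$mask, inpaint_params())
  expect_equal(sum(res$log$filled), sum(img$mask))
  expect_true(all(res$image >= 0 & res$image <= 255))
  for (ch in 1:3) {
    expect_identical(res$image[, , ch][!img$mask],
                     img$pixels[, , ch][!img$mask])
  }
  expect_lte(nrow(res$log), sum(img$mask))
  expect_true(all(res$log$filled >= 1))  # |Omega| strictly decreases
  expect_equal(res$markers, 2)

  expect_error(inpaint_image(img$pixels, matrix(TRUE, 64, 64)),
               "entire image")
})

test_that("unbounded elliptic search reproduces the whole-image fill order", {
  spec <- tiny_spec(seed = 13, n = 2)
  img <- make_back_image(spec)
  # band = whole image: huge margin, no candidate floor
  local_run <- inpaint_image(img$pixels, img$mask,
                             inpaint_params(mode = "improved",
                                            ellipse_margin = 1e6,
                                            min_candidates = 0))
  # whole-image search with the same exponential priority: force fallback
  global_run <- inpaint_image(img$pixels, img$mask,
                              inpaint_params(mode = "improved",
                                             min_candidates = .Machine$integer.max))
  expect_identical(local_run$log[c("x", "y")], global_run$log[c("x", "y")])
  expect_identical(local_run$image, global_run$image)
})
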