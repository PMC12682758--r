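#' Three-channel peak signal-to-noise ratio
#'
#' Per-channel mean squared error over the evaluated region, turned into
#' decibels. Two variants are exposed: `"paper_sum"` sums the three
#' per-channel log terms
#' (`10 * sum_c log10(255^2 / MSE_c)`), which runs about three times a
#' conventional PSNR; `"channel_mean"` (the default for reporting) divides
#' that sum by 3. A zero MSE in any channel yields the `+Inf` sentinel
#' rather than an error.
#'
#' @param a,b H x W x 3 arrays in \[0,255\], same shape.
#' @param mask optional H x W logical region over which to evaluate.
#' @param variant `"channel_mean"` or `"paper_sum"`.
#' @return PSNR in decibels (possibly `Inf`), with attribute
#'   `per_channel` holding the three channel terms.
#' @examples
#' a <- array(100, c(8, 8, 3)); b <- a + 1
#' psnr3(a, b)  # 10*log10(255^2) ~ 48.13 dB
#' @export
psnr3 <- function(a, b, mask = NULL,
                  variant = c("channel_mean", "paper_sum")) {
  variant <- match.arg(variant)
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  stopifnot(length(dim(a)) == 3, dim(a)[3] == 3)
  sel <- if (is.null(mask)) TRUE else as.vector(mask)
  terms <- vapply(1:3, function(ch) {
    da <- as.vector(a[, , ch])[sel] - as.vector(b[, , ch])[sel]
    mse <- mean(da^2)
    if (mse == 0) Inf else 10 * log10(255^2 / mse)
  }, numeric(1))
  total <- sum(terms)
  out <- if (variant == "paper_sum") total else total / 3
  attr(out, "per_channel") <- terms
  out
}

#' Global structural similarity index
#'
#' Single-window SSIM: per-channel global means, variances and covariance
#' over the region, combined as
#' `(2*mu_x*mu_y + c1) * (2*sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1) * (sigma_x^2 + sigma_y^2 + c2))`
#' with `c1 = (k1*L)^2`, `c2 = (k2*L)^2`, then averaged over channels.
#' Equal inputs give exactly 1; the constants stabilize flat regions.
#'
#' @param a,b H x W x 3 arrays in \[0,255\], same shape.
#' @param mask optional H x W logical region.
#' @param L dynamic range of the samples (255 for 8-bit).
#' @param k1,k2 stabilization constants (0.01 and 0.03).
#' @return SSIM in \[-1, 1\], with attribute `per_channel`.
#' @export
ssim_global <- function(a, b, mask = NULL, L = 255, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  stopifnot(length(dim(a)) == 3, dim(a)[3] == 3)
  sel <- if (is.null(mask)) TRUE else as.vector(mask)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- vapply(1:3, function(ch) {
    x <- as.vector(a[, , ch])[sel]; y <- as.vector(b[, , ch])[sel]
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    vxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + c1) * (2 * vxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }, numeric(1))
  out <- mean(vals)
  attr(out, "per_channel") <- vals
  out
}

#' Average processing time of a de-labeling run
#'
#' The efficiency figure is defined per acupoint (seconds per marker) but
#' printed as a mean of whole-image times; both conventions are exposed.
#' `"per_image"` is `mean(T_i)` exactly as written; `"per_marker"`
#' (the default, honoring the stated unit) is `mean(T_i / count_i)`.
#'
#' @param times per-image processing times in seconds (> 0).
#' @param counts per-image marker counts (>= 1); ignored by `per_image`.
#' @param convention `"per_marker"` or `"per_image"`.
#' @return seconds (per image or per marker).
#' @export
per_marker_time <- function(times, counts = NULL,
                            convention = c("per_marker", "per_image")) {
  convention <- match.arg(convention)
  if (length(times) == 0) stop("no records")
  stopifnot(all(times > 0))
  if (convention == "per_image") return(mean(times))
  if (is.null(counts)) stop("per_marker convention needs marker counts")
  stopifnot(length(counts) == length(times), all(counts >= 1))
  mean(times / counts)
}

#' Average efficiency improvement between two algorithms
#'
#' Pairwise-matched per-image times of a baseline (`T_ic`) and an improved
#' (`T_ip`) algorithm. `"mean_of_ratios"` is
#' `mean(1 - T_ip / T_ic) * 100` exactly as the per-image definition
#' averages; `"ratio_of_means"` is `(1 - mean(T_p) / mean(T_c)) * 100`.
#'
#' @param baseline_times,improved_times equal-length positive vectors,
#'   matched by image.
#' @param convention `"mean_of_ratios"` or `"ratio_of_means"`.
#' @return percent improvement.
#' @examples
#' efficiency_gain(c(10, 20), c(5, 5))                    # 62.5
#' efficiency_gain(c(10, 20), c(5, 5), "ratio_of_means")  # 66.7
#' @export
efficiency_gain <- function(baseline_times, improved_times,
                            convention = c("mean_of_ratios",
                                           "ratio_of_means")) {
  convention <- match.arg(convention)
  stopifnot(length(baseline_times) == length(improved_times),
            length(baseline_times) > 0)
  if (any(baseline_times == 0)) stop("baseline time of 0 is not allowed")
  if (convention == "mean_of_ratios") {
    mean(1 - improved_times / baseline_times) * 100
  } else {
    (1 - mean(improved_times) / mean(baseline_times)) * 100
  }
}

#' Restoration-quality report for an image pair
#'
#' Convenience wrapper bundling [psnr3()] and [ssim_global()].
#'
#' @param a,b H x W x 3 arrays in \[0,255\].
#' @param mask optional H x W logical region.
#' @return list with `psnr`, `psnr_paper_sum`, `ssim` and per-channel terms.
#' @export
quality_report <- function(a, b, mask = NULL) {
  p <- psnr3(a, b, mask)
  ps <- psnr3(a, b, mask, variant = "paper_sum")
  s <- ssim_global(a, b, mask)
  list(psnr = as.numeric(p), psnr_per_channel = attr(p, "per_channel"),
       psnr_paper_sum = as.numeric(ps),
       ssim = as.numeric(s), ssim_per_channel = attr(s, "per_channel"))
}
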