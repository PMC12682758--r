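#' Configuration for acupoint accuracy evaluation
#'
#' @param scale_k millimeters per pixel at the working distance
#'   (default 1.3, the platform's measured conversion at 640 x 480).
#' @param tolerance_px pixel tolerance subtracted from each pair's distance
#'   before averaging (clamped at 0). Default 0: the plain mean pixel
#'   error, the only reading consistent with the reported error and recall
#'   figures. The literal printed constant is reachable via
#'   `tolerance_px = 10 * scale_k`.
#' @param region_diameter_mm diameter of the effective acupoint region
#'   (default 10 mm); two equal circular regions overlap iff their centers
#'   are closer than this.
#' @return list of class `eval_config`.
#' @export
eval_config <- function(scale_k = 1.3, tolerance_px = 0,
                        region_diameter_mm = 10) {
  stopifnot(scale_k > 0, tolerance_px >= 0, region_diameter_mm > 0)
  structure(list(scale_k = scale_k, tolerance_px = tolerance_px,
                 region_diameter_mm = region_diameter_mm),
            class = "eval_config")
}

#' Average pixel error of predicted acupoints in one image
#'
#' Mean over label-matched visible pairs of
#' `max(||P_j - G_j||_2 - tolerance_px, 0)`.
#'
#' @param pred,truth [keypoint_set()]s; pairs are matched by label and
#'   must both be visible.
#' @param cfg an [eval_config()].
#' @return mean pixel error (pixels).
#' @export
ape_image <- function(pred, truth, cfg = eval_config()) {
  m <- match_keypoints(pred, truth)
  if (length(m$pred) == 0) stop("no matched visible keypoint pairs")
  pred <- as_keypoint_set(pred); truth <- as_keypoint_set(truth)
  d <- sqrt((pred$x[m$pred] - truth$x[m$truth])^2 +
              (pred$y[m$pred] - truth$y[m$truth])^2)
  mean(pmax(d - cfg$tolerance_px, 0))
}

#' Convert a pixel error to millimeters
#'
#' Multiplies by the pixel-to-millimeter scale factor
#' (`APDE = k * APE`, k = 1.3 mm/px by default).
#'
#' @param ape_px mean pixel error (>= 0).
#' @param cfg an [eval_config()].
#' @return error in millimeters.
#' @examples
#' apde(4.45)  # 5.785 mm
#' @export
apde <- function(ape_px, cfg = eval_config()) {
  stopifnot(all(ape_px >= 0))
  ape_px * cfg$scale_k
}

#' Summarize per-image pixel errors over a test sample
#'
#' @param per_image_ape non-empty vector of per-image mean pixel errors.
#' @param cfg an [eval_config()].
#' @return list with `mAPE` (pixels), `mAPDE` (millimeters) and `variance`
#'   (sample variance of the per-image values, divisor n-1; 0 for a single
#'   image).
#' @export
summarize_ape <- function(per_image_ape, cfg = eval_config()) {
  if (length(per_image_ape) == 0) stop("no per-image errors given")
  m <- mean(per_image_ape)
  v <- if (length(per_image_ape) > 1) stats::var(per_image_ape) else 0
  list(mAPE = m, mAPDE = apde(m, cfg), variance = v)
}

#' Classify predictions against effective acupoint regions
#'
#' Each ground-truth acupoint carries a circular effective region of
#' `region_diameter_mm`; the prediction carries an equal region. The two
#' overlap — an effective recognition (TP) — iff the center distance is
#' strictly below the diameter; otherwise the point is a miss (FN) with
#' error `d` equal to the center distance in millimeters. A missing or
#' invisible prediction is an FN with `d = NA`.
#'
#' @param pred,truth [keypoint_set()]s matched by label; every visible
#'   truth point is classified.
#' @param cfg an [eval_config()].
#' @return data frame of class `hit_report` with columns `label`,
#'   `distance_mm`, `verdict` (`"TP"`/`"FN"`), `d`.
#' @export
classify_hits <- function(pred, truth, cfg = eval_config()) {
  pred <- as_keypoint_set(pred); truth <- as_keypoint_set(truth)
  tv <- truth[truth$visible, , drop = FALSE]
  ip <- match(tv$label, pred$label)
  has_pred <- !is.na(ip) & pred$visible[ifelse(is.na(ip), 1L, ip)]
  dist_mm <- rep(NA_real_, nrow(tv))
  if (any(has_pred)) {
    j <- ip[has_pred]
    dist_mm[has_pred] <- sqrt((pred$x[j] - tv$x[has_pred])^2 +
                                (pred$y[j] - tv$y[has_pred])^2) * cfg$scale_k
  }
  tp <- has_pred & dist_mm < cfg$region_diameter_mm
  tp[is.na(tp)] <- FALSE
  out <- data.frame(label = tv$label, distance_mm = dist_mm,
                    verdict = ifelse(tp, "TP", "FN"),
                    d = ifelse(tp, NA_real_, dist_mm),
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_report", "data.frame")
  out
}

#' Mean per-image recall of acupoint recognition
#'
#' `100 * mean_i(TP_i / (TP_i + FN_i))` over images — the mean of
#' per-image recalls, not the pooled ratio.
#'
#' @param reports list of `hit_report`s (one per image), or a single
#'   report.
#' @return recall in percent.
#' @export
kp_recall <- function(reports) {
  if (inherits(reports, "hit_report")) reports <- list(reports)
  if (length(reports) == 0) stop("no hit reports given")
  per_image <- vapply(reports, function(rep) {
    if (nrow(rep) == 0) stop("a hit report with zero keypoints was given")
    mean(rep$verdict == "TP")
  }, numeric(1))
  mean(per_image) * 100
}
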