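#' Parameters for exemplar-based marker removal
#'
#' Two modes are provided. `"baseline"` is the classical exemplar-based
#' scheme: fill priority is the product of a confidence term C(p) and a
#' data (isophote) term D(p), and the best source patch is searched over
#' the whole image. `"improved"` replaces the product by the exponential
#' sum `exp(C + D)` with C floored at `k_thr` — keeping the priority
#' informative when propagated confidence decays toward zero — and
#' restricts the patch search to an elliptic band around each marker
#' (falling back to the whole image when the band holds fewer than
#' `min_candidates` candidates).
#'
#' @param patch_radius half-width of the square fill patch; patches are
#'   `(2*patch_radius+1)^2` pixels (default 4, i.e. 9 x 9).
#' @param k_thr confidence floor in (0,1) applied in improved mode
#'   (default 0.2).
#' @param alpha normalization of the data term; 255 for 8-bit images.
#' @param mode `"improved"` or `"baseline"`.
#' @param ellipse_margin scale factor applied to each marker's equivalent
#'   ellipse to form the local search band (default 2.5).
#' @param min_candidates minimum number of candidate source patches the
#'   band must contain before the whole-image fallback engages (default 50).
#' @param seed reserved; the fill itself is deterministic.
#' @return list of class `inpaint_params`.
#' @export
inpaint_params <- function(patch_radius = 4, k_thr = 0.2, alpha = 255,
                           mode = c("improved", "baseline"),
                           ellipse_margin = 2.5, min_candidates = 50,
                           seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(patch_radius >= 1, k_thr > 0, k_thr < 1, alpha > 0,
            ellipse_margin >= 1, min_candidates >= 0)
  structure(list(patch_radius = as.integer(patch_radius), k_thr = k_thr,
                 alpha = alpha, mode = mode,
                 ellipse_margin = ellipse_margin,
                 min_candidates = as.integer(min_candidates),
                 seed = as.integer(seed)),
            class = "inpaint_params")
}

#' Initialize fill-state bookkeeping for inpainting
#'
#' Confidence starts at 1 on the source region and 0 on the region to fill;
#' the remaining map marks pixels still unknown and shrinks monotonically
#' as filling proceeds.
#'
#' @param mask H x W logical matrix: TRUE on the region to fill.
#' @param patch_radius patch half-width carried with the state.
#' @return environment of class `fill_state` with `confidence`, `remaining`,
#'   `patch_radius`.
#' @export
fill_state <- function(mask, patch_radius = 4) {
  mask <- as.matrix(mask); storage.mode(mask) <- "logical"
  st <- new.env(parent = emptyenv())
  st$confidence <- 1 - mask * 1
  st$remaining <- mask
  st$patch_radius <- as.integer(patch_radius)
  class(st) <- "fill_state"
  st
}

#' Extract the fill front of a region
#'
#' The fill front is the set of unknown pixels having at least one
#' 4-neighbor in the known region. Pixels beyond the image border do not
#' count as known.
#'
#' @param remaining H x W logical matrix of the region still to fill.
#' @return integer matrix with columns `x`, `y` (0-based), one row per
#'   front pixel, in row-major (y, then x) order.
#' @export
extract_front <- function(remaining) {
  h <- nrow(remaining); w <- ncol(remaining)
  known <- !remaining
  nb <- matrix(FALSE, h, w)
  if (h > 1) {
    nb[-1, ] <- nb[-1, ] | known[-h, ]
    nb[-h, ] <- nb[-h, ] | known[-1, ]
  }
  if (w > 1) {
    nb[, -1] <- nb[, -1] | known[, -w]
    nb[, -w] <- nb[, -w] | known[, -1]
  }
  idx <- which(remaining & nb, arr.ind = TRUE)
  m <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  m[order(m[, "y"], m[, "x"]), , drop = FALSE]
}

# Masked central-difference gradients of a luminance matrix: NA-aware,
# one-sided at borders/unknowns, 0 where no known neighbor pair exists.
masked_gradients <- function(lum, known) {
  h <- nrow(lum); w <- ncol(lum)
  L <- lum; L[!known] <- NA
  left <- cbind(NA, L[, -w, drop = FALSE])
  right <- cbind(L[, -1, drop = FALSE], NA)
  up <- rbind(NA, L[-h, , drop = FALSE])
  down <- rbind(L[-1, , drop = FALSE], NA)
  gx <- (right - left) / 2
  one_sided_x <- ifelse(!is.na(right) & !is.na(L), right - L,
                        ifelse(!is.na(left) & !is.na(L), L - left, 0))
  gx[is.na(gx)] <- one_sided_x[is.na(gx)]
  gy <- (down - up) / 2
  one_sided_y <- ifelse(!is.na(down) & !is.na(L), down - L,
                        ifelse(!is.na(up) & !is.na(L), L - up, 0))
  gy[is.na(gy)] <- one_sided_y[is.na(gy)]
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  list(gx = gx, gy = gy)
}

# Unit normal of the fill-front at each pixel: gradient of a 5x5
# box-smoothed indicator of the remaining region.
front_normals <- function(remaining) {
  sm <- box_sum(remaining * 1, 2) / box_area(nrow(remaining),
                                             ncol(remaining), 2)
  h <- nrow(sm); w <- ncol(sm)
  nx <- matrix(0, h, w); ny <- matrix(0, h, w)
  nx[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  ny[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  list(nx = nx, ny = ny)
}

#' Priority terms for a fill-front pixel
#'
#' Computes the confidence term C(p) (mean confidence of the known pixels
#' in the patch around p, divided by the in-image patch area; floored at
#' `k_thr` in improved mode), the data term
#' `D(p) = |isophote . n_p| / alpha` — the isophote being the 90-degree
#' rotation of the strongest known luminance gradient within the patch,
#' and `n_p` the unit normal of the fill front — and the resulting
#' priority: `exp(C + D)` in improved mode, `C * D` in baseline mode.
#'
#' @param image H x W x 3 array in \[0,255\].
#' @param state a [fill_state()].
#' @param p length-2 `c(x, y)` 0-based pixel on the current fill front.
#' @param params an [inpaint_params()].
#' @return list with elements `C`, `D`, `P`.
#' @export
priority_terms <- function(image, state, p, params = inpaint_params()) {
  front <- extract_front(state$remaining)
  if (!any(front[, "x"] == p[1] & front[, "y"] == p[2])) {
    stop("p = (", p[1], ", ", p[2], ") is not on the fill front")
  }
  pr <- priority_all(image, state, rbind(p), params)
  list(C = pr$C[1], D = pr$D[1], P = pr$P[1])
}

# Vectorized priority computation over front pixels (matrix with x, y
# columns). Shared by priority_terms() and the fill loop.
priority_all <- function(image, state, front, params) {
  known <- !state$remaining
  r <- state$patch_radius
  h <- nrow(known); w <- ncol(known)
  conf_sum <- box_sum(state$confidence * known, r)
  area <- box_area(h, w, r)
  lum <- luminance(image)
  g <- masked_gradients(lum, known)
  gmag2 <- g$gx^2 + g$gy^2
  nrm <- front_normals(state$remaining)
  n <- nrow(front)
  C <- numeric(n); D <- numeric(n)
  for (i in seq_len(n)) {
    x <- front[i, 1]; y <- front[i, 2]
    C[i] <- conf_sum[y + 1, x + 1] / area[y + 1, x + 1]
    rows <- max(1, y + 1 - r):min(h, y + 1 + r)
    cols <- max(1, x + 1 - r):min(w, x + 1 + r)
    sub <- gmag2[rows, cols] * known[rows, cols]
    j <- which.max(sub)
    if (length(j) && sub[j] > 0) {
      ry <- rows[(j - 1) %% length(rows) + 1]
      rx <- cols[(j - 1) %/% length(rows) + 1]
      iso_x <- -g$gy[ry, rx]; iso_y <- g$gx[ry, rx]  # 90-deg rotation
      nx <- nrm$nx[y + 1, x + 1]; ny <- nrm$ny[y + 1, x + 1]
      nlen <- sqrt(nx^2 + ny^2)
      if (nlen > 0) {
        D[i] <- abs(iso_x * nx / nlen + iso_y * ny / nlen) / params$alpha
      }
    }
  }
  if (params$mode == "improved") {
    C <- pmax(C, params$k_thr)
    P <- exp(C + D)
  } else {
    P <- C * D
  }
  list(C = C, D = D, P = P)
}

#' Equivalent ellipse and quadrant search band of a marker region
#'
#' Fits an ellipse to a connected marker component from its centroid and
#' second moments (half-axes = twice the eigen standard deviations, so a
#' disc of radius r maps to half-axes ~ r), scales it by `margin` to form
#' the local search band (band = scaled ellipse minus the component), and
#' splits the band into four quadrants along the ellipse's symmetry axes.
#'
#' @param component H x W logical matrix, one non-empty connected region.
#' @param margin scale factor >= 1 applied to the half-axes.
#' @return list of class `ellipse_region`: `center` (0-based x, y), `axes`
#'   (half-lengths), `orientation` (radians), `band` (logical matrix),
#'   `quadrants` (list of four logical matrices partitioning the band).
#' @export
elliptic_region <- function(component, margin = 2.5) {
  component <- as.matrix(component); storage.mode(component) <- "logical"
  idx <- which(component, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("component is empty")
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  cx <- mean(xs); cy <- mean(ys)
  cov <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  if (length(xs) == 1 || any(!is.finite(cov))) cov <- diag(2) * 0.25
  # regularize so 1-pixel-thin components still give a 2-D ellipse
  cov <- cov + diag(2) * 1 / 12
  eg <- eigen(cov, symmetric = TRUE)
  axes <- 2 * sqrt(pmax(eg$values, 1e-12))
  orientation <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  h <- nrow(component); w <- ncol(component)
  X <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cx
  Y <- matrix(seq_len(h) - 1, h, w) - cy
  u <- X * eg$vectors[1, 1] + Y * eg$vectors[2, 1]
  v <- X * eg$vectors[1, 2] + Y * eg$vectors[2, 2]
  a <- axes[1] * margin; b <- axes[2] * margin
  inside <- (u / a)^2 + (v / b)^2 <= 1
  band <- inside & !component
  quadrants <- list(band & u >= 0 & v >= 0,
                    band & u >= 0 & v < 0,
                    band & u < 0 & v < 0,
                    band & u < 0 & v >= 0)
  structure(list(center = c(cx, cy), axes = axes,
                 orientation = orientation, band = band,
                 quadrants = quadrants, basis = eg$vectors),
            class = "ellipse_region")
}

# Valid candidate patch centers: full patch inside the image and free of
# remaining (unknown) pixels. Returns a logical matrix.
valid_candidates <- function(remaining, r) {
  h <- nrow(remaining); w <- ncol(remaining)
  cnt <- box_sum(remaining * 1, r)
  ok <- cnt == 0
  if (r > 0) {
    ok[c(seq_len(min(r, h)), seq_len(min(r, h)) + h - min(r, h)), ] <- FALSE
    ok[, c(seq_len(min(r, w)), seq_len(min(r, w)) + w - min(r, w))] <- FALSE
  }
  ok
}

#' Find the best-matching source patch for a front pixel
#'
#' Minimizes the sum of squared RGB differences over the already-known
#' pixels of the patch at `p`, among candidate patch centers that lie fully
#' inside the image with no unknown pixel. Ties are broken by smaller
#' Euclidean distance to `p`, then row-major order. When `region` is given,
#' the search is restricted to its band; if the band holds no valid
#' candidate the function signals fallback by returning `NULL` (callers
#' widen to the whole image).
#'
#' @param image H x W x 3 array in \[0,255\].
#' @param state a [fill_state()].
#' @param p length-2 `c(x, y)` 0-based front pixel.
#' @param region optional [elliptic_region()] restricting the search.
#' @param min_candidates if the band yields fewer valid candidates than
#'   this, `NULL` is returned to request whole-image fallback.
#' @return length-2 `c(x, y)` center of the best source patch, with
#'   attribute `ssd`; or `NULL` when the restricted search starves.
#' @export
match_patch <- function(image, state, p, region = NULL, min_candidates = 0) {
  r <- state$patch_radius
  ok <- valid_candidates(state$remaining, r)
  if (!is.null(region)) ok <- ok & region$band
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0 || (!is.null(region) && nrow(idx) < min_candidates)) {
    if (!is.null(region)) return(NULL)
    stop("no valid candidate patch exists in the image")
  }
  cand_r <- idx[, 1] - 1L; cand_c <- idx[, 2] - 1L
  ssd <- ssd_scan(image, !state$remaining, p[2], p[1], r, cand_r, cand_c)
  best <- which(ssd == min(ssd))
  if (length(best) > 1) {
    d2 <- (cand_c[best] - p[1])^2 + (cand_r[best] - p[2])^2
    best <- best[d2 == min(d2)]
    if (length(best) > 1) {
      ord <- order(cand_r[best], cand_c[best])
      best <- best[ord[1]]
    }
  }
  best <- best[1]
  structure(c(cand_c[best], cand_r[best]), ssd = ssd[best])
}

#' Remove marked regions from an image by exemplar-based filling
#'
#' Runs the fill loop: extract the fill front, score priorities, copy the
#' best-matching source patch into the unknown pixels of the top-priority
#' patch, propagate confidence, and repeat until nothing remains. In
#' improved mode the patch search is restricted per marker component to
#' its elliptic band (whole-image fallback when candidates are scarce).
#'
#' @param image H x W x 3 numeric array in \[0,255\].
#' @param mask H x W logical matrix of pixels to fill (must not cover the
#'   whole image).
#' @param params an [inpaint_params()].
#' @param max_iter iteration cap; default one iteration per masked pixel.
#' @return list of class `inpaint_result`: `image` (restored array), `log`
#'   (data frame with per-iteration `filled` counts and chosen positions),
#'   `time` (elapsed seconds), `markers` (connected components in `mask`).
#' @examples
#' spec <- fixture_spec(width = 64, height = 64,
#'   keypoints = list(M1 = c(32, 32)), marker_radius = 4, seed = 2)
#' img <- make_back_image(spec)
#' res <- inpaint_image(img$pixels, img$mask,
#'                      inpaint_params(mode = "improved"))
#' sum(res$log$filled) == sum(img$mask)
#' @export
inpaint_image <- function(image, mask, params = inpaint_params(),
                          max_iter = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  mask <- as.matrix(mask); storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(image)[1:2])) {
    stop("mask shape must equal image shape")
  }
  if (all(mask)) stop("mask covers the entire image: no source region")
  t0 <- proc.time()[["elapsed"]]
  comp <- label_components(mask)
  n_markers <- max(comp)
  st <- fill_state(mask, params$patch_radius)
  regions <- NULL
  if (params$mode == "improved" && n_markers > 0) {
    regions <- lapply(seq_len(n_markers), function(k) {
      elliptic_region(comp == k, params$ellipse_margin)
    })
  }
  omega0 <- sum(mask)
  if (is.null(max_iter)) max_iter <- omega0 + 1L
  out <- image
  log_it <- integer(0); log_x <- integer(0); log_y <- integer(0)
  log_filled <- integer(0)
  iter <- 0L
  r <- params$patch_radius
  h <- nrow(mask); w <- ncol(mask)
  while (any(st$remaining)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("inpainting did not converge: ", sum(st$remaining),
           " pixels remaining after ", max_iter, " iterations")
    }
    front <- extract_front(st$remaining)
    pr <- priority_all(out, st, front, params)
    best <- which.max(pr$P)
    p <- c(front[best, 1], front[best, 2])
    q <- NULL
    if (!is.null(regions)) {
      k <- comp[p[2] + 1, p[1] + 1]
      if (k > 0) {
        q <- match_patch(out, st, p, regions[[k]], params$min_candidates)
      }
    }
    if (is.null(q)) q <- match_patch(out, st, p)
    rows <- max(1, p[2] + 1 - r):min(h, p[2] + 1 + r)
    cols <- max(1, p[1] + 1 - r):min(w, p[1] + 1 + r)
    sub_rem <- st$remaining[rows, cols]
    fill_idx <- which(sub_rem, arr.ind = TRUE)
    src_rows <- q[2] + 1 + (rows - (p[2] + 1))
    src_cols <- q[1] + 1 + (cols - (p[1] + 1))
    for (ch in 1:3) {
      dst <- out[rows, cols, ch]
      src <- out[src_rows, src_cols, ch]
      dst[sub_rem] <- src[sub_rem]
      out[rows, cols, ch] <- dst
    }
    cp <- min(pr$C[best], 1)
    conf_sub <- st$confidence[rows, cols]
    conf_sub[sub_rem] <- cp
    st$confidence[rows, cols] <- conf_sub
    rem_sub <- st$remaining[rows, cols]
    rem_sub[sub_rem] <- FALSE
    st$remaining[rows, cols] <- rem_sub
    log_it <- c(log_it, iter)
    log_x <- c(log_x, p[1]); log_y <- c(log_y, p[2])
    log_filled <- c(log_filled, nrow(fill_idx))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(
    image = out,
    log = data.frame(iteration = log_it, x = log_x, y = log_y,
                     filled = log_filled),
    time = elapsed,
    markers = n_markers
  ), class = "inpaint_result")
}

#' @export
print.inpaint_result <- function(x, ...) {
  cat(sprintf(
    "<inpaint_result: %d iterations, %d px filled, %d markers, %.2f s>\n",
    nrow(x$log), sum(x$log$filled), x$markers, x$time))
  invisible(x)
}

#' Build a marker mask from annotated points
#'
#' When no explicit mask exists, discs of a given radius around each
#' visible annotated point define the region to remove.
#'
#' @param keypoints a [keypoint_set()].
#' @param width,height image size in pixels.
#' @param radius disc radius in pixels.
#' @return H x W logical matrix.
#' @export
mask_from_keypoints <- function(keypoints, width, height, radius) {
  keypoints <- as_keypoint_set(keypoints)
  mask <- matrix(FALSE, height, width)
  for (i in which(keypoints$visible)) {
    p <- c(keypoints$x[i], keypoints$y[i])
    x0 <- max(0, floor(p[1] - radius)); x1 <- min(width - 1, ceiling(p[1] + radius))
    y0 <- max(0, floor(p[2] - radius)); y1 <- min(height - 1, ceiling(p[2] + radius))
    if (x0 > x1 || y0 > y1) next
    gx <- x0:x1; gy <- y0:y1
    d <- sqrt(outer((gy - p[2])^2, (gx - p[1])^2, `+`))
    mask[gy + 1, gx + 1] <- mask[gy + 1, gx + 1] | (d <= radius)
  }
  mask
}
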