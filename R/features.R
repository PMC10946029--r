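# The four contour features: closure, signed squashed curvature, symmetry
# and orientation. Closure, curvature and orientation are gated by the
# neuron's CRF extent and are therefore defined per (neuron, stimulus);
# symmetry is a global, neuron-independent property of the stimulus.

#' Curvature computation parameters
#'
#' @param a squashing constant (dimensionless, raw curvature in 1/pixels).
#'   At `a = 20` the sigmoid reaches ~0.46 for a 20-pixel fitted radius.
#' @param window_scales window side lengths as fractions of the stimulus
#'   size. Default `(1, 3/4, 2/4, 1/4, 1/10)`.
#' @param slide_step window slide step in pixels.
#' @param min_points minimum contour points (within window and CRF extent)
#'   required to fit a circle.
#' @param error_percentile fits with an RMS radial residual above this
#'   percentile of the (stimulus, neuron) error distribution are dropped.
#' @param max_circles keep at most this many lowest-error fits.
#' @return list of parameters.
#' @export
curvature_params <- function(a = 20, window_scales = c(1, 3/4, 2/4, 1/4, 1/10),
                             slide_step = 10, min_points = 10,
                             error_percentile = 80, max_circles = 20) {
  stopifnot(a > 0, all(window_scales > 0), all(window_scales <= 1),
            slide_step >= 1, min_points >= 3,
            error_percentile > 0, error_percentile <= 100, max_circles >= 1)
  list(a = a, window_scales = window_scales, slide_step = slide_step,
       min_points = min_points, error_percentile = error_percentile,
       max_circles = max_circles)
}

#' Sigmoidal curvature squashing
#'
#' `c' = 2 / (1 + exp(-a * c)) - 1`: a monotone odd map from raw curvature
#' (inverse fitted radius, 1/pixels) to `(-1, 1)`, flattening the heavy
#' upper tail that small fitted radii would otherwise produce.
#'
#' @param c_raw raw curvature values (1/pixels).
#' @param a squashing constant.
#' @return squashed values in `(-1, 1)`.
#' @export
squash_curvature <- function(c_raw, a = 20) {
  2 / (1 + exp(-a * c_raw)) - 1
}

# internal: accept a single-contour tibble or an x/y data frame
as_points <- function(contour) {
  if (!is.null(contour$stimulus_id) &&
      length(unique(contour$stimulus_id)) != 1)
    cc_abort("expected a single contour")
  list(x = as.numeric(contour$x), y = as.numeric(contour$y))
}

#' Closure of a contour around the CRF centre
#'
#' `n_rays` radial lines are cast from the CRF centre at equal angular
#' intervals; closure is the fraction of rays whose first intersection
#' with the contour polyline lies inside the CRF extent. A contour the
#' rays never reach inside the extent scores 0 (the definition needs no
#' minimum amount of contour, so closure is never missing).
#'
#' @param contour single-contour tibble (columns `x`, `y`).
#' @param crf `"crf"` object.
#' @param n_rays number of radial lines.
#' @return closure in `[0, 1]`.
#' @export
compute_closure <- function(contour, crf, n_rays = 100) {
  p <- as_points(contour)
  hits <- closure_hits_cpp(p$x, p$y, crf$center[1], crf$center[2],
                           as.integer(n_rays),
                           crf$center[1], crf$center[2],
                           crf$sd[1], crf$sd[2])
  mean(hits)
}

#' Local signed squashed curvatures of a contour within a CRF
#'
#' Square windows at several scales are slid across the stimulus; within
#' each window the contour points that also fall in the CRF extent are
#' fitted by an algebraic least-squares circle when at least
#' `min_points` of them are available. Fits with an RMS radial residual
#' above the `error_percentile` of this (stimulus, neuron) pair's error
#' distribution are dropped and at most `max_circles` lowest-error fits
#' are kept. Each surviving fit contributes `sign * c'` where `c'` is the
#' squashed inverse radius and the sign is +1 when the fitted circle's
#' centre lies on the figure side of the contour (convex with respect to
#' the figure) and -1 otherwise.
#'
#' @param contour single-contour tibble (needs `figure_side`, `patch_size`).
#' @param crf `"crf"` object.
#' @param params see [curvature_params()].
#' @return tibble of surviving local fits (possibly 0 rows) with columns
#'   `scale`, `wx`, `wy`, `n`, `radius`, `fit_error`, `c_raw`, `sign`,
#'   `value`.
#' @export
compute_local_curvatures <- function(contour, crf, params = curvature_params()) {
  p <- as_points(contour)
  patch <- contour$patch_size[1] %||% 69
  fs <- contour$figure_side[1] %||% 1L
  cand <- curvature_scan_cpp(p$x, p$y, crf$center[1], crf$center[2],
                             crf$sd[1], crf$sd[2], patch,
                             params$window_scales, params$slide_step,
                             as.integer(params$min_points))
  err <- cand$fit_error
  if (!length(err)) return(curvature_empty())
  keep <- which(err <= quantile(err, params$error_percentile / 100,
                                names = FALSE))
  if (length(keep) > params$max_circles)
    keep <- keep[order(err[keep])[seq_len(params$max_circles)]]
  imid <- cand$imid[keep]
  qx <- cand$qx[keep]; qy <- cand$qy[keep]
  coll <- cand$collinear[keep] > 0
  n <- length(p$x)
  i0 <- pmax(1L, imid - 1L); i1 <- pmin(n, imid + 1L)
  tx <- p$x[i1] - p$x[i0]; ty <- p$y[i1] - p$y[i0]
  # figure-pointing normal: fs * (ty, -tx)
  s <- (qx - p$x[imid]) * (fs * ty) + (qy - p$y[imid]) * (-fs * tx)
  sgn <- ifelse(coll, NA_integer_, ifelse(s >= 0, 1L, -1L))
  radius <- cand$radius[keep]
  c_raw <- ifelse(is.finite(radius), 1 / radius, 0)
  value <- ifelse(is.na(sgn), 0, sgn) * squash_curvature(c_raw, params$a)
  tibble::tibble(scale = cand$scale[keep], wx = cand$wx[keep],
                 wy = cand$wy[keep], n = cand$n[keep], radius = radius,
                 fit_error = err[keep], c_raw = c_raw,
                 sign = sgn, value = value)
}

curvature_empty <- function() {
  tibble::tibble(scale = numeric(), wx = numeric(), wy = numeric(),
                 n = integer(), radius = numeric(), fit_error = numeric(),
                 c_raw = numeric(), sign = integer(), value = numeric())
}

#' Raw mirror symmetry of a contour
#'
#' Contour points are blurred into a Gaussian density map (SD
#' `blur_sd` pixels); for each of `n_axes` candidate axes through the
#' stimulus centre (equal 7.5 degree steps for the default 24) the map is
#' folded about the axis and the overlap with itself computed. The
#' largest overlap across axes is the raw score; [normalize_symmetry()]
#' rescales raw scores to `[0, 1]` across a stimulus set. Overlap is the
#' sum of the pixel-wise minimum of the map and its reflection
#' (`method = "min"`); the dot product is available as an alternative.
#'
#' @param contour single-contour tibble.
#' @param blur_sd Gaussian blur SD in pixels.
#' @param n_axes number of candidate mirror axes in `[0, 180)`.
#' @param method overlap statistic, `"min"` or `"dot"`.
#' @return raw symmetry score (not yet normalized); attribute
#'   `"best_axis"` records the maximizing axis angle in degrees.
#' @export
compute_symmetry <- function(contour, blur_sd = 2, n_axes = 24,
                             method = c("min", "dot")) {
  method <- match.arg(method)
  p <- as_points(contour)
  patch <- contour$patch_size[1] %||% 69
  angles <- seq(0, 180, length.out = n_axes + 1)[seq_len(n_axes)]
  ov <- symmetry_overlaps_cpp(p$x, p$y, as.integer(patch), blur_sd,
                              angles, use_min = (method == "min"))
  structure(max(ov), best_axis = angles[which.max(ov)])
}

#' Min-max normalize raw symmetry scores across a stimulus set
#'
#' @param raw numeric vector of raw scores (one per stimulus).
#' @return values in `[0, 1]`; an all-equal input maps to all zeros.
#' @export
normalize_symmetry <- function(raw) {
  if (length(raw) < 2) cc_abort("need >= 2 stimuli to normalize symmetry")
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(0, length(raw)))
  (raw - rng[1]) / diff(rng)
}

# internal: resample a polyline at (approximately) unit arc-length spacing
resample_polyline <- function(x, y, spacing = 1) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  if (L < spacing) return(list(x = x, y = y))
  s <- seq(0, L, by = spacing)
  list(x = stats::approx(cl, x, xout = s, ties = "ordered")$y,
       y = stats::approx(cl, y, xout = s, ties = "ordered")$y)
}

#' Mean orientation of a contour within a CRF
#'
#' Local orientations are measured from all point pairs separated by
#' `pair_sep` pixels along the (unit-spacing resampled) contour with both
#' points inside the CRF extent, and combined by the axial circular mean
#' (angles doubled, unit vectors averaged, resultant halved), which is
#' immune to the 0/180 wrap. The naive arithmetic mean of the raw angles
#' is available via `method = "naive"`.
#'
#' @param contour single-contour tibble.
#' @param crf `"crf"` object.
#' @param pair_sep separation along the contour in pixels.
#' @param method `"axial"` (default) or `"naive"`.
#' @return orientation in degrees `[0, 180)`, or `NA` when no pair
#'   qualifies. Attributes: `"resultant"` (axial mean resultant length in
#'   `[0, 1]`; small values flag a degenerate, near-isotropic set) and
#'   `"n_pairs"`.
#' @export
compute_orientation <- function(contour, crf, pair_sep = 5,
                                method = c("axial", "naive")) {
  method <- match.arg(method)
  p <- as_points(contour)
  rp <- resample_polyline(p$x, p$y, spacing = 1)
  n <- length(rp$x)
  if (n <= pair_sep) return(structure(NA_real_, resultant = NA_real_, n_pairs = 0L))
  i <- seq_len(n - pair_sep)
  j <- i + pair_sep
  ok <- in_extent(crf, rp$x[i], rp$y[i]) & in_extent(crf, rp$x[j], rp$y[j])
  if (!any(ok)) return(structure(NA_real_, resultant = NA_real_, n_pairs = 0L))
  dx <- rp$x[j][ok] - rp$x[i][ok]
  dy <- rp$y[j][ok] - rp$y[i][ok]
  th <- atan2(dy, dx) %% pi                     # axial angle in [0, pi)
  if (method == "naive") {
    val <- mean(th) * 180 / pi
    return(structure(val %% 180, resultant = NA_real_, n_pairs = sum(ok)))
  }
  C <- mean(cos(2 * th)); S <- mean(sin(2 * th))
  res <- sqrt(C^2 + S^2)
  val <- (atan2(S, C) / 2) %% pi * 180 / pi
  structure(val, resultant = res, n_pairs = sum(ok))
}

#' Compute the full feature table for neurons x stimuli
#'
#' Applies the four feature computations to every combination of a
#' contour and a neuron's CRF. Symmetry is computed once per stimulus and
#' min-max normalized across the set. Gated features that cannot be
#' estimated (insufficient contour inside the CRF extent) are `NA` /
#' empty, never defaulted.
#'
#' @param contours contour tibble (many stimuli).
#' @param crfs named list of `"crf"` objects; names are neuron ids.
#' @param params [curvature_params()].
#' @param n_rays,pair_sep,blur_sd,n_axes feature parameters.
#' @return tibble with one row per (neuron, stimulus): `closure`,
#'   `curvatures` (list column of signed squashed local curvatures),
#'   `curvature_mean`, `symmetry` (normalized), `orientation`.
#' @export
compute_features <- function(contours, crfs, params = curvature_params(),
                             n_rays = 100, pair_sep = 5,
                             blur_sd = 2, n_axes = 24) {
  stopifnot(is.list(crfs), !is.null(names(crfs)))
  split_c <- split(contours, contours$stimulus_id)
  stim_ids <- names(split_c)
  sym_raw <- vapply(split_c, function(g) as.numeric(compute_symmetry(
    g, blur_sd = blur_sd, n_axes = n_axes)), numeric(1))
  sym <- normalize_symmetry(sym_raw)
  nn <- length(crfs); ns <- length(stim_ids)
  neuron_id <- rep(names(crfs), times = ns)
  stimulus_id <- rep(stim_ids, each = nn)
  closure <- ori <- cmean <- numeric(nn * ns)
  curv_list <- vector("list", nn * ns)
  k <- 0L
  for (si in seq_along(stim_ids)) {
    g <- split_c[[si]]
    for (nid in names(crfs)) {
      crf <- crfs[[nid]]
      curv <- compute_local_curvatures(g, crf, params)
      k <- k + 1L
      closure[k] <- compute_closure(g, crf, n_rays = n_rays)
      curv_list[[k]] <- curv$value
      cmean[k] <- if (nrow(curv)) mean(curv$value) else NA_real_
      ori[k] <- as.numeric(compute_orientation(g, crf, pair_sep = pair_sep))
    }
  }
  tibble::tibble(neuron_id = neuron_id, stimulus_id = stimulus_id,
                 closure = closure, curvatures = curv_list,
                 curvature_mean = cmean,
                 symmetry = rep(sym, each = nn), orientation = ori)
}
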