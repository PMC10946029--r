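# Classical receptive field (CRF) model: an axis-aligned 2-D Gaussian
# fitted to a grid of grating-patch responses. The CRF "extent" is the
# open 2-SD ellipse; all CRF-gated feature computations use it.

#' Construct a CRF model
#'
#' @param center_x,center_y Gaussian centre, stimulus coordinates.
#' @param sd_x,sd_y Gaussian SDs (same units, both > 0).
#' @param amplitude,baseline response amplitude and baseline (spikes).
#' @return object of class `"crf"`.
#' @export
crf_model <- function(center_x, center_y, sd_x, sd_y,
                      amplitude = 1, baseline = 0) {
  if (sd_x <= 0 || sd_y <= 0) cc_abort("CRF SDs must be positive")
  structure(
    list(center = c(x = center_x, y = center_y),
         sd = c(x = sd_x, y = sd_y),
         amplitude = amplitude, baseline = max(0, baseline),
         rss = NA_real_, fittable = TRUE),
    class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("<crf> center (%.2f, %.2f), sd (%.2f, %.2f), amp %.2f, base %.2f\n",
              x$center[1], x$center[2], x$sd[1], x$sd[2],
              x$amplitude, x$baseline))
  invisible(x)
}

crf_predict <- function(par, x, y) {
  par[["base"]] + par[["amp"]] *
    exp(-((x - par[["cx"]])^2 / (2 * par[["sx"]]^2) +
            (y - par[["cy"]])^2 / (2 * par[["sy"]]^2)))
}

#' Fit a 2-D Gaussian CRF to a grating-patch response grid
#'
#' Least-squares fit of `baseline + amplitude * exp(-dx^2/(2 sx^2) -
#' dy^2/(2 sy^2))` to mean responses on a position grid (5 x 5 in the
#' standard protocol). The baseline is fitted jointly and clipped at zero.
#' A grid whose responses are all equal carries no positional information
#' and is flagged unfittable (`$fittable = FALSE`), which excludes the
#' neuron downstream.
#'
#' @param grid tibble with columns `x`, `y` (grid positions) and
#'   `response` (mean spike count per position, >= 0).
#' @return `"crf"` object with residual sum of squares in `$rss`.
#' @export
fit_crf <- function(grid) {
  stopifnot(all(c("x", "y", "response") %in% names(grid)))
  if (nrow(grid) < 4) cc_abort("need >= 4 grid positions")
  if (any(grid$response < 0)) cc_abort("grid responses must be >= 0")
  r <- grid$response
  if (diff(range(r)) == 0) {
    out <- crf_model(mean(grid$x), mean(grid$y), 1, 1, 0, r[1])
    out$fittable <- FALSE
    return(out)
  }
  rngx <- diff(range(grid$x)); rngy <- diff(range(grid$y))
  rngx <- max(rngx, 1e-6); rngy <- max(rngy, 1e-6)
  base0 <- min(r)
  w <- r - base0
  cx0 <- sum(grid$x * w) / sum(w)
  cy0 <- sum(grid$y * w) / sum(w)
  sx0 <- sqrt(max(sum((grid$x - cx0)^2 * w) / sum(w), (0.05 * rngx)^2))
  sy0 <- sqrt(max(sum((grid$y - cy0)^2 * w) / sum(w), (0.05 * rngy)^2))
  # second start: at the peak cell, narrow
  i <- which.max(r)
  starts <- list(
    c(cx = cx0, cy = cy0, sx = sx0, sy = sy0, amp = max(w), base = base0),
    c(cx = grid$x[i], cy = grid$y[i], sx = 0.3 * rngx, sy = 0.3 * rngy,
      amp = max(w), base = base0))
  lower <- c(min(grid$x) - rngx, min(grid$y) - rngy,
             0.02 * rngx, 0.02 * rngy, 1e-9, 0)
  upper <- c(max(grid$x) + rngx, max(grid$y) + rngy,
             3 * rngx, 3 * rngy, 10 * max(r) + 1, max(r))
  obj <- function(p) {
    names(p) <- c("cx", "cy", "sx", "sy", "amp", "base")
    sum((crf_predict(p, grid$x, grid$y) - r)^2)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(unname(p0), lower), upper), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    out <- crf_model(cx0, cy0, sx0, sy0, max(w), base0)
    out$fittable <- FALSE
    return(out)
  }
  p <- setNames(best$par, c("cx", "cy", "sx", "sy", "amp", "base"))
  out <- crf_model(p[["cx"]], p[["cy"]], p[["sx"]], p[["sy"]],
                   p[["amp"]], max(0, p[["base"]]))
  out$rss <- best$value
  out
}

#' CRF extent membership
#'
#' A point is inside the extent iff
#' `((x - cx)/sx)^2 + ((y - cy)/sy)^2 < 4`, the open axis-aligned 2-SD
#' ellipse (the boundary itself is outside).
#'
#' @param crf `"crf"` object.
#' @param x,y coordinates (vectorized).
#' @return logical vector.
#' @export
in_extent <- function(crf, x, y) {
  ((x - crf$center[1]) / crf$sd[1])^2 +
    ((y - crf$center[2]) / crf$sd[2])^2 < 4
}

#' @method tidy crf
#' @export
tidy.crf <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "sd_x", "sd_y", "amplitude", "baseline"),
    estimate = c(x$center, x$sd, x$amplitude, x$baseline))
}

#' @method glance crf
#' @export
glance.crf <- function(x, ...) {
  tibble::tibble(rss = x$rss, fittable = x$fittable)
}
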