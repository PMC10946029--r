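# Fixtures and independent oracles used across the test files. Oracles
# are deliberately naive re-implementations (nested loops, direct
# geometry) kept separate from the package's code paths.

ctr_default <- 34

# closed circle contour (first point repeated to close the polyline)
circle_contour <- function(r, cx = ctr_default, cy = ctr_default,
                           n = max(32, ceiling(2 * pi * r)),
                           figure = c("inside", "outside"), id = "circ") {
  figure <- match.arg(figure)
  t <- seq(0, 2 * pi, length.out = n + 1)
  x <- cx + r * cos(t); y <- cy + r * sin(t)
  probe <- if (figure == "inside") c(cx, cy) else c(cx + 1.5 * r, cy)
  contour_tbl(id, x, y,
              figure_side = figure_side_from_probe(x, y, probe))
}

# circular arc centred (in angle) on the point nearest (cx, cy)
arc_contour <- function(r, span_deg, cx = ctr_default, cy = ctr_default,
                        alpha = 0, id = "arc") {
  t0 <- alpha + pi
  tt <- seq(t0 - span_deg * pi / 360, t0 + span_deg * pi / 360,
            length.out = max(16, ceiling(span_deg * pi / 180 * r)))
  ccx <- cx + r * cos(alpha); ccy <- cy + r * sin(alpha)
  x <- ccx + r * cos(tt); y <- ccy + r * sin(tt)
  contour_tbl(id, x, y, figure_side = 1L)
}

# arc at constant radius AROUND the centre (polar angles 0..span)
polar_arc <- function(r, span_deg, cx = ctr_default, cy = ctr_default,
                      id = "parc") {
  tt <- seq(0, span_deg * pi / 180,
            length.out = max(16, ceiling(span_deg * pi / 180 * r)))
  contour_tbl(id, cx + r * cos(tt), cy + r * sin(tt), figure_side = 1L)
}

line_contour <- function(angle_deg = 0, len = 60, cx = ctr_default,
                         cy = ctr_default, id = "line") {
  th <- angle_deg * pi / 180
  s <- seq(-len / 2, len / 2, by = 1)
  contour_tbl(id, cx + s * cos(th), cy + s * sin(th), figure_side = 1L)
}

# --- oracles -------------------------------------------------------------

# brute-force ray casting: fraction of rays whose first polyline
# intersection lies strictly inside the 2SD ellipse
closure_oracle <- function(contour, crf, n_rays = 100) {
  x <- contour$x; y <- contour$y
  ox <- crf$center[1]; oy <- crf$center[2]
  hits <- 0
  for (k in 0:(n_rays - 1)) {
    th <- 2 * pi * k / n_rays
    dx <- cos(th); dy <- sin(th)
    tbest <- Inf
    for (i in seq_len(length(x) - 1)) {
      ex <- x[i + 1] - x[i]; ey <- y[i + 1] - y[i]
      rx <- x[i] - ox; ry <- y[i] - oy
      den <- dx * ey - dy * ex
      if (abs(den) < 1e-12) next
      tt <- (rx * ey - ry * ex) / den
      u <- (rx * dy - ry * dx) / den
      if (tt > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9 && tt < tbest) tbest <- tt
    }
    if (is.finite(tbest)) {
      px <- ox + tbest * dx; py <- oy + tbest * dy
      if (((px - ox) / crf$sd[1])^2 + ((py - oy) / crf$sd[2])^2 < 4)
        hits <- hits + 1
    }
  }
  hits / n_rays
}

# dense-grid density map built with plain R (outer products), matching
# the truncated-Gaussian stamping of the package renderer
density_oracle <- function(x, y, size = 69, sd = 2, trunc = 4) {
  D <- matrix(0, size, size)
  g <- 0:(size - 1)
  rad <- ceiling(trunc * sd)
  for (i in seq_along(x)) {
    wx <- exp(-(g - x[i])^2 / (2 * sd^2))
    wy <- exp(-(g - y[i])^2 / (2 * sd^2))
    wx[g < floor(x[i]) - rad | g > ceiling(x[i]) + rad] <- 0
    wy[g < floor(y[i]) - rad | g > ceiling(y[i]) + rad] <- 0
    D <- D + outer(wy, wx)
  }
  D
}

# brute-force fold overlap over the same 24 axes
symmetry_oracle <- function(contour, blur_sd = 2, n_axes = 24) {
  size <- contour$patch_size[1]
  ctr <- (size - 1) / 2
  D <- density_oracle(contour$x, contour$y, size, blur_sd)
  best <- -Inf
  for (ang in seq(0, 180 - 180 / n_axes, by = 180 / n_axes)) {
    th <- ang * pi / 180
    ux <- cos(th); uy <- sin(th)
    vx <- contour$x - ctr; vy <- contour$y - ctr
    dd <- vx * ux + vy * uy
    rx <- ctr + 2 * dd * ux - vx
    ry <- ctr + 2 * dd * uy - vy
    Dr <- density_oracle(rx, ry, size, blur_sd)
    best <- max(best, sum(pmin(D, Dr)))
  }
  best
}

# doubled-angle axial mean of a set of orientation angles (degrees)
axial_mean_oracle <- function(deg) {
  th <- deg * pi / 180
  (atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2) %% pi * 180 / pi
}

# nested-loop plug-in MI on a joint count table (bits)
mi_oracle <- function(joint) {
  n <- sum(joint)
  px <- unname(rowSums(joint)) / n
  py <- unname(colSums(joint)) / n
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j] / n
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  mi
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# queue flood fill from the patch corner; blocked = within 0.5 px of the
# contour polyline. Returns counts of exterior / blocked / interior.
flood_fill_oracle <- function(contour) {
  size <- contour$patch_size[1]
  blocked <- matrix(FALSE, size, size)
  for (gx in 0:(size - 1)) for (gy in 0:(size - 1)) {
    d2 <- min((contour$x - gx)^2 + (contour$y - gy)^2)
    if (d2 <= 0.25) blocked[gy + 1, gx + 1] <- TRUE
  }
  visited <- matrix(FALSE, size, size)
  queue <- matrix(c(1L, 1L), ncol = 2)
  visited[1, 1] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
      r <- cur[1] + d[1]; cc <- cur[2] + d[2]
      if (r < 1 || r > size || cc < 1 || cc > size) next
      if (visited[r, cc] || blocked[r, cc]) next
      visited[r, cc] <- TRUE
      queue <- rbind(queue, c(r, cc))
    }
  }
  list(exterior = sum(visited), blocked = sum(blocked),
       interior = size^2 - sum(visited) - sum(blocked))
}

# cached synthetic stimulus set shared by the generator-dependent tests
.cc_cache <- new.env(parent = emptyenv())
cached_stimuli <- function() {
  if (is.null(.cc_cache$gen))
    .cc_cache$gen <- generate_contours(stimulus_set_config(seed = 1))
  .cc_cache$gen
}

# memoized population analyses shared between the end-to-end tests: one
# stimulus set (seed 1), populations varying by seed
cached_population <- function(seed, n_neurons = 72) {
  key <- paste0("pop", seed)
  if (is.null(.cc_cache[[key]])) {
    st <- simulate_study(stimuli = cached_stimuli(), n_neurons = n_neurons,
                         trials = 10, seed = seed)
    fx <- expand_features(st$features, st$presentations)
    fx$curvature <- NULL
    tun <- estimate_tuning(fx, st$responses, seed = seed)
    .cc_cache[[key]] <- list(study = st, features_pres = fx, tuning = tun)
  }
  .cc_cache[[key]]
}
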