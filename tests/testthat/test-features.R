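# Feature engine: closure, curvature, symmetry, orientation.

test_that("closure of canonical shapes behaves as defined", {
  crf <- crf_model(34, 34, 10, 10)     # extent radius 20
  circ <- circle_contour(10)
  expect_equal(compute_closure(circ, crf), 1.0)
  # contour entirely outside the extent -> no collision inside, closure 0
  far <- contour_tbl("far", c(34, 60, 60), c(34.4, 34.4, 60))
  crf_small <- crf_model(10, 10, 2, 2)
  expect_equal(compute_closure(far, crf_small), 0)
  # half circle around the CRF centre: about half of the rays collide
  half <- polar_arc(10, 180)
  v <- compute_closure(half, crf)
  expect_gte(v, 0.49); expect_lte(v, 0.52)
  expect_equal(v, closure_oracle(half, crf))
})

test_that("closure matches brute-force ray casting on parametric arcs", {
  crf <- crf_model(34, 34, 12, 12)
  set.seed(21)
  for (span in c(60, 140, 220, 330)) {
    a <- arc_contour(runif(1, 5, 18), span, alpha = runif(1, 0, 2 * pi))
    expect_equal(compute_closure(a, crf), closure_oracle(a, crf),
                 tolerance = 0.02)
  }
})

test_that("closure is invariant to point reversal and refinement", {
  crf <- crf_model(34, 34, 10, 10)
  a <- arc_contour(12, 200)
  v <- compute_closure(a, crf)
  rev_a <- a; rev_a$x <- rev(a$x); rev_a$y <- rev(a$y)
  expect_equal(compute_closure(rev_a, crf), v)
  # insert collinear midpoints between consecutive points
  n <- nrow(a)
  fine <- contour_tbl("fine",
                      as.vector(rbind(a$x[-n], (a$x[-n] + a$x[-1]) / 2)),
                      as.vector(rbind(a$y[-n], (a$y[-n] + a$y[-1]) / 2)))
  expect_equal(compute_closure(fine, crf), v, tolerance = 0.011)
})

test_that("closure grows monotonically with angular coverage of an arc", {
  crf <- crf_model(34, 34, 10, 10)
  spans <- seq(40, 360, by = 40)
  vals <- vapply(spans, function(s) {
    compute_closure(polar_arc(10, s), crf)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("curvature of an exact circle matches the analytic value and sign", {
  crf <- crf_model(34, 34, 12, 12)
  circ_in <- circle_contour(20, figure = "inside")
  cv <- compute_local_curvatures(circ_in, crf)
  expect_gt(nrow(cv), 0)
  expect_equal(cv$radius, rep(20, nrow(cv)), tolerance = 1e-6)
  expect_equal(cv$value, rep(2 / (1 + exp(-1)) - 1, nrow(cv)),
               tolerance = 1e-3)
  expect_true(all(cv$sign == 1))
  circ_out <- circle_contour(20, figure = "outside")
  cv2 <- compute_local_curvatures(circ_out, crf)
  expect_equal(cv2$value, -cv$value, tolerance = 1e-9)
})

test_that("straight contours have near-zero signed curvature", {
  crf <- crf_model(34, 34, 12, 12)
  cv <- compute_local_curvatures(line_contour(30), crf)
  expect_gt(nrow(cv), 0)
  expect_true(all(abs(cv$value) <= 0.01))
})

test_that("flipping the figure side flips signed curvature only", {
  crf <- crf_model(34, 34, 12, 12)
  set.seed(31)
  a <- arc_contour(15, 250, alpha = 1)
  b <- a; b$figure_side <- -b$figure_side
  cva <- compute_local_curvatures(a, crf)
  cvb <- compute_local_curvatures(b, crf)
  expect_equal(cvb$value, -cva$value)
  expect_equal(cvb$radius, cva$radius)
})

test_that("the squashing function follows its printed form", {
  expect_equal(squash_curvature(0), 0)
  set.seed(4)
  cc <- rnorm(20, 0, 0.1)
  expect_equal(squash_curvature(-cc), -squash_curvature(cc))
  expect_equal(squash_curvature(0.05, a = 20), 2 / (1 + exp(-1)) - 1)
  expect_true(all(abs(squash_curvature(rnorm(50, 0, 1))) <= 1))
  expect_true(all(abs(squash_curvature(runif(50, -0.2, 0.2))) < 1))
})

test_that("symmetry of a mirror-symmetric set attains the self-overlap bound", {
  # V shape symmetric about the vertical axis through the centre
  s <- seq(1, 20, by = 1)
  x <- c(34 - rev(s) * 0.6, 34, 34 + s * 0.6)
  y <- c(34 - rev(s), 33.2, 34 - s)
  ct <- contour_tbl("v", x, y)
  raw <- compute_symmetry(ct)
  D <- density_oracle(ct$x, ct$y)
  expect_lte(as.numeric(raw), sum(D) + 1e-8)
  expect_equal(as.numeric(raw), sum(D), tolerance = 0.02)
  expect_equal(attr(raw, "best_axis"), 90)
})

test_that("symmetry equals the brute-force 24-axis maximum", {
  set.seed(41)
  for (i in 1:3) {
    x <- runif(20, 14, 54); y <- runif(20, 14, 54)
    x[1] <- 34; y[1] <- 34
    ct <- contour_tbl("r", x, y)
    expect_equal(as.numeric(compute_symmetry(ct)), symmetry_oracle(ct),
                 tolerance = 1e-6)
  }
})

test_that("symmetry raw score is invariant under reflection about a tested axis", {
  set.seed(43)
  x <- runif(15, 16, 52); y <- runif(15, 16, 52)
  ct <- contour_tbl("r", x, y)
  raw <- as.numeric(compute_symmetry(ct))
  for (ang in c(0, 45, 112.5)) {
    th <- ang * pi / 180; ux <- cos(th); uy <- sin(th)
    vx <- x - 34; vy <- y - 34
    dd <- vx * ux + vy * uy
    rct <- contour_tbl("m", 34 + 2 * dd * ux - vx, 34 + 2 * dd * uy - vy)
    # axis-aligned reflections map the pixel grid onto itself; oblique
    # ones only approximately
    expect_equal(as.numeric(compute_symmetry(rct)), raw,
                 tolerance = if (ang %% 45 == 0) 1e-9 else 1e-3)
  }
})

test_that("rotating a contour by the axis spacing preserves the maximum", {
  a <- arc_contour(14, 200)
  raw <- as.numeric(compute_symmetry(a))
  th <- 7.5 * pi / 180
  vx <- a$x - 34; vy <- a$y - 34
  rot <- contour_tbl("rot", 34 + vx * cos(th) - vy * sin(th),
                     34 + vx * sin(th) + vy * cos(th))
  expect_equal(as.numeric(compute_symmetry(rot)), raw,
               tolerance = 0.03 * raw)
})

test_that("min-max symmetry normalization is affine-invariant", {
  expect_equal(normalize_symmetry(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(6)
  raw <- runif(30, 5, 50)
  expect_equal(which.max(normalize_symmetry(raw)), which.max(raw))
  expect_equal(max(normalize_symmetry(raw)), 1)
  expect_equal(normalize_symmetry(3 * raw - 2), normalize_symmetry(raw))
  expect_equal(normalize_symmetry(rep(4, 5)), rep(0, 5))
})

test_that("orientation of axis-aligned segments is exact", {
  crf <- crf_model(34, 34, 12, 12)
  expect_equal(as.numeric(compute_orientation(line_contour(0), crf)), 0,
               tolerance = 1e-6)
  expect_equal(as.numeric(compute_orientation(line_contour(90), crf)), 90,
               tolerance = 1e-6)
})

test_that("orientation matches the doubled-angle oracle and flags degeneracy", {
  crf <- crf_model(34, 34, 12, 12)
  set.seed(51)
  for (ang in c(20, 75, 130, 169)) {
    v <- compute_orientation(line_contour(ang), crf)
    expect_equal(as.numeric(v), ang, tolerance = 0.5)
  }
  # X shape: 45 and 135 degree segments -> doubled angles cancel
  s <- seq(-15, 15, by = 1)
  x <- c(34 + s, 34 + s); y <- c(34 + s, 34 - s)
  ct <- contour_tbl("x", x, y)
  v <- compute_orientation(ct, crf)
  expect_lt(attr(v, "resultant"), 0.3)   # near-cancelling doubled angles
})

test_that("orientation is translation-invariant and rotation-equivariant", {
  crf <- crf_model(34, 34, 12, 12)
  base <- line_contour(25, len = 30)
  v0 <- as.numeric(compute_orientation(base, crf))
  shifted <- base; shifted$x <- base$x + 3; shifted$y <- base$y - 2
  expect_equal(as.numeric(compute_orientation(shifted, crf)), v0,
               tolerance = 0.5)
  th <- 40 * pi / 180
  vx <- base$x - 34; vy <- base$y - 34
  rot <- contour_tbl("r", 34 + vx * cos(th) - vy * sin(th),
                     34 + vx * sin(th) + vy * cos(th))
  expect_equal(as.numeric(compute_orientation(rot, crf)) %% 180,
               (v0 + 40) %% 180, tolerance = 0.5)
})

test_that("gated features are missing, not defaulted, for remote CRFs", {
  tiny <- crf_model(5, 5, 1.5, 1.5)    # extent far from the contour
  ct <- line_contour(0, len = 20)
  cv <- compute_local_curvatures(ct, tiny)
  expect_equal(nrow(cv), 0)
  expect_true(is.na(compute_orientation(ct, tiny)))
})

test_that("the feature driver assembles a complete neuron x stimulus table", {
  crfs <- list(nA = crf_model(34, 34, 12, 12), nB = crf_model(30, 38, 9, 11))
  cts <- dplyr::bind_rows(circle_contour(15, id = "c1"),
                          line_contour(30, id = "l1"),
                          arc_contour(12, 200, id = "a1"))
  ft <- compute_features(cts, crfs)
  expect_equal(nrow(ft), 6)
  expect_setequal(unique(ft$neuron_id), c("nA", "nB"))
  expect_true(all(ft$symmetry >= 0 & ft$symmetry <= 1))
  expect_true(all(ft$closure >= 0 & ft$closure <= 1))
  expect_true(all(vapply(ft$curvatures, function(v) all(abs(v) <= 1),
                         logical(1))))
  # symmetry is neuron-independent
  sym <- tidyr::pivot_wider(ft[, c("neuron_id", "stimulus_id", "symmetry")],
                            names_from = "neuron_id", values_from = "symmetry")
  expect_equal(sym$nA, sym$nB)
})
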