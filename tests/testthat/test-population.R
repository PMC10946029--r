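# Response matrix, nonmetric MDS, NS preference, axis grouping,
# moving-window profiles and axis regressions.

test_that("response matrix rows are max-normalized and scale-invariant", {
  resp <- tibble::tibble(
    neuron_id = rep(c("n1", "n2"), each = 2),
    stimulus_id = rep(c("a", "b"), 2),
    rate = c(2, 4, 1, 0.5), n_trials = 1)
  M <- build_response_matrix(resp)
  expect_equal(unname(M["n1", ]), c(0.5, 1))
  resp2 <- dplyr::mutate(resp, rate = ifelse(neuron_id == "n1", rate * 7, rate))
  expect_equal(build_response_matrix(resp2)["n1", ], M["n1", ])
})

test_that("kind filtering recomputes row maxima on the kept columns", {
  resp <- tibble::tibble(
    neuron_id = "n1", stimulus_id = c("a.nat", "a.sil", "b.nat", "b.sil"),
    rate = c(8, 2, 4, 1), n_trials = 1)
  kinds <- tibble::tibble(stimulus_id = resp$stimulus_id,
                          kind = rep(c("natural", "silhouette"), 2))
  Ms <- build_response_matrix(resp, kinds, kind_filter = "silhouette")
  expect_equal(ncol(Ms), 2)
  expect_equal(max(Ms["n1", ]), 1)           # maxima recomputed: 2 -> 1
  expect_equal(unname(Ms["n1", ]), c(1, 0.5))
})

test_that("all-zero neurons are dropped with a message", {
  resp <- tibble::tibble(
    neuron_id = rep(c("n1", "nz"), each = 2),
    stimulus_id = rep(c("a", "b"), 2),
    rate = c(1, 2, 0, 0), n_trials = 1)
  expect_message(M <- build_response_matrix(resp), "all-zero")
  expect_equal(rownames(M), "n1")
})

test_that("MDS recovers planted 2-D configurations almost exactly", {
  set.seed(71)
  X <- matrix(rnorm(100), 50, 2)
  rownames(X) <- sprintf("n%02d", 1:50)
  map <- run_mds(X, k = 2, seed = 2, n_restarts = 8)
  expect_lt(map$stress, 1e-3)
  al <- procrustes_align(map, X)
  expect_lt(attr(al, "procrustes_rmse"), 1e-3)
})

test_that("three equidistant neurons embed with near-zero stress", {
  M <- diag(3) * 2
  rownames(M) <- c("a", "b", "c")
  map <- run_mds(M, k = 2, seed = 1, n_restarts = 5)
  expect_lt(map$stress, 1e-6)
  d <- dist(as.matrix(map$coords[, -1]))
  expect_lt(diff(range(d)) / mean(d), 1e-3)  # equilateral
})

test_that("stress does not increase with embedding dimension", {
  set.seed(72)
  M <- matrix(runif(20 * 12), 20, 12)
  rownames(M) <- sprintf("n%02d", 1:20)
  sw <- mds_stress_by_dim(M, dims = 1:3, seed = 4, n_restarts = 10)
  expect_true(all(diff(sw$stress) <= 1e-6))
})

test_that("NS preference follows its definition", {
  expect_equal(ns_preference(3, 3), 0)
  expect_equal(ns_preference(5, 0), 1)
  expect_equal(ns_preference(0, 2), -1)
  expect_equal(ns_preference(3, 1), 0.5)
  expect_true(is.na(ns_preference(0, 0)))
  resp <- tibble::tibble(
    neuron_id = "n1", stimulus_id = c("a.nat", "a.sil"),
    rate = c(3, 1), n_trials = 1)
  kinds <- tibble::tibble(stimulus_id = c("a.nat", "a.sil"),
                          kind = c("natural", "silhouette"))
  expect_equal(ns_preference_table(resp, kinds)$ns_pref, 0.5)
})

test_that("equal-count grouping splits by quantile with stable ties", {
  g <- group_equal_count(c(10, 1, 5, 7, 2, 8, 3, 9, 4, 6), k = 5)
  expect_equal(as.integer(table(g)), rep(2L, 5))
  expect_equal(g[2], 1L)   # smallest value in first group
  expect_equal(g[1], 5L)   # largest value in last group
  # ties broken by input order
  gt <- group_equal_count(c(1, 1, 1, 1), k = 2)
  expect_equal(gt, c(1L, 1L, 2L, 2L))
  # sizes differ by at most one, matching a sort-based oracle
  set.seed(73)
  v <- rnorm(23)
  g2 <- group_equal_count(v, k = 5)
  expect_lte(diff(range(table(g2))), 1)
  expect_true(all(tapply(v, g2, max)[-5] <= tapply(v, g2, min)[-1] + 1e-12))
})

test_that("axis profiles slide 30-neuron windows and smooth on request", {
  coord <- seq_len(60)
  all_sig <- rep(TRUE, 60)
  pr <- axis_profile(coord, all_sig, window = 30, smooth = 5)
  expect_true(all(pr$value == 1))
  expect_equal(nrow(pr), 31)
  # step labels cross 0.5 near the boundary and are monotone
  step <- c(rep(FALSE, 30), rep(TRUE, 30))
  ps <- axis_profile(coord, step, window = 30, smooth = 1)
  expect_true(all(diff(ps$value) >= 0))
  expect_equal(ps$value[1], 0)
  expect_equal(ps$value[31], 1)
  expect_equal(ps$value[16], 0.5)
  # smoothing with span one returns the raw profile
  expect_equal(ps$value, ps$raw)
  expect_error(axis_profile(1:10, rep(1, 10), window = 30), "window")
})

test_that("axis regression matches the closed-form OLS solution", {
  set.seed(74)
  coord <- rnorm(40)
  vals <- 2 + 0.7 * coord + rnorm(40, 0, 0.3)
  out <- regress_axis(vals, coord)
  b <- cov(vals, coord) / var(coord)
  r <- cor(vals, coord)
  expect_equal(out$slope, b, tolerance = 1e-12)
  expect_equal(out$r, r, tolerance = 1e-12)
  expect_equal(out$r_squared, r^2, tolerance = 1e-12)
  expect_equal(out$p, cor.test(vals, coord)$p.value, tolerance = 1e-9)
  # exact linearity
  lin <- suppressWarnings(regress_axis(3 * coord - 1, coord))
  expect_equal(lin$r_squared, 1)
  # degenerate input flagged
  expect_true(regress_axis(rep(2, 10), rnorm(10))$degenerate)
})

test_that("axis orientation makes the covariate slope positive", {
  set.seed(75)
  X <- matrix(rnorm(80), 40, 2)
  rownames(X) <- sprintf("n%02d", 1:40)
  map <- run_mds(X, seed = 5, n_restarts = 5)
  v <- -tidy(map)$axis1 + rnorm(40, 0, 0.1)   # anti-aligned covariate
  map2 <- orient_map(map, list(v))
  expect_gt(regress_axis(v, tidy(map2)$axis1)$r, 0)
})

test_that("a planted tuning-breadth gradient organizes the primary axis", {
  # direct construction: neurons tuned to 0..3 features, clean rate
  # vectors, recover a positive significant trend of feature count on
  # the oriented primary axis in >= 90% of seeds
  hits <- vapply(1:20, function(sd) {
    set.seed(sd)
    ns <- 100
    fx <- cbind(runif(ns), runif(ns, -1, 1), runif(ns), runif(ns, 0, pi))
    n_tuned <- rep(0:3, each = 15)
    R <- t(vapply(n_tuned, function(k) {
      drive <- rep(1, ns)
      if (k > 0) for (f in sample(4, k)) {
        kern <- if (f %in% c(1, 3))
          exp(-(fx[, f] - runif(1, 0.2, 0.8))^2 / 0.25^2)
        else (1 + cos(fx[, f] - runif(1, -1, 1))) / 2
        rng <- range(kern)
        drive <- drive * (kern - rng[1]) / diff(rng)
      }
      0.5 + 10 * drive + rnorm(ns, 0, 0.4)
    }, numeric(ns)))
    rownames(R) <- sprintf("n%02d", seq_along(n_tuned))
    M <- pmax(R, 0) / apply(pmax(R, 0), 1, max)
    map <- orient_map(run_mds(M, seed = sd, n_restarts = 8), list(n_tuned))
    rr <- regress_axis(n_tuned, tidy(map)$axis1)
    rr$r > 0 && rr$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("feature-count and NS-gain gradients load on different axes", {
  set.seed(91)
  hits <- vapply(1:5, function(sd) {
    set.seed(100 + sd)
    ns <- 80
    fx <- runif(ns)                       # one contour feature per stimulus
    kind_nat <- rep(c(TRUE, FALSE), each = ns)   # natural + silhouette pair
    n_tuned <- rep(0:1, 30)
    ns_gain <- exp(seq(-0.8, 0.8, length.out = 60))[sample(60)]
    # one shared tuning kernel: the tuned/untuned contrast is a single
    # response-pattern direction, orthogonal to the planted NS gradient
    R <- t(vapply(seq_len(60), function(i) {
      kern <- if (n_tuned[i] > 0)
        exp(-(fx - 0.5)^2 / 0.2^2) else rep(1, ns)
      base <- 0.5 + 8 * (kern - min(kern)) / max(diff(range(kern)), 1e-9)
      lam <- c(base * ns_gain[i], base) + rnorm(2 * ns, 0, 0.3)
      pmax(lam, 0)
    }, numeric(2 * ns)))
    rownames(R) <- sprintf("n%02d", 1:60)
    M <- R / apply(R, 1, max)
    nsp <- ns_preference(rowMeans(R[, kind_nat]), rowMeans(R[, !kind_nat]))
    map <- orient_map(run_mds(M, seed = sd, n_restarts = 8),
                      list(n_tuned, nsp))
    co <- tidy(map)
    # MDS axes carry no intrinsic order: each gradient should dominate
    # a different axis, whichever that is
    ax_ns <- which.max(c(abs(regress_axis(nsp, co$axis1)$r),
                         abs(regress_axis(nsp, co$axis2)$r)))
    ax_nt <- which.max(c(abs(regress_axis(n_tuned, co$axis1)$r),
                         abs(regress_axis(n_tuned, co$axis2)$r)))
    ax_ns != ax_nt
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
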