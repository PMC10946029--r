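# Plug-in mutual information, binning rule, exclusions, permutation
# significance, MI-ratio profiles and group comparisons.

test_that("the binning rule follows the base-2 Sturges reading", {
  expect_equal(sturges_bins(2), 2)
  expect_equal(sturges_bins(210), ceiling(1 + log2(210)))
  expect_error(sturges_bins(1), "n >= 2")
  # crossing a power of two adds exactly one bin
  expect_equal(sturges_bins(257) - sturges_bins(129), 1)
  expect_equal(sturges_bins(128), sturges_bins(65))
  # literal base-10 variant stays available
  expect_equal(sturges_bins(50, base = "log10"), ceiling(1 + log10(100)))
})

test_that("MI equals the nested-loop oracle to 1e-12", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(30:300, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    nb <- sturges_bins(n)
    mi <- compute_mi(x, y)
    # rebuild the joint table exactly as binned
    bx <- findInterval(x, seq(min(x), max(x), length.out = nb + 1),
                       rightmost.closed = TRUE)
    by <- findInterval(y, seq(min(y), max(y), length.out = nb + 1),
                       rightmost.closed = TRUE)
    bx <- pmin(pmax(bx, 1), nb); by <- pmin(pmax(by, 1), nb)
    joint <- table(factor(bx, 1:nb), factor(by, 1:nb))
    expect_equal(as.numeric(mi), mi_oracle(unclass(joint)), tolerance = 1e-12)
  }
})

test_that("identical variables on two equal-mass bins carry one bit", {
  x <- rep(c(0, 1), each = 50)
  expect_equal(as.numeric(compute_mi(x, x, nbin = 2)), 1)
})

test_that("MI is non-negative, bounded by marginal entropies, and symmetric", {
  set.seed(62)
  for (i in 1:50) {
    n <- sample(40:200, 1)
    x <- rnorm(n); y <- rnorm(n) + sample(c(0, 1), 1) * x
    mi <- as.numeric(compute_mi(x, y))
    nb <- sturges_bins(n)
    px <- tabulate(pmin(pmax(findInterval(
      x, seq(min(x), max(x), length.out = nb + 1),
      rightmost.closed = TRUE), 1), nb), nb) / n
    py <- tabulate(pmin(pmax(findInterval(
      y, seq(min(y), max(y), length.out = nb + 1),
      rightmost.closed = TRUE), 1), nb), nb) / n
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy_bits(px), entropy_bits(py)) + 1e-12)
    expect_equal(mi, as.numeric(compute_mi(y, x)), tolerance = 1e-12)
  }
})

test_that("independent variables approach zero MI as n grows", {
  set.seed(63)
  x <- runif(20000); y <- runif(20000)
  expect_lt(as.numeric(compute_mi(x, y)), 0.02)
})

test_that("degenerate inputs yield zero bits and a flag", {
  mi <- compute_mi(rep(2, 10), runif(10))
  expect_equal(as.numeric(mi), 0)
  expect_true(attr(mi, "degenerate"))
})

test_that("weak-response exclusion uses an inclusive 15-spike boundary", {
  tot <- c(a = 14, b = 15, c = 200)
  ex <- exclude_weak(tot)
  expect_equal(ex$retained, c(FALSE, TRUE, TRUE))
  # threshold zero disables the exclusion
  expect_true(all(exclude_weak(tot, threshold = 0)$retained))
})

test_that("MI permutation test hits the floor for dependence, reproduces by seed", {
  set.seed(64)
  x <- runif(200); y <- x
  r <- permutation_test_mi(x, y, n_perm = 400, seed = 5)
  expect_equal(r$p, 1 / 401)
  expect_true(r$significant)
  r2 <- permutation_test_mi(x, y, n_perm = 400, seed = 5)
  expect_identical(r$p, r2$p)
  # independent pair is rarely significant
  r3 <- permutation_test_mi(runif(200), runif(200), n_perm = 400, seed = 6)
  expect_gt(r3$p, 0.05)
})

test_that("MI ratio profile matches a max/min/sum oracle", {
  mk <- function(m) tibble::tibble(
    neuron_id = rep(sprintf("n%d", seq_len(nrow(m))), each = 4),
    feature = rep(c("closure", "curvature", "symmetry", "orientation"),
                  nrow(m)),
    mi = as.vector(t(m)))
  eq <- mi_profile(mk(matrix(0.05, 1, 4)))
  expect_equal(eq$greatest, 0.25)
  expect_equal(eq$least, 0.25)
  dom <- mi_profile(mk(matrix(c(1, 0, 0, 0), 1)))
  expect_equal(dom$greatest, 1)
  expect_equal(dom$least, 0)
  set.seed(65)
  M <- matrix(runif(40, 0.01, 0.2), 10, 4)
  pr <- mi_profile(mk(M))
  expect_equal(pr$greatest, apply(M, 1, max) / rowSums(M))
  expect_equal(pr$least, apply(M, 1, min) / rowSums(M))
  expect_equal(pr$mi_var, apply(M, 1, var))
  # all-zero quadruples are dropped
  z <- mi_profile(mk(rbind(M[1, ], c(0, 0, 0, 0))))
  expect_equal(nrow(z), 1)
})

test_that("the one-sample ratio test detects deviation from the even share", {
  set.seed(66)
  shifted <- 0.33 + rnorm(60, 0, 0.03)
  r <- test_mi_ratio(shifted, n_resample = 2000, seed = 2)
  expect_lt(r$p, 0.01)
  expect_gt(r$cliffs_delta, 0.9)
  null <- 0.25 + rnorm(60, 0, 0.03)
  r0 <- test_mi_ratio(null, n_resample = 2000, seed = 2)
  expect_gt(r0$p, 0.05)
})

test_that("tuned-vs-untuned comparison matches exact rank enumeration", {
  g1 <- c(1.3, 2.1, 4.5)
  g2 <- c(0.2, 0.8, 1.9, 3.0)
  out <- compare_tuned_vs_untuned(c(g1, g2), c(TRUE, TRUE, TRUE,
                                               FALSE, FALSE, FALSE, FALSE))
  # exhaustive enumeration of all assignments of ranks
  ranks <- rank(c(g1, g2))
  W_obs <- sum(ranks[1:3]) - 3 * 4 / 2
  combs <- utils::combn(7, 3)
  W_null <- apply(combs, 2, function(ix) sum(ranks[ix]) - 6)
  p_exact <- mean(abs(W_null - 6) >= abs(W_obs - 6))
  expect_equal(out$p, p_exact, tolerance = 1e-12)
  # identical groups: no effect
  same <- compare_tuned_vs_untuned(c(1, 2, 3, 4, 1, 2, 3, 4),
                                   rep(c(TRUE, FALSE), each = 4))
  expect_gt(same$p, 0.5)
  expect_lt(abs(same$effect_r), 0.1)
  # disjoint support: maximal effect size
  far <- compare_tuned_vs_untuned(c(10, 11, 12, 1, 2, 3),
                                  c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_gt(abs(far$effect_r), 0.75)
  # empty group: skipped with a message
  expect_message(res <- compare_tuned_vs_untuned(1:4, rep(TRUE, 4)),
                 "skipped")
  expect_null(res)
})

test_that("disabling the weak exclusion never changes a retained neuron's MI", {
  set.seed(67)
  features <- tibble::tibble(
    neuron_id = rep(c("n1", "n2"), each = 20),
    stimulus_id = rep(sprintf("s%02d", 1:20), 2),
    closure = runif(40),
    curvatures = replicate(40, runif(4, -1, 1), simplify = FALSE),
    symmetry = rep(runif(20), 2),
    orientation = runif(40, 0, 180))
  resp <- tibble::tibble(
    neuron_id = rep(c("n1", "n2"), each = 20),
    stimulus_id = rep(sprintf("s%02d", 1:20), 2),
    rate = c(rpois(20, 8), rpois(20, 0.2)), n_trials = 1)
  with_ex <- estimate_mi(features, resp, n_perm = 50, seed = 3)
  without <- estimate_mi(features, resp, weak_threshold = 0, n_perm = 50, seed = 3)
  kept <- with_ex[!with_ex$excluded, c("neuron_id", "feature", "mi")]
  matched <- dplyr::inner_join(kept, without,
                               by = c("neuron_id", "feature"))
  expect_equal(matched$mi.x, matched$mi.y)
  expect_true(all(with_ex$excluded[with_ex$neuron_id == "n2"]))
})
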