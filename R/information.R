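# Plug-in mutual information between spike counts and contour features,
# with the Sturges-type binning rule, weak-response exclusion,
# permutation significance, and the greatest/least MI-ratio profile.

#' Number of histogram bins from the Sturges-type rule
#'
#' Default reading: `nbin = ceiling(1 + log2(n))` (Sturges' rule), with a
#' minimum of 2. The literal base-10 form `1 + log10(2 n)` is available
#' via `base = "log10"`.
#'
#' @param n number of data points (>= 2).
#' @param base `"log2"` (default) or `"log10"`.
#' @return integer bin count.
#' @export
sturges_bins <- function(n, base = c("log2", "log10")) {
  base <- match.arg(base)
  if (any(n < 2)) cc_abort("sturges_bins() needs n >= 2")
  nb <- if (base == "log2") ceiling(1 + log2(n)) else ceiling(1 + log10(2 * n))
  pmax(as.integer(nb), 2L)
}

# equal-width bin indices over the observed range; a constant vector
# collapses to a single bin (index 1)
ew_bins <- function(v, nbin) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(1L, length(v)))
  b <- findInterval(v, seq(rng[1], rng[2], length.out = nbin + 1),
                    rightmost.closed = TRUE)
  pmin(pmax(b, 1L), nbin)
}

mi_from_indices <- function(ix, iy, nx, ny) {
  n <- length(ix)
  jt <- tabulate(ix + nx * (iy - 1L), nx * ny)
  px <- tabulate(ix, nx) / n
  py <- tabulate(iy, ny) / n
  p <- jt / n
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / (px[(seq_len(nx * ny) - 1L) %% nx + 1L][pos] *
                                py[(seq_len(nx * ny) - 1L) %/% nx + 1L][pos])))
}

#' Plug-in mutual information between responses and a feature
#'
#' `I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` on the joint
#' histogram of paired responses and feature values, with `0 log 0 = 0`.
#' Both axes are binned with equal-width bins over the observed range;
#' the bin count defaults to [sturges_bins()] of the pair count and is
#' applied to each axis. A constant response or constant feature yields 0
#' bits (degenerate, flagged by attribute `"degenerate"`).
#'
#' @param responses per-observation response values.
#' @param values per-observation feature values (same length).
#' @param nbin optional bin count overriding the rule.
#' @return MI in bits (attributes `"nbin"`, `"n"`, `"degenerate"`).
#' @export
compute_mi <- function(responses, values, nbin = NULL) {
  keep <- !is.na(responses) & !is.na(values)
  responses <- responses[keep]; values <- values[keep]
  n <- length(responses)
  if (n < 4) cc_abort("need >= 4 paired observations")
  nbin <- nbin %||% sturges_bins(n)
  degen <- diff(range(responses)) == 0 || diff(range(values)) == 0
  mi <- if (degen) 0 else
    mi_from_indices(ew_bins(responses, nbin), ew_bins(values, nbin), nbin, nbin)
  structure(mi, nbin = nbin, n = n, degenerate = degen)
}

#' Exclude weakly responding neurons
#'
#' Neurons whose total analyzed spike count is below `threshold` (default
#' 15 spikes) are removed; `threshold = 0` disables the exclusion.
#'
#' @param totals named numeric vector or tibble (`neuron_id`, `total`) of
#'   per-neuron total spike counts over the analyzed stimuli.
#' @param threshold minimum total spike count to retain (retained iff
#'   `total >= threshold`).
#' @return tibble `neuron_id`, `total`, `retained`.
#' @export
exclude_weak <- function(totals, threshold = 15) {
  if (!is.data.frame(totals))
    totals <- tibble::tibble(neuron_id = names(totals), total = as.numeric(totals))
  dplyr::mutate(totals, retained = .data$total >= threshold)
}

#' Permutation significance of mutual information
#'
#' Feature values are shuffled across stimuli `n_perm` times and MI
#' recomputed on the fixed binning; `p` is the fraction of shuffled MI
#' values at least as large as the observed one (with the +1 correction,
#' so the floor is `1/(n_perm + 1)`).
#'
#' @inheritParams compute_mi
#' @param n_perm number of shuffles.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list `mi`, `p`, `significant`, `n_perm`.
#' @export
permutation_test_mi <- function(responses, values, nbin = NULL,
                                n_perm = 1000, alpha = 0.05, seed = NULL) {
  keep <- !is.na(responses) & !is.na(values)
  responses <- responses[keep]; values <- values[keep]
  n <- length(responses)
  nbin <- nbin %||% sturges_bins(n)
  ix <- ew_bins(responses, nbin); iy <- ew_bins(values, nbin)
  obs <- mi_from_indices(ix, iy, nbin, nbin)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mi_from_indices(ix, sample(iy), nbin, nbin), numeric(1))
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  list(mi = obs, p = p, significant = p < alpha, n_perm = n_perm)
}

#' Mutual information between responses and every feature, per neuron
#'
#' For closure, symmetry and orientation each stimulus contributes one
#' (response, value) pair; the multi-valued curvature feature pairs each
#' local curvature with the stimulus response (`curvature_unit =
#' "local"`), or uses the per-stimulus mean (`"mean"`). Shuffling for the
#' significance test is at the stimulus level in both cases. Neurons
#' whose total spike count over the analyzed stimuli is below
#' `weak_threshold` are excluded.
#'
#' @param features feature table from [compute_features()].
#' @param responses response tibble (trials) or [mean_responses()] output.
#' @param features_to_use feature names.
#' @param weak_threshold spike-total exclusion threshold (0 disables).
#' @param curvature_unit `"local"` or `"mean"`.
#' @param n_perm,alpha permutation-test settings.
#' @param seed base RNG seed.
#' @return tibble per (neuron, feature): `mi` (bits), `nbin`, `n`,
#'   `p_perm`, `significant`, `excluded`, `reason`.
#' @export
estimate_mi <- function(features, responses,
                        features_to_use = c("closure", "curvature",
                                            "symmetry", "orientation"),
                        weak_threshold = 15,
                        curvature_unit = c("local", "mean"),
                        n_perm = 1000, alpha = 0.05, seed = 1) {
  curvature_unit <- match.arg(curvature_unit)
  if (!"rate" %in% names(responses)) {
    totals <- responses |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
    responses <- mean_responses(responses)
  } else {
    if (!"n_trials" %in% names(responses)) responses$n_trials <- 1
    totals <- responses |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(total = sum(.data$rate * .data$n_trials),
                       .groups = "drop")
  }
  dat <- dplyr::inner_join(features, responses,
                           by = c("neuron_id", "stimulus_id"))
  weak <- exclude_weak(totals, weak_threshold)
  out <- list()
  nids <- unique(dat$neuron_id)
  for (ni in seq_along(nids)) {
    nid <- nids[ni]
    nd <- dat[dat$neuron_id == nid, ]
    retained <- weak$retained[match(nid, weak$neuron_id)]
    for (feat in features_to_use) {
      row <- tibble::tibble(neuron_id = nid, feature = feat,
                            mi = NA_real_, nbin = NA_integer_, n = NA_integer_,
                            p_perm = NA_real_, significant = FALSE,
                            excluded = TRUE, reason = NA_character_)
      if (!isTRUE(retained)) {
        row$reason <- "weak response (< threshold spikes)"
        out[[length(out) + 1L]] <- row; next
      }
      if (feat == "curvature" && curvature_unit == "local") {
        keep <- lengths(nd$curvatures) > 0
        if (sum(keep) < 4) {
          row$reason <- "insufficient data"; out[[length(out) + 1L]] <- row; next
        }
        vals_by_stim <- nd$curvatures[keep]
        r_stim <- nd$rate[keep]
        reps <- lengths(vals_by_stim)
        x <- rep(r_stim, reps); y <- unlist(vals_by_stim)
        n <- length(x)
        nbin <- sturges_bins(n)
        ix <- ew_bins(x, nbin); iy0 <- ew_bins(y, nbin)
        obs <- mi_from_indices(ix, iy0, nbin, nbin)
        # stimulus-level shuffle leaves both marginals fixed, so bin
        # indices can be precomputed per stimulus
        bxs <- ew_bins(r_stim, nbin)
        biny <- split(iy0, rep(seq_along(reps), reps))
        set.seed(seed + 104729L * ni + match(feat, features_to_use))
        null <- vapply(seq_len(n_perm), function(i) {
          pe <- sample(length(biny))
          mi_from_indices(rep(bxs, reps[pe]),
                          unlist(biny[pe], use.names = FALSE), nbin, nbin)
        }, numeric(1))
        p <- (1 + sum(null >= obs)) / (n_perm + 1)
        out[[length(out) + 1L]] <- tibble::tibble(
          neuron_id = nid, feature = feat, mi = obs, nbin = nbin, n = n,
          p_perm = p, significant = p < alpha, excluded = FALSE,
          reason = NA_character_)
        next
      }
      vals <- switch(feat, closure = nd$closure, symmetry = nd$symmetry,
                     orientation = nd$orientation,
                     curvature = vapply(nd$curvatures, function(v)
                       if (length(v)) mean(v) else NA_real_, numeric(1)))
      keep <- !is.na(vals)
      if (sum(keep) < 4) {
        row$reason <- "insufficient data"; out[[length(out) + 1L]] <- row; next
      }
      pt <- permutation_test_mi(nd$rate[keep], vals[keep], n_perm = n_perm,
                                alpha = alpha,
                                seed = seed + 104729L * ni +
                                  match(feat, features_to_use))
      out[[length(out) + 1L]] <- tibble::tibble(
        neuron_id = nid, feature = feat, mi = pt$mi,
        nbin = sturges_bins(sum(keep)), n = sum(keep),
        p_perm = pt$p, significant = pt$significant, excluded = FALSE,
        reason = NA_character_)
    }
  }
  dplyr::bind_rows(out)
}

#' Greatest/least MI-ratio profile across the four features
#'
#' For each neuron with all four MI values present, the ratio of the
#' greatest and of the least MI to the sum of the four. Neurons with a
#' zero MI sum are dropped.
#'
#' @param mi_tbl output of [estimate_mi()] (or any tibble with
#'   `neuron_id`, `feature`, `mi`).
#' @return tibble per neuron: the four MI values (wide), `mi_sum`,
#'   `greatest`, `least`, and `mi_var` (within-neuron variance of the
#'   four MI values).
#' @export
mi_profile <- function(mi_tbl) {
  wide <- mi_tbl |>
    dplyr::filter(!is.na(.data$mi)) |>
    dplyr::select("neuron_id", "feature", "mi") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "mi",
                       names_prefix = "mi_")
  need <- c("mi_closure", "mi_curvature", "mi_symmetry", "mi_orientation")
  miss <- setdiff(need, names(wide))
  for (m in miss) wide[[m]] <- NA_real_
  M <- as.matrix(wide[, need])
  complete <- rowSums(is.na(M)) == 0
  wide <- wide[complete, ]; M <- M[complete, , drop = FALSE]
  s <- rowSums(M)
  ok <- s > 0
  wide <- wide[ok, ]; M <- M[ok, , drop = FALSE]; s <- s[ok]
  wide$mi_sum <- s
  wide$greatest <- apply(M, 1, max) / s
  wide$least <- apply(M, 1, min) / s
  wide$mi_var <- apply(M, 1, var)
  wide
}

#' One-sample permutation test of an MI ratio against the even share
#'
#' Sign-flip resampling of `ratio - null` (default even share 0.25)
#' tests whether the population of per-neuron ratios deviates from the
#' value expected when all four features contribute equally. Effect size
#' is Cliff's delta against the null value.
#'
#' @param ratios per-neuron greatest or least MI ratios.
#' @param null null value (0.25 for four features).
#' @param n_resample sign-flip resamples.
#' @param seed RNG seed.
#' @return tibble: `mean_ratio`, `statistic` (mean deviation), `p`
#'   (two-sided), `cliffs_delta`, `n`.
#' @export
test_mi_ratio <- function(ratios, null = 0.25, n_resample = 10000, seed = 1) {
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < 2) cc_abort("need >= 2 ratios")
  d0 <- ratios - null
  obs <- mean(d0)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * n_resample, replace = TRUE), n_resample, n)
  null_stats <- as.numeric(flips %*% d0) / n
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_resample + 1)
  delta <- (sum(ratios > null) - sum(ratios < null)) / n
  tibble::tibble(mean_ratio = mean(ratios), statistic = obs, p = p,
                 cliffs_delta = delta, n = n)
}

#' Compare MI between significantly tuned and untuned neurons
#'
#' Wilcoxon rank-sum test of MI values between the two groups, with the
#' effect size `r = z / sqrt(n)` from the tie-corrected normal
#' approximation of the rank-sum statistic.
#'
#' @param mi per-neuron MI values.
#' @param tuned logical vector, `TRUE` for neurons with significant tuning.
#' @return one-row tibble: `statistic` (rank-sum W), `p` (two-sided),
#'   `effect_r`, group sizes; `NULL` with a message when a group is empty.
#' @export
compare_tuned_vs_untuned <- function(mi, tuned) {
  keep <- !is.na(mi) & !is.na(tuned)
  mi <- mi[keep]; tuned <- as.logical(tuned[keep])
  n1 <- sum(tuned); n2 <- sum(!tuned)
  if (n1 == 0 || n2 == 0) {
    message("compare_tuned_vs_untuned: a group is empty; comparison skipped")
    return(NULL)
  }
  wt <- suppressWarnings(wilcox.test(mi[tuned], mi[!tuned]))
  # tie-corrected normal approximation for the effect size
  r_all <- rank(mi)
  W <- sum(r_all[tuned]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(mi)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  tibble::tibble(statistic = unname(wt$statistic), p = wt$p.value,
                 effect_r = z / sqrt(n), n_tuned = n1, n_untuned = n2)
}
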