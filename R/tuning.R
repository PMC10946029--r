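# Tuning maps, constrained tuning-curve fits and permutation significance.
#
# A tuning map is the histogram of mean spike counts per feature bin,
# normalized by its maximum. Closure and symmetry maps are fitted by a
# constrained Gaussian, curvature and orientation maps by a cosine.
# Significance compares the fitting error of the observed map against
# maps rebuilt from shuffled stimulus-response pairings.

#' Default tuning-map bin edges per feature
#'
#' Closure and symmetry use 10 bins on `[0, 1]`, curvature 20 bins on
#' `[-1, 1]`, orientation 18 bins of 10 degrees.
#'
#' @return named list of bin-edge vectors.
#' @export
tuning_bins <- function() {
  list(closure = seq(0, 1, length.out = 11),
       curvature = seq(-1, 1, length.out = 21),
       symmetry = seq(0, 1, length.out = 11),
       orientation = seq(0, 180, length.out = 19))
}

tuning_family <- function(feature) {
  switch(feature,
         closure = "gaussian", symmetry = "gaussian",
         curvature = "cosine_free", orientation = "cosine_box",
         cc_abort(paste0("unknown feature: ", feature)))
}

bin_index <- function(v, edges) {
  b <- findInterval(v, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

row_maxs <- function(M) do.call(pmax, as.data.frame(M))

# Build raw map weight matrix for one or many response orderings.
# R: matrix (n_orderings x n_stimuli) of per-stimulus mean responses.
# values: numeric vector (scalar feature) or list of numeric vectors
# (local curvatures). Returns list(W, n) with W (n_orderings x n_bins).
map_weights <- function(values, R, edges, statistic = "mean") {
  nb <- length(edges) - 1L
  if (is.list(values)) {
    H <- matrix(0, ncol(R), nb)
    for (s in seq_along(values)) {
      v <- values[[s]]
      if (length(v)) H[s, ] <- tabulate(bin_index(v, edges), nb)
    }
    cnt <- colSums(H)
    W <- R %*% H
    if (statistic == "mean")
      W[, cnt > 0] <- sweep(W[, cnt > 0, drop = FALSE], 2, cnt[cnt > 0], "/")
    list(W = W, n = cnt)
  } else {
    b <- bin_index(values, edges)
    M <- matrix(0, length(values), nb)
    M[cbind(seq_along(b), b)] <- 1
    cnt <- colSums(M)
    W <- R %*% M
    W[, cnt > 0] <- sweep(W[, cnt > 0, drop = FALSE], 2, cnt[cnt > 0], "/")
    list(W = W, n = cnt)
  }
}

#' Build a tuning map
#'
#' For scalar features the map holds the mean spike count of the stimuli
#' falling in each feature bin. For curvature (`values` a list of local
#' curvatures per stimulus) each stimulus contributes its local-curvature
#' histogram multiplied by the stimulus response; the per-bin sums across
#' stimuli are divided by the local-curvature counts (`statistic =
#' "mean"`, the default) so the map again holds mean spikes per bin.
#' Either way the map is normalized by its maximum.
#'
#' @param values per-stimulus feature values: numeric vector, or list of
#'   numeric vectors for the multi-valued curvature feature.
#' @param rates per-stimulus mean spike counts (same length/order).
#' @param feature feature name (selects default bins).
#' @param edges optional bin edges overriding the default.
#' @param statistic for the multi-valued curvature feature: `"mean"`
#'   (default) divides the summed response histogram by the
#'   local-curvature count histogram, giving the mean spike count per
#'   curvature occurrence in each bin -- the same mean-spikes semantics
#'   as the scalar features; `"sum"` keeps the raw summed response
#'   histogram.
#' @return a `"tuning_map"` tibble: `bin`, `lo`, `hi`, `mid`, `n`,
#'   `weight` (raw), `norm` (max-normalized; `NA` on empty bins).
#' @export
build_tuning_map <- function(values, rates, feature, edges = NULL,
                             statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  edges <- edges %||% tuning_bins()[[feature]]
  keep <- if (is.list(values)) !vapply(values, function(v) length(v) == 0, logical(1))
          else !is.na(values)
  if (!any(keep)) cc_abort("all feature values missing")
  values <- if (is.list(values)) values[keep] else values[keep]
  rates <- rates[keep]
  mw <- map_weights(values, matrix(rates, nrow = 1), edges, statistic)
  w <- as.numeric(mw$W)
  mx <- max(w)
  norm <- if (mx > 0) w / mx else w
  norm[mw$n == 0] <- NA_real_
  w[mw$n == 0] <- NA_real_
  out <- tibble::tibble(
    bin = seq_len(length(edges) - 1L),
    lo = edges[-length(edges)], hi = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    n = mw$n, weight = w, norm = norm)
  class(out) <- c("tuning_map", class(out))
  attr(out, "feature") <- feature
  attr(out, "edges") <- edges
  out
}

# ---- vectorized grid fitting -------------------------------------------
# Each engine takes Y (n_maps x n_bins, occupied bins only, rows
# max-normalized) and bin centres x, and returns the per-row best rmse
# plus parameters. The amplitude/offset are profiled in closed form given
# the peak/width grid point, so the procedure is deterministic and
# identical for observed and shuffled maps.

grid_fit_gaussian <- function(Y, x, nb_grid = 26, nc_grid = 24) {
  bs <- seq(0, 1, length.out = nb_grid)
  cs <- seq(0.08, 1, length.out = nc_grid)
  gb <- rep(bs, times = nc_grid); gc <- rep(cs, each = nb_grid)
  G <- exp(-outer(x, gb, `-`)^2 / rep(gc^2, each = length(x)))
  g2 <- colSums(G^2)
  YG <- Y %*% G
  A <- sweep(YG, 2, g2, "/")
  A[A < 0] <- 0; A[A > 1] <- 1
  RSS <- rowSums(Y^2) - 2 * A * YG + sweep(A^2, 2, g2, "*")
  RSS <- matrix(RSS, nrow(Y))
  j <- max.col(-RSS, ties.method = "first")
  pick <- cbind(seq_len(nrow(Y)), j)
  list(rmse = sqrt(RSS[pick] / length(x)),
       a = A[pick], b = gb[j], c = gc[j], d = rep(NA_real_, nrow(Y)))
}

# two-parameter linear solve for f = a*u + d, unconstrained
solve_ad <- function(Y, u) {
  n <- length(u)
  su <- sum(u); suu <- sum(u^2)
  det <- n * suu - su^2
  Syu <- Y %*% u; Sy <- rowSums(Y)
  a <- (n * Syu - su * Sy) / det
  d <- (suu * Sy - su * Syu) / det
  cbind(a = as.numeric(a), d = as.numeric(d))
}

rss_ad <- function(Y, u, a, d) {
  fit <- outer(a, u) + d
  rowSums((Y - fit)^2)
}

grid_fit_cosine <- function(Y, x, c_grid, box = FALSE) {
  n <- nrow(Y)
  best_rmse <- rep(Inf, n)
  best <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("a", "c", "d")))
  for (cv in c_grid) {
    u <- cos(x - cv)
    ad <- solve_ad(Y, u)
    a <- ad[, 1]; d <- ad[, 2]
    if (box) {
      out <- a < 0 | a > 1 | d < 0 | d > 1
      if (any(out)) {
        idx <- which(out)
        Yb <- Y[idx, , drop = FALSE]
        su <- sum(u); suu <- sum(u^2); m <- length(u)
        cand_a <- cbind(0, 1,
                        pmin(pmax((Yb %*% u) / suu, 0), 1),
                        pmin(pmax(((Yb - 1) %*% u) / suu, 0), 1))
        cand_d <- cbind(pmin(pmax(rowSums(Yb) / m, 0), 1),
                        pmin(pmax(rowSums(Yb - rep(u, each = nrow(Yb))) / m, 0), 1),
                        0, 1)
        r_best <- rep(Inf, length(idx)); a_best <- d_best <- numeric(length(idx))
        for (k in 1:4) {
          rk <- rss_ad(Yb, u, cand_a[, k], cand_d[, k])
          upd <- rk < r_best
          r_best[upd] <- rk[upd]
          a_best[upd] <- cand_a[upd, k]; d_best[upd] <- cand_d[upd, k]
        }
        a[idx] <- a_best; d[idx] <- d_best
      }
    }
    r <- sqrt(rss_ad(Y, u, a, d) / length(x))
    upd <- r < best_rmse
    best_rmse[upd] <- r[upd]
    best[upd, ] <- cbind(a, cv, d)[upd, ]
  }
  list(rmse = best_rmse, a = best[, "a"], b = rep(1, n),
       c = best[, "c"], d = best[, "d"])
}

grid_fit <- function(Y, x, family) {
  switch(family,
         gaussian = grid_fit_gaussian(Y, x),
         cosine_free = grid_fit_cosine(Y, x, seq(-1, 1, length.out = 41)),
         cosine_box = grid_fit_cosine(Y, x, seq(0, pi, length.out = 37),
                                      box = TRUE))
}

# model evaluation in feature units
tuning_curve <- function(par, x, family) {
  if (family == "gaussian")
    par[["a"]] * exp(-(x - par[["b"]])^2 / par[["c"]]^2)
  else
    par[["a"]] * cos(x - par[["c"]]) + par[["d"]]
}

polish_fit <- function(y, x, family, start) {
  obj <- function(p) {
    names(p) <- c("a", "b", "c", "d")[seq_along(p)]
    if (family == "gaussian") sum((tuning_curve(p, x, family) - y)^2)
    else sum((p[["a"]] * cos(x - p[["b"]]) + p[["c"]] - y)^2)
  }
  if (family == "gaussian") {
    p0 <- c(start$a, start$b, max(start$c, 1e-3))
    lo <- c(0, 0, 1e-3); hi <- c(1, 1, 1)
  } else if (family == "cosine_free") {
    p0 <- c(start$a, start$c, start$d); lo <- c(-Inf, -1, -Inf); hi <- c(Inf, 1, Inf)
  } else {
    p0 <- c(start$a, start$c, start$d); lo <- c(0, 0, 0); hi <- c(1, pi, 1)
  }
  fit <- tryCatch(
    optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(start)
  sse0 <- if (family == "gaussian")
    sum((start$a * exp(-(x - start$b)^2 / start$c^2) - y)^2)
  else sum((start$a * cos(x - start$c) + start$d - y)^2)
  if (fit$value >= sse0) return(start)
  pp <- unname(fit$par)
  if (family == "gaussian")
    list(a = pp[1], b = pp[2], c = pp[3], d = NA_real_,
         rmse = sqrt(fit$value / length(x)))
  else
    list(a = pp[1], b = 1, c = pp[2], d = pp[3],
         rmse = sqrt(fit$value / length(x)))
}

fit_optimal <- function(par, family, feature) {
  if (family == "gaussian") return(par$b)
  if (feature == "curvature") {
    xx <- seq(-1, 1, length.out = 401)
    return(xx[which.max(par$a * cos(xx - par$c) + par$d)])
  }
  xx <- seq(0, pi, length.out = 721)
  xx[which.max(par$a * cos(xx - par$c) + par$d)] * 180 / pi
}

#' Fit a constrained tuning function to a tuning map
#'
#' Gaussian `f(x) = a exp(-(x - b)^2 / c^2)` with `0 <= a, b, c <= 1`
#' for closure and symmetry; cosine `f(x) = a cos(x - c) + d` with
#' `-1 <= c <= 1` (`a`, `d` free) for curvature and with
#' `0 <= a, d <= 1`, `0 <= c <= pi` for orientation (bin centres in
#' radians). The frequency parameter of the cosine is fixed at 1. Fitting
#' is least squares on the max-normalized map over occupied bins: a
#' deterministic profile grid (closed-form amplitude/offset at each
#' candidate peak/width) followed by a bounded quasi-Newton polish.
#'
#' @param map a `"tuning_map"` (see [build_tuning_map()]).
#' @param feature feature name; defaults to the map's feature attribute.
#' @return a `"tuning_fit"` list: family, parameters `a`, `b`, `c`, `d`,
#'   `rmse` (normalized-spike units), `strength` (`a/c` Gaussian, `a`
#'   cosine), `optimal` (peak location in feature units), `n_bins`.
#' @export
fit_tuning <- function(map, feature = NULL) {
  feature <- feature %||% attr(map, "feature")
  family <- tuning_family(feature)
  ok <- !is.na(map$norm)
  if (sum(ok) < 4) cc_abort("need >= 4 occupied bins to fit tuning")
  x <- map$mid[ok]
  if (feature == "orientation") x <- x * pi / 180
  y <- map$norm[ok]
  g <- grid_fit(matrix(y, 1), x, family)
  start <- list(a = g$a, b = g$b, c = g$c, d = g$d, rmse = g$rmse)
  par <- polish_fit(y, x, family, start)
  structure(
    list(family = family, feature = feature,
         a = as.numeric(par$a), b = if (family == "gaussian") as.numeric(par$b) else 1,
         c = as.numeric(par$c),
         d = if (family == "gaussian") NA_real_ else as.numeric(par$d),
         rmse = as.numeric(par$rmse %||% g$rmse),
         strength = as.numeric(if (family == "gaussian") par$a / par$c else par$a),
         optimal = as.numeric(fit_optimal(par, family, feature)),
         n_bins = sum(ok)),
    class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("<tuning_fit %s/%s> a=%.3f b=%.3f c=%.3f d=%s rmse=%.4f optimal=%.3f\n",
              x$feature, x$family, x$a, x$b, x$c,
              ifelse(is.na(x$d), "-", sprintf("%.3f", x$d)),
              x$rmse, x$optimal))
  invisible(x)
}

#' @method tidy tuning_fit
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = c(x$a, x$b, x$c, x$d))
}

#' @method glance tuning_fit
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(family = x$family, feature = x$feature, rmse = x$rmse,
                 strength = x$strength, optimal = x$optimal,
                 n_bins = x$n_bins)
}

# core permutation machinery shared by the exported test and the driver
tune_perm_core <- function(values, rates, feature, edges, n_perm, alpha, seed) {
  edges <- edges %||% tuning_bins()[[feature]]
  family <- tuning_family(feature)
  ns <- length(rates)
  if (!is.null(seed)) set.seed(seed)
  Pm <- vapply(seq_len(n_perm), function(i) sample.int(ns), integer(ns))
  R <- rbind(rates, matrix(rates[Pm], n_perm, ns, byrow = TRUE))
  mw <- map_weights(values, R, edges)
  occ <- mw$n > 0
  if (sum(occ) < 4)
    return(list(valid = FALSE, reason = "fewer than 4 occupied bins"))
  W <- mw$W[, occ, drop = FALSE]
  rmax <- row_maxs(W)
  if (rmax[1] <= 0) return(list(valid = FALSE, reason = "all-zero map"))
  rmax[rmax <= 0] <- 1
  Y <- W / rmax
  x <- (edges[-length(edges)] + edges[-1])[occ] / 2
  if (feature == "orientation") x <- x * pi / 180
  g <- grid_fit(Y, x, family)
  obs <- g$rmse[1]; null <- g$rmse[-1]
  crit <- quantile(null, alpha, type = 1, names = FALSE)
  list(valid = TRUE, rmse_obs = obs, null = null, crit = crit,
       significant = obs < crit,
       p = (1 + sum(null <= obs)) / (n_perm + 1),
       grid_par = list(a = g$a[1], b = g$b[1], c = g$c[1], d = g$d[1]),
       x = x, y = Y[1, ], occ = occ, family = family)
}

#' Permutation significance of tuning
#'
#' The stimulus-response pairing is shuffled `n_perm` times; each shuffle
#' rebuilds and refits the tuning map under the identical deterministic
#' fitting procedure. Tuning is significant when the observed fitting
#' error is smaller than the bottom `alpha` quantile of the shuffled
#' errors (the "bottom 1%" criterion at the default `alpha = 0.01` with
#' 1000 shuffles).
#'
#' @inheritParams build_tuning_map
#' @param n_perm number of shuffles.
#' @param alpha significance level of the error criterion.
#' @param seed RNG seed (shuffles are reproducible given the seed).
#' @return list with `significant`, `p` (permutation p-value),
#'   `rmse_obs`, `crit` (null error criterion) and `n_perm`.
#' @export
permutation_test_tuning <- function(values, rates, feature, edges = NULL,
                                    n_perm = 1000, alpha = 0.01, seed = NULL) {
  keep <- if (is.list(values)) lengths(values) > 0 else !is.na(values)
  core <- tune_perm_core(if (is.list(values)) values[keep] else values[keep],
                         rates[keep], feature, edges, n_perm, alpha, seed)
  if (!isTRUE(core$valid))
    return(list(significant = FALSE, p = NA_real_, rmse_obs = NA_real_,
                crit = NA_real_, n_perm = n_perm, reason = core$reason))
  list(significant = core$significant, p = core$p, rmse_obs = core$rmse_obs,
       crit = core$crit, n_perm = n_perm, reason = NA_character_)
}

#' Estimate tuning for every neuron and feature
#'
#' Joins a feature table with trial-averaged responses and, for each
#' (neuron, feature), builds the tuning map, tests significance by
#' permutation and reports the polished constrained fit. Exclusion rules:
#' neurons with any missing curvature or orientation value are excluded
#' from those features; closure analyses retain neurons with partial
#' missingness (missing stimuli are dropped); symmetry is always
#' complete.
#'
#' @param features feature table from [compute_features()].
#' @param responses response tibble (trials) or output of
#'   [mean_responses()].
#' @param features_to_fit subset of the four feature names.
#' @param bins named list of bin edges (default [tuning_bins()]).
#' @param n_perm,alpha permutation-test settings.
#' @param seed base RNG seed; each (neuron, feature) derives its own.
#' @return tibble with one row per (neuron, feature): fit parameters,
#'   `rmse`, `strength`, `optimal`, `p_perm`, `significant`, `excluded`,
#'   `reason`.
#' @export
estimate_tuning <- function(features, responses,
                            features_to_fit = c("closure", "curvature",
                                                "symmetry", "orientation"),
                            bins = tuning_bins(), n_perm = 1000,
                            alpha = 0.01, seed = 1) {
  if (!"rate" %in% names(responses)) responses <- mean_responses(responses)
  dat <- dplyr::inner_join(features, responses,
                           by = c("neuron_id", "stimulus_id"))
  out <- list()
  nids <- unique(dat$neuron_id)
  empty_fit <- function(nid, feat, reason) tibble::tibble(
    neuron_id = nid, feature = feat, n_stimuli = NA_integer_,
    a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
    rmse = NA_real_, strength = NA_real_, optimal = NA_real_,
    p_perm = NA_real_, significant = FALSE, excluded = TRUE, reason = reason)
  for (ni in seq_along(nids)) {
    nid <- nids[ni]
    nd <- dat[dat$neuron_id == nid, ]
    for (feat in features_to_fit) {
      vals <- switch(feat,
                     closure = nd$closure, symmetry = nd$symmetry,
                     orientation = nd$orientation, curvature = nd$curvatures)
      miss <- if (feat == "curvature") lengths(vals) == 0 else is.na(vals)
      if (feat %in% c("curvature", "orientation") && any(miss)) {
        out[[length(out) + 1L]] <- empty_fit(nid, feat, "missing feature values")
        next
      }
      keep <- !miss
      if (!any(keep)) {
        out[[length(out) + 1L]] <- empty_fit(nid, feat, "all feature values missing")
        next
      }
      vals_k <- if (feat == "curvature") vals[keep] else vals[keep]
      rates_k <- nd$rate[keep]
      core <- tune_perm_core(vals_k, rates_k, feat, bins[[feat]],
                             n_perm, alpha,
                             seed = seed + 7919L * ni + match(feat, features_to_fit))
      if (!isTRUE(core$valid)) {
        out[[length(out) + 1L]] <- empty_fit(nid, feat, core$reason)
        next
      }
      par <- polish_fit(core$y, core$x, core$family, core$grid_par)
      fam <- core$family
      out[[length(out) + 1L]] <- tibble::tibble(
        neuron_id = nid, feature = feat, n_stimuli = sum(keep),
        a = par$a, b = if (fam == "gaussian") par$b else 1,
        c = par$c, d = if (fam == "gaussian") NA_real_ else par$d,
        rmse = par$rmse %||% core$rmse_obs,
        strength = if (fam == "gaussian") par$a / par$c else par$a,
        optimal = fit_optimal(par, fam, feat),
        p_perm = core$p, significant = core$significant,
        excluded = FALSE, reason = NA_character_)
    }
  }
  dplyr::bind_rows(out)
}

#' Distribution of optimal features normalized by stimulus density
#'
#' @param optima optimal feature values of (significantly tuned) neurons.
#' @param stimulus_values the feature's values across stimuli.
#' @param edges histogram bin edges.
#' @return tibble with raw neuron counts, stimulus density (proportion
#'   per bin) and their ratio; bins with optima but zero stimulus density
#'   are masked (`NA`) and flagged.
#' @export
optimal_distribution <- function(optima, stimulus_values, edges) {
  nb <- length(edges) - 1L
  cnt <- if (length(optima)) tabulate(bin_index(optima, edges), nb) else integer(nb)
  dens <- tabulate(bin_index(stimulus_values[!is.na(stimulus_values)], edges), nb)
  dens <- dens / sum(dens)
  norm <- ifelse(dens > 0, cnt / dens, NA_real_)
  masked <- dens == 0 & cnt > 0
  if (any(masked))
    rlang::warn("optima fall in bins with zero stimulus density; masked")
  tibble::tibble(bin = seq_len(nb), lo = edges[-nb - 1L], hi = edges[-1],
                 mid = (edges[-nb - 1L] + edges[-1]) / 2,
                 count = cnt, density = dens, normalized = norm,
                 masked = masked)
}

#' Cross-tuning of optimal closure and optimal curvature
#'
#' @param closure_optima,curvature_optima per-neuron optimal values
#'   (paired; use neurons significant for closure and/or curvature).
#' @param stim_closure,stim_curvature per-stimulus feature values whose
#'   joint histogram is the normalizing density.
#' @param closure_edges,curvature_edges bin edges.
#' @return `"cross_tuning"` list of three matrices: neuron `counts`,
#'   stimulus joint `density` (proportions) and their ratio `normalized`
#'   (`NA` where the density is zero).
#' @export
cross_tuning <- function(closure_optima, curvature_optima,
                         stim_closure, stim_curvature,
                         closure_edges = tuning_bins()$closure,
                         curvature_edges = tuning_bins()$curvature) {
  stopifnot(length(closure_optima) == length(curvature_optima))
  nb1 <- length(closure_edges) - 1L; nb2 <- length(curvature_edges) - 1L
  joint <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    ia <- bin_index(a[keep], closure_edges)
    ib <- bin_index(b[keep], curvature_edges)
    matrix(tabulate(ia + nb1 * (ib - 1L), nb1 * nb2), nb1, nb2)
  }
  counts <- joint(closure_optima, curvature_optima)
  dens <- joint(stim_closure, stim_curvature)
  dens <- dens / sum(dens)
  normalized <- ifelse(dens > 0, counts / dens, NA_real_)
  structure(list(counts = counts, density = dens, normalized = normalized,
                 closure_edges = closure_edges,
                 curvature_edges = curvature_edges),
            class = "cross_tuning")
}
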