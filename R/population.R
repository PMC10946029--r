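# Population-level representation: row-normalized response matrix,
# nonmetric MDS (Kruskal Stress-1), natural-vs-silhouette preference,
# equal-count axis grouping, moving-window axis profiles, and axis
# regressions.

#' Build the normalized response matrix
#'
#' Trial-averaged responses per (neuron, stimulus), each neuron's row
#' divided by its maximum across stimuli. Neurons with an all-zero row
#' are dropped (with a message).
#'
#' @param responses response tibble (trials) or [mean_responses()] output.
#' @param kinds optional tibble `stimulus_id`, `kind`
#'   (`"natural"`/`"silhouette"`); stored as the column-kind attribute.
#' @param kind_filter optionally keep only one stimulus kind (e.g.
#'   `"silhouette"`); row maxima are recomputed on the kept columns.
#' @return numeric matrix (neurons x stimuli) with attribute `"kind"`.
#' @export
build_response_matrix <- function(responses, kinds = NULL, kind_filter = NULL) {
  if (!"rate" %in% names(responses)) responses <- mean_responses(responses)
  wide <- responses |>
    dplyr::select("neuron_id", "stimulus_id", "rate") |>
    tidyr::pivot_wider(names_from = "stimulus_id", values_from = "rate")
  M <- as.matrix(wide[, -1])
  rownames(M) <- wide$neuron_id
  if (anyNA(M)) cc_abort("response matrix has missing (neuron, stimulus) cells")
  kind <- NULL
  if (!is.null(kinds)) {
    kind <- kinds$kind[match(colnames(M), kinds$stimulus_id)]
    if (!is.null(kind_filter)) {
      M <- M[, kind %in% kind_filter, drop = FALSE]
      kind <- kind[kind %in% kind_filter]
    }
  }
  mx <- apply(M, 1, max)
  drop <- mx == 0
  if (any(drop)) {
    message("dropping ", sum(drop), " all-zero neuron(s): ",
            paste(rownames(M)[drop], collapse = ", "))
    M <- M[!drop, , drop = FALSE]; mx <- mx[!drop]
  }
  M <- M / mx
  attr(M, "kind") <- kind
  M
}

#' Nonmetric MDS of the neural population
#'
#' Embeds neurons in `k` dimensions by nonmetric MDS minimizing Kruskal's
#' Stress-1, with `n_restarts` randomized initial configurations (plus a
#' classical-scaling start); the lowest-stress solution is kept and
#' centred at the origin.
#'
#' @param mat response matrix from [build_response_matrix()].
#' @param k embedding dimension.
#' @param dissim `"euclidean"` (distance between normalized response
#'   rows) or `"correlation"` (1 - Pearson r).
#' @param seed RNG seed for the randomized starts.
#' @param n_restarts number of random initial configurations.
#' @return `"population_map"` list: `coords` tibble (`neuron_id`,
#'   `axis1`, `axis2`, ...), `stress`, `k`, `dissim`, `n_restarts`.
#' @export
run_mds <- function(mat, k = 2, dissim = c("euclidean", "correlation"),
                    seed = 1, n_restarts = 20) {
  dissim <- match.arg(dissim)
  if (nrow(mat) < 3) cc_abort("need >= 3 neurons for MDS")
  d <- if (dissim == "euclidean") dist(mat) else
    stats::as.dist(1 - cor(t(mat)))
  n <- nrow(mat)
  starts <- vector("list", n_restarts + 1)
  starts[[1]] <- cmdscale(d, k = k)
  if (ncol(starts[[1]]) < k) {                 # degenerate cmdscale
    starts[[1]] <- cbind(starts[[1]],
                         matrix(0, n, k - ncol(starts[[1]])))
  }
  for (i in seq_len(n_restarts)) {
    set.seed(seed + i)
    starts[[i + 1]] <- matrix(rnorm(n * k), n, k)
  }
  best <- NULL
  for (y0 in starts) {
    m <- tryCatch(
      vegan::monoMDS(d, y = y0, k = k, model = "global",
                     maxit = 1000, smin = 1e-10, sfgrmin = 1e-10,
                     sratmax = 0.9999999),
      error = function(e) NULL)
    if (!is.null(m) && (is.null(best) || m$stress < best$stress)) best <- m
  }
  if (is.null(best)) cc_abort("MDS failed to converge in all restarts")
  pts <- scale(best$points, scale = FALSE)
  coords <- tibble::as_tibble(stats::setNames(
    as.data.frame(pts), paste0("axis", seq_len(k))))
  coords <- dplyr::bind_cols(tibble::tibble(neuron_id = rownames(mat)), coords)
  structure(list(coords = coords, stress = best$stress, k = k,
                 dissim = dissim, n_restarts = n_restarts),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("<population_map> %d neurons, k = %d, stress-1 = %.4g (%s)\n",
              nrow(x$coords), x$k, x$stress, x$dissim))
  invisible(x)
}

#' @method tidy population_map
#' @export
tidy.population_map <- function(x, ...) x$coords

#' @method glance population_map
#' @export
glance.population_map <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n_neurons = nrow(x$coords),
                 dissim = x$dissim, n_restarts = x$n_restarts)
}

#' Stress as a function of embedding dimension
#'
#' @inheritParams run_mds
#' @param dims dimensions to sweep.
#' @return tibble `k`, `stress`.
#' @export
mds_stress_by_dim <- function(mat, dims = 1:3, dissim = "euclidean",
                              seed = 1, n_restarts = 20) {
  purrr::map_dfr(dims, function(k) {
    m <- run_mds(mat, k = k, dissim = dissim, seed = seed,
                 n_restarts = n_restarts)
    tibble::tibble(k = k, stress = m$stress)
  })
}

#' Align an embedding to a reference configuration
#'
#' Procrustes rotation/reflection/translation (and scaling) of a map's
#' coordinates onto a reference, removing the rigid-motion ambiguity of
#' MDS so repeated runs are comparable.
#'
#' @param map `"population_map"`.
#' @param reference matrix or `"population_map"` with matching rows.
#' @return the map with aligned coordinates; attribute
#'   `"procrustes_rmse"` records the root-mean-square residual of the
#'   symmetric Procrustes superimposition.
#' @export
procrustes_align <- function(map, reference) {
  ref <- if (inherits(reference, "population_map"))
    as.matrix(reference$coords[, -1]) else as.matrix(reference)
  X <- as.matrix(map$coords[, -1])
  pr <- vegan::procrustes(ref, X, symmetric = FALSE)
  prs <- vegan::procrustes(ref, X, symmetric = TRUE)
  map$coords[, -1] <- as.data.frame(pr$Yrot)
  attr(map, "procrustes_rmse") <- sqrt(prs$ss / nrow(X))
  map
}

#' Orient map axes so chosen covariates increase along them
#'
#' MDS axes have arbitrary sign; this flips each axis so the regression
#' slope of the given per-neuron values on that axis is positive.
#'
#' @param map `"population_map"`.
#' @param values list (or single vector) of per-neuron covariates, one
#'   per axis to orient; `NULL` entries leave the axis unchanged.
#' @return the map with axes flipped as needed.
#' @export
orient_map <- function(map, values) {
  if (!is.list(values)) values <- list(values)
  for (a in seq_along(values)) {
    v <- values[[a]]
    if (is.null(v) || a > map$k) next
    ax <- map$coords[[paste0("axis", a)]]
    keep <- !is.na(v)
    if (sum(keep) >= 3 && cor(ax[keep], v[keep]) < 0)
      map$coords[[paste0("axis", a)]] <- -ax
  }
  map
}

#' Natural-to-silhouette preference
#'
#' `NSpref = (R_nat - R_sil) / (R_nat + R_sil)`, positive for neurons
#' responding more to natural than to silhouette stimuli.
#'
#' @param r_nat,r_sil mean spike counts to natural and silhouette
#'   stimuli (vectorized).
#' @return values in `[-1, 1]`; `NA` where both means are zero.
#' @export
ns_preference <- function(r_nat, r_sil) {
  ifelse(r_nat + r_sil > 0, (r_nat - r_sil) / (r_nat + r_sil), NA_real_)
}

#' Per-neuron NS preference from a response table
#'
#' @param responses response tibble (trials) or [mean_responses()] output.
#' @param kinds tibble `stimulus_id`, `kind`.
#' @return tibble `neuron_id`, `r_natural`, `r_silhouette`, `ns_pref`.
#' @export
ns_preference_table <- function(responses, kinds) {
  if (!"rate" %in% names(responses)) responses <- mean_responses(responses)
  responses |>
    dplyr::inner_join(kinds, by = "stimulus_id") |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      r_natural = mean(.data$rate[.data$kind == "natural"]),
      r_silhouette = mean(.data$rate[.data$kind == "silhouette"]),
      .groups = "drop") |>
    dplyr::mutate(ns_pref = ns_preference(.data$r_natural, .data$r_silhouette))
}

#' Split neurons into equal-count groups along an axis
#'
#' Quantile split: group sizes differ by at most one; ties at a boundary
#' are broken by stable input order.
#'
#' @param coord per-neuron axis coordinate.
#' @param k number of groups.
#' @return integer group labels (1 = lowest coordinates) in input order.
#' @export
group_equal_count <- function(coord, k = 5) {
  n <- length(coord)
  if (n < k) cc_abort("fewer neurons than groups")
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  lab_sorted <- rep(seq_len(k), times = sizes)
  out <- integer(n)
  out[order(coord)] <- lab_sorted            # order() is stable: ties by input order
  out
}

moving_average <- function(v, span) {
  if (span <= 1) return(v)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    h <- (span - 1) / 2
    lo <- max(1, ceiling(i - h)); hi <- min(n, floor(i + h))
    mean(v[lo:hi])
  }, numeric(1))
}

#' Moving-window profile of a covariate along a map axis
#'
#' Neurons are sorted by the axis coordinate; each contiguous window of
#' `window` neurons yields the mean (or, for logical labels, the ratio)
#' of the covariate and the mean coordinate of the window. The profile
#' is then smoothed by a centred moving average of `smooth` windows, and
#' a dispersion band (window SD, similarly smoothed) is attached.
#'
#' @param coord per-neuron axis coordinate.
#' @param values per-neuron covariate: logical (ratio) or numeric (mean).
#' @param window neurons per window.
#' @param smooth moving-average span in windows (1 = no smoothing).
#' @return tibble `center` (window mean coordinate), `value` (smoothed
#'   window statistic), `raw`, `sd`, `n`.
#' @export
axis_profile <- function(coord, values, window = 30, smooth = 15) {
  n <- length(coord)
  if (n < window) cc_abort("fewer neurons than the window size")
  ord <- order(coord)
  cs <- coord[ord]; vs <- as.numeric(values)[ord]
  nw <- n - window + 1
  idx <- seq_len(window)
  center <- raw <- s <- numeric(nw)
  for (i in seq_len(nw)) {
    w <- vs[idx + i - 1L]
    center[i] <- mean(cs[idx + i - 1L])
    raw[i] <- mean(w, na.rm = TRUE)
    s[i] <- sd(w, na.rm = TRUE)
  }
  tibble::tibble(center = center, value = moving_average(raw, smooth),
                 raw = raw, sd = moving_average(s, smooth),
                 n = window)
}

#' Linear regression of a covariate on a map axis
#'
#' Ordinary least squares of the per-neuron values on the axis
#' coordinate.
#'
#' @param values per-neuron dependent variable.
#' @param coord per-neuron axis coordinate.
#' @return one-row tibble: `r_squared`, `r` (signed), `p`, `slope`,
#'   `intercept`, `n`; zero-variance input is flagged in `degenerate`.
#' @export
regress_axis <- function(values, coord) {
  keep <- !is.na(values) & !is.na(coord)
  values <- values[keep]; coord <- coord[keep]
  if (length(values) < 3) cc_abort("need >= 3 neurons")
  if (var(values) == 0 || var(coord) == 0)
    return(tibble::tibble(r_squared = NA_real_, r = NA_real_, p = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          n = length(values), degenerate = TRUE))
  fit <- lm(values ~ coord)
  sm <- summary(fit)
  slope <- coef(fit)[[2]]
  tibble::tibble(r_squared = sm$r.squared,
                 r = sign(slope) * sqrt(sm$r.squared),
                 p = sm$coefficients[2, 4],
                 slope = slope, intercept = coef(fit)[[1]],
                 n = length(values), degenerate = FALSE)
}
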