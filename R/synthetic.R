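# Synthetic study generator: contour stimuli with controlled feature
# statistics (quasi-uniform, mutually near-independent marginals), mirror
# augmentation, Poisson model neurons with known multi-feature tuning and
# a natural-vs-silhouette gain, and grating grids for CRF estimation.
#
# The stimulus families (segments and radial arms, circular arcs and
# arc arms, lassos, gentle wiggles, mirror-symmetric Vs, a few spirals)
# are parametric stand-ins for human-marked natural contours; a
# stochastic swap optimizer then picks a subset whose four-feature
# marginals are flat and pairwise decorrelated, emulating curated
# stimulus statistics.

#' Configuration of the synthetic stimulus set
#'
#' @param n_patches total stimuli including mirror variants (even).
#' @param patch_size patch side in pixels.
#' @param pool_size candidate contours generated before selection.
#' @param max_cor bound on the absolute pairwise Pearson correlation
#'   among the four features across the selected set.
#' @param flat_ratio required min/max ratio of the 10-bin marginal
#'   histograms of the selected set.
#' @param ref_sd SD (pixels) of the reference central CRF used to score
#'   candidate features during selection.
#' @param seed RNG seed.
#' @return config list.
#' @export
stimulus_set_config <- function(n_patches = 210, patch_size = 69,
                                pool_size = 2000, max_cor = 0.1,
                                flat_ratio = 0.5, ref_sd = 12, seed = 1) {
  if (n_patches %% 2 != 0) cc_abort("n_patches must be even (mirror pairs)")
  stopifnot(max_cor > 0, max_cor < 1, pool_size >= n_patches)
  list(n_patches = n_patches, patch_size = patch_size,
       pool_size = pool_size, max_cor = max_cor, flat_ratio = flat_ratio,
       ref_sd = ref_sd, seed = seed)
}

#' Reference central CRF of a stimulus set
#'
#' @param cfg [stimulus_set_config()].
#' @return `"crf"` centred on the patch with SD `ref_sd`.
#' @export
reference_crf <- function(cfg = stimulus_set_config()) {
  ctr <- (cfg$patch_size - 1) / 2
  crf_model(ctr, ctr, cfg$ref_sd, cfg$ref_sd)
}

# ---- candidate contour families ----------------------------------------
# All candidates pass within 1 px of the patch centre and stay within
# radius `rmax` of it, so that mirroring about the central tangent keeps
# them inside the patch.

rot2 <- function(x, y, th) list(x = x * cos(th) - y * sin(th),
                                y = x * sin(th) + y * cos(th))

# trim to the contiguous run of points within rmax that contains the
# point nearest the centre
trim_to_radius <- function(x, y, ctr, rmax) {
  d <- sqrt((x - ctr)^2 + (y - ctr)^2)
  ok <- d <= rmax
  i0 <- which.min(d)
  if (!ok[i0]) return(NULL)
  lo <- i0; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(x) && ok[hi + 1]) hi <- hi + 1
  list(x = x[lo:hi], y = y[lo:hi])
}

# A contour whose interior passes through the patch centre "shadows"
# about half of the radial directions, so its closure is near 0.5; low
# closure requires the contour to END at the centre (radial arms), and
# high closure a curve wrapping around the centre (spirals). The families
# below cover that geometry, plus exactly mirror-symmetric V shapes that
# populate the upper symmetry range.

cand_segment <- function(ctr, rmax, arm = FALSE) {
  th <- runif(1, 0, 2 * pi)
  if (arm) {
    L <- runif(1, 16, rmax)
    s <- seq(0.3, L, by = 1)
  } else {
    L <- runif(1, 20, 2 * rmax)
    s <- seq(-L / 2, L / 2, by = 1)
  }
  p <- rot2(s, rep(0, length(s)), th)
  list(x = p$x + ctr, y = p$y + ctr, fs = sample(c(-1L, 1L), 1))
}

cand_arc <- function(ctr, rmax, arm = FALSE) {
  # log-uniform radii from tight curls to near-straight sweeps, so every
  # squashed-curvature band is reachable by a constant-curvature contour
  r <- exp(runif(1, log(3), log(250)))
  alpha <- runif(1, 0, 2 * pi)
  span <- runif(1, 40, 360) * pi / 180
  cc <- c(ctr + r * cos(alpha), ctr + r * sin(alpha))
  t0 <- alpha + pi                                  # centre lies at angle t0
  tt <- if (arm) seq(t0, t0 + span, by = 1 / r)
        else seq(t0 - span / 2, t0 + span / 2, by = 1 / r)
  x <- cc[1] + r * cos(tt); y <- cc[2] + r * sin(tt)
  p <- trim_to_radius(x, y, ctr, rmax)
  if (is.null(p) || length(p$x) < 14) return(NULL)
  # figure inside or outside the circle, fixed by the stored sign rule
  inside <- sample(c(TRUE, FALSE), 1)
  tx <- p$x[2] - p$x[1]; ty <- p$y[2] - p$y[1]
  s_in <- sign((cc[1] - p$x[1]) * ty - (cc[2] - p$y[1]) * tx)
  fs <- as.integer(if (inside) s_in else -s_in)
  list(x = p$x, y = p$y, fs = fs)
}

cand_spiral <- function(ctr, rmax) {
  wrap <- runif(1, 0.08, 1.45) * 2 * pi
  r_end <- runif(1, 10, min(26, rmax))
  phi <- seq(0, wrap, by = 0.03)
  r <- 0.4 + (r_end - 0.4) * phi / wrap
  th0 <- runif(1, 0, 2 * pi)
  x <- ctr + r * cos(phi + th0); y <- ctr + r * sin(phi + th0)
  # enforce ~unit spacing by arc-length resampling
  p <- resample_polyline(x, y, spacing = 1)
  if (length(p$x) < 14) return(NULL)
  list(x = p$x, y = p$y, fs = sample(c(-1L, 1L), 1))
}

# gentle long-wavelength undulations: asymmetric but locally
# near-straight, so wiggles stay coherent in curvature
wiggle_offsets <- function(s) {
  off <- rep(0, length(s))
  for (k in 1:3) {
    A <- runif(1, 0.5, 3); lam <- runif(1, 25, 60); ph <- runif(1, 0, 2 * pi)
    off <- off + A * sin(2 * pi * s / lam + ph)
  }
  off
}

cand_wiggle <- function(ctr, rmax) {
  th <- runif(1, 0, pi)
  L <- runif(1, 40, 2 * rmax)
  s <- seq(-L / 2, L / 2, by = 1)
  off <- wiggle_offsets(s)
  off <- off - off[which.min(abs(s))]               # pin the centre point
  p <- rot2(s, off, th)
  p <- trim_to_radius(p$x + ctr, p$y + ctr, ctr, rmax)
  if (is.null(p) || length(p$x) < 14) return(NULL)
  list(x = p$x, y = p$y, fs = sample(c(-1L, 1L), 1))
}

# "lasso": a straight spoke from the centre joined to a constant-radius
# loop around it -- local curvature is coherent (either 0 on the spoke or
# 1/r on the loop) while the loop's wrap angle sets closure freely
cand_lasso <- function(ctr, rmax) {
  r <- runif(1, 5, min(24, rmax - 2))
  wrap <- runif(1, 0.25, 1.9) * pi
  th0 <- runif(1, 0, 2 * pi)
  spoke <- seq(0.2, r, by = 1)
  loop <- seq(0, wrap, by = 1 / r)
  x <- c(spoke * cos(th0), r * cos(th0 + loop))
  y <- c(spoke * sin(th0), r * sin(th0 + loop))
  p <- resample_polyline(x + ctr, y + ctr, spacing = 1)
  if (length(p$x) < 14) return(NULL)
  list(x = p$x, y = p$y, fs = sample(c(-1L, 1L), 1))
}

# mirror-symmetric V: a wiggly arm and its exact reflection about an axis
# through the centre
cand_symwiggle <- function(ctr, rmax) {
  th <- runif(1, 0, 2 * pi)
  L <- runif(1, 14, rmax - 1)
  s <- seq(0.3, L, by = 1)
  off <- wiggle_offsets(s) * runif(1, 0.1, 1)
  off <- off - off[1] + runif(1, 0.1, 0.6)          # arm tip within 1 px of centre
  x <- c(rev(s), s); y <- c(-rev(off), off)
  p <- rot2(x, y, th)
  p <- trim_to_radius(p$x + ctr, p$y + ctr, ctr, rmax)
  if (is.null(p) || length(p$x) < 14) return(NULL)
  list(x = p$x, y = p$y, fs = sample(c(-1L, 1L), 1))
}

make_candidate <- function(ctr, rmax) {
  fam <- sample(c("segment", "segment_arm", "arc", "arc_arm", "spiral",
                  "lasso", "wiggle", "symwiggle"), 1,
                prob = c(0.08, 0.06, 0.24, 0.16, 0.02, 0.26, 0.06, 0.12))
  p <- switch(fam,
              segment = cand_segment(ctr, rmax),
              segment_arm = cand_segment(ctr, rmax, arm = TRUE),
              arc = cand_arc(ctr, rmax),
              arc_arm = cand_arc(ctr, rmax, arm = TRUE),
              spiral = cand_spiral(ctr, rmax),
              lasso = cand_lasso(ctr, rmax),
              wiggle = cand_wiggle(ctr, rmax),
              symwiggle = cand_symwiggle(ctr, rmax))
  if (is.null(p)) return(NULL)
  p$family <- fam
  p
}

# scalar features of one candidate under the reference CRF, plus its
# local-curvature histogram (20 bins on [-1, 1]) for coverage control
cand_features <- function(ct, crf, params) {
  clos <- compute_closure(ct, crf)
  curv <- compute_local_curvatures(ct, crf, params)
  ori <- compute_orientation(ct, crf)
  sym <- as.numeric(compute_symmetry(ct))
  list(f = c(closure = clos,
             curvature = if (nrow(curv)) mean(curv$value) else NA_real_,
             symmetry = sym, orientation = as.numeric(ori)),
       lh = tabulate(bin_index(curv$value, seq(-1, 1, length.out = 21)), 20L))
}

hist10 <- function(v, lo, hi) tabulate(pmin(pmax(
  findInterval(v, seq(lo, hi, length.out = 11), rightmost.closed = TRUE),
  1L), 10L), 10L)

# selection objective: flat 10-bin marginals, decorrelated pairs, and no
# under-populated bands in the pooled local-curvature histogram (a band
# owned by one stimulus would make that tuning-map bin a copy of a
# single neuron-stimulus response). Symmetry is min-max normalized
# within the current selection, mirroring how the feature is reported.
selection_state <- function(F, lhist, min_local = 30) {
  Fs <- F
  Fs[, "symmetry"] <- normalize_symmetry(F[, "symmetry"])
  cors <- cor(Fs)
  mc <- max(abs(cors[upper.tri(cors)]))
  doms <- list(closure = c(0, 1), curvature = c(-1, 1),
               symmetry = c(0, 1), orientation = c(0, 180))
  ratios <- vapply(colnames(Fs), function(f) {
    h <- hist10(Fs[, f], doms[[f]][1], doms[[f]][2])
    min(h) / max(h)
  }, numeric(1))
  flat_pen <- sum(vapply(colnames(Fs), function(f) {
    h <- hist10(Fs[, f], doms[[f]][1], doms[[f]][2])
    sum((h - mean(h))^2) / (mean(h)^2)
  }, numeric(1)))
  cor_pen <- sum(pmax(0, abs(cors[upper.tri(cors)]) - 0.06)^2)
  hole_pen <- sum((pmax(0, min_local - lhist) / min_local)^2)
  list(max_cor = mc, ratios = ratios, min_local = min(lhist),
       objective = flat_pen + 4000 * cor_pen + 50 * hole_pen)
}

#' Generate the synthetic contour stimulus set
#'
#' Samples a large pool of parametric contour candidates, scores the four
#' features of each (and of its mirror variant) under the reference
#' central CRF, and selects `n_patches / 2` originals by stochastic swap
#' optimization so the selected set (originals plus mirrors) has flat
#' 10-bin feature marginals and all pairwise feature correlations within
#' `max_cor`.
#'
#' @param cfg [stimulus_set_config()].
#' @param params [curvature_params()] used for the candidate scoring.
#' @param max_iter swap-optimization iterations.
#' @return list: `contours` (tidy contour tibble of all `n_patches`
#'   stimuli), `features` (per-stimulus tibble of the four scalar
#'   features under the reference CRF, symmetry normalized), `config`.
#' @export
generate_contours <- function(cfg = stimulus_set_config(),
                              params = curvature_params(),
                              max_iter = 30000) {
  set.seed(cfg$seed)
  ctr <- (cfg$patch_size - 1) / 2
  rmax <- ctr - 2.5                                  # mirror-safe radius
  crf <- reference_crf(cfg)
  pool <- list(); featsO <- list(); featsM <- list()
  tries <- 0L
  while (length(pool) < cfg$pool_size && tries < 40L * cfg$pool_size) {
    tries <- tries + 1L
    p <- make_candidate(ctr, rmax)
    if (is.null(p)) next
    ct <- contour_tbl(paste0("cand", length(pool) + 1L), p$x, p$y,
                      figure_side = p$fs, patch_size = cfg$patch_size)
    fo <- cand_features(ct, crf, params)
    if (anyNA(fo$f)) next
    mr <- mirror_contours(ct)
    fm <- cand_features(mr, crf, params)
    if (anyNA(fm$f)) next
    pool[[length(pool) + 1L]] <- list(ct = ct, mr = mr, family = p$family)
    featsO[[length(pool)]] <- fo
    featsM[[length(pool)]] <- fm
  }
  if (length(pool) < cfg$pool_size)
    cc_abort("candidate generation starved; relax family constraints")
  FO <- do.call(rbind, lapply(featsO, `[[`, "f"))
  FM <- do.call(rbind, lapply(featsM, `[[`, "f"))
  # mirroring preserves signed local curvature, so each selected patch
  # contributes its histogram twice
  LH <- do.call(rbind, lapply(featsO, `[[`, "lh"))

  n_half <- cfg$n_patches / 2
  # local-curvature coverage floor, scaled to the set size
  min_local <- max(4, min(30, round(0.15 * cfg$n_patches)))
  sel <- sample.int(length(pool), n_half)
  Fsel <- rbind(FO[sel, , drop = FALSE], FM[sel, , drop = FALSE])
  lsel <- 2 * colSums(LH[sel, , drop = FALSE])
  st <- selection_state(Fsel, lsel, min_local)
  target_cor <- min(0.095, cfg$max_cor * 0.95)
  target_ratio <- max(0.55, cfg$flat_ratio * 1.1)
  for (it in seq_len(max_iter)) {
    if (st$max_cor <= target_cor && all(st$ratios >= target_ratio) &&
        st$min_local >= min_local) break
    i <- sample.int(n_half, 1)
    j <- sample.int(length(pool), 1)
    if (j %in% sel) next
    Fnew <- Fsel
    Fnew[i, ] <- FO[j, ]; Fnew[n_half + i, ] <- FM[j, ]
    lnew <- lsel + 2 * (LH[j, ] - LH[sel[i], ])
    st_new <- selection_state(Fnew, lnew, min_local)
    if (st_new$objective < st$objective) {
      sel[i] <- j; Fsel <- Fnew; lsel <- lnew; st <- st_new
    }
  }
  if (st$max_cor > cfg$max_cor || any(st$ratios < cfg$flat_ratio))
    cc_abort(paste0(
      "stimulus selection could not satisfy the feature-statistics ",
      "targets (max |R| = ", signif(st$max_cor, 3), ", min flatness ratio = ",
      signif(min(st$ratios), 3), "); increase pool_size"))

  ids <- sprintf("s%03d", seq_len(n_half))
  contours <- dplyr::bind_rows(lapply(seq_along(sel), function(k) {
    ct <- pool[[sel[k]]]$ct
    ct$stimulus_id <- ids[k]
    mr <- pool[[sel[k]]]$mr
    mr$stimulus_id <- paste0(ids[k], "_m")
    dplyr::bind_rows(ct, mr)
  }))
  Ford <- rbind(FO[sel, , drop = FALSE], FM[sel, , drop = FALSE])
  feat <- tibble::tibble(
    stimulus_id = c(ids, paste0(ids, "_m")),
    is_mirror = rep(c(FALSE, TRUE), each = n_half),
    family = rep(vapply(pool[sel], `[[`, character(1), "family"), 2),
    closure = Ford[, "closure"],
    curvature = Ford[, "curvature"],
    symmetry = normalize_symmetry(Ford[, "symmetry"]),
    orientation = Ford[, "orientation"])
  # interleave originals and mirrors in id order
  ord <- order(feat$stimulus_id)
  feat <- feat[ord, ]
  validate_contours(contours)
  list(contours = contours, features = feat, config = cfg)
}

# ---- model neurons ------------------------------------------------------

# Kernel families mirror the tuning models fitted downstream: Gaussian
# over closure/symmetry, unit-frequency cosine over curvature (feature
# units are radians-like on [-1, 1]) and over orientation (degrees
# mapped to radians), so a tuned neuron's map is of the fitted form. The
# multi-valued curvature feature is averaged over the contour's local
# curvatures. Each kernel's values are affinely rescaled to span [0, 1]
# across the stimulus ensemble before combination, so `gain` is the
# peak-above-baseline modulation every tuned neuron actually expresses
# over the stimuli it is shown -- without this, broad kernels (the unit-
# frequency cosine in particular) barely modulate across the ensemble
# and planted tuning would be undetectable by construction. With
# combine = "product" the rescaled kernels multiply (conjunctive
# selectivity, troughs at baseline); "sum" averages them.
kernel_drive <- function(kern, rows, combine = "product") {
  ns <- length(rows)
  if (length(kern) == 0) return(rep(1, ns))
  KM <- vapply(names(kern), function(f) {
    k <- kern[[f]]
    v <- vapply(rows, function(row) {
      x <- row[[f]]
      mean(switch(k$family,
        gaussian = exp(-(x - k$peak)^2 / k$width^2),
        cosine = (1 + cos(k$scale * (x - k$peak))) / 2))
    }, numeric(1))
    rng <- range(v)
    if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(1, ns)
  }, numeric(ns))
  KM <- matrix(KM, nrow = ns)
  if (combine == "product") apply(KM, 1, prod) else rowMeans(KM)
}

#' Generate a population of Poisson model neurons
#'
#' Each neuron has its own CRF (centre jittered around the patch centre,
#' SDs drawn uniformly), a set of tuned features with Gaussian kernels
#' (closure, symmetry) or raised-cosine kernels (curvature, orientation),
#' multiplicative kernel combination, a firing gain and baseline, and a
#' natural-to-silhouette gain. The composition mixes untuned,
#' single-feature and multi-feature neurons so pipeline recovery can be
#' checked against known labels.
#'
#' @param n_neurons population size.
#' @param patch_size stimulus patch size in pixels.
#' @param p_untuned,p_single,p_multi mixture proportions.
#' @param combine kernel combination rule for multi-feature neurons:
#'   `"product"` (default; conjunctive selectivity, which keeps each
#'   per-feature map's trough near the baseline as the offset-free
#'   Gaussian tuning model assumes) or `"sum"` (independent additive
#'   drives, which put the other features' mean drive under every map
#'   as a pedestal).
#' @param gain,baseline expected spikes at the kernel peak / floor.
#' @param ns_gain_sd SD of the log-normal natural-kind gain (0 disables).
#'   Kept moderate so the shared natural/silhouette geometry does not
#'   build a deterministic response structure that would break the
#'   exchangeability the permutation tests rest on.
#' @param seed RNG seed.
#' @return tibble: `neuron_id`, `type`, `n_tuned`, `tuned` (list of
#'   feature names), `kernels` (list), `crf` (list of `"crf"`), `gain`,
#'   `baseline`, `ns_gain`.
#' @export
neuron_population <- function(n_neurons = 72, patch_size = 69,
                              p_untuned = 1/3, p_single = 1/3, p_multi = 1/3,
                              gain = 12, baseline = 0.5,
                              ns_gain_sd = 0.15, combine = c("product", "sum"),
                              seed = 1) {
  combine <- match.arg(combine)
  set.seed(seed)
  ctr <- (patch_size - 1) / 2
  feats <- c("closure", "curvature", "symmetry", "orientation")
  rows <- lapply(seq_len(n_neurons), function(i) {
    type <- sample(c("untuned", "single", "multi"), 1,
                   prob = c(p_untuned, p_single, p_multi))
    n_tuned <- switch(type, untuned = 0L, single = 1L,
                      multi = sample(2:3, 1, prob = c(0.8, 0.2)))
    tuned <- if (n_tuned > 0) sample(feats, n_tuned) else character(0)
    kerns <- lapply(setNames(tuned, tuned), function(f) {
      if (f %in% c("closure", "symmetry"))
        list(family = "gaussian", peak = runif(1, 0.15, 0.95),
             width = runif(1, 0.18, 0.3))
      else if (f == "curvature")
        # acute-curvature preference dominates in mid-level visual cortex;
        # peaks drawn away
        # from zero also give maps the monotone/dent shapes the
        # unit-frequency cosine fits cleanly
        list(family = "cosine",
             peak = sample(c(-1, 1), 1) * runif(1, 0.5, 0.95), scale = 1)
      else
        list(family = "cosine", peak = runif(1, 0, 180), scale = pi / 180)
    })
    crf <- crf_model(ctr + runif(1, -3, 3), ctr + runif(1, -3, 3),
                     runif(1, 9, 14), runif(1, 9, 14),
                     amplitude = gain, baseline = baseline)
    tibble::tibble(
      neuron_id = sprintf("n%03d", i), type = type, n_tuned = n_tuned,
      tuned = list(tuned), kernels = list(kerns), crf = list(crf),
      combine = combine, gain = gain, baseline = baseline,
      ns_gain = exp(rnorm(1, 0, ns_gain_sd)))
  })
  dplyr::bind_rows(rows)
}

#' Presentation table for a generated contour set
#'
#' Every contour is presented both as a natural patch and as its
#' silhouette; presentations get distinct stimulus ids.
#'
#' @param contour_ids contour identifiers.
#' @return tibble `stimulus_id`, `contour_id`, `kind`.
#' @export
presentation_table <- function(contour_ids) {
  tidyr::expand_grid(contour_id = contour_ids,
                     kind = c("natural", "silhouette")) |>
    dplyr::mutate(stimulus_id = paste0(.data$contour_id, ".",
                                       substr(.data$kind, 1, 3)),
                  .before = 1)
}

#' Expand per-contour features to per-presentation rows
#'
#' Natural and silhouette presentations of a contour share its geometry,
#' hence its features; this re-keys a feature table from contour ids to
#' presentation ids so it joins against a response table.
#'
#' @param features feature table keyed by contour id in `stimulus_id`.
#' @param presentations tibble from [presentation_table()].
#' @return feature tibble keyed by presentation id (column `kind` added).
#' @export
expand_features <- function(features, presentations) {
  pres <- dplyr::select(presentations, pres_id = "stimulus_id",
                        stimulus_id = "contour_id", "kind")
  out <- dplyr::inner_join(features, pres, by = "stimulus_id",
                           relationship = "many-to-many")
  out$contour_id <- out$stimulus_id
  out$stimulus_id <- out$pres_id
  out$pres_id <- NULL
  out
}

#' Simulate spike-count responses of model neurons
#'
#' Expected rate per presentation is
#' `baseline + gain * K(features) * drive * (ns_gain if natural)`, where
#' `K` is the product of the neuron's feature kernels evaluated on the
#' per-(neuron, contour) feature values and `drive` is a per-presentation
#' log-normal factor (SD `drive_sd` on the log scale, unit mean)
#' emulating stimulus-to-stimulus response variability beyond Poisson
#' noise -- texture and surface content that the contour features do not
#' capture. Missing feature values are imputed with the across-contour
#' median so an unestimable feature exerts a neutral drive. Counts are
#' Poisson per trial; negative expected rates cannot arise (kernels are
#' non-negative).
#'
#' @param neurons tibble from [neuron_population()].
#' @param presentations tibble from [presentation_table()].
#' @param features per-(neuron, contour) feature table under each
#'   neuron's own CRF ([compute_features()]; `stimulus_id` holds the
#'   contour id) -- or the generator's per-contour feature tibble, which
#'   is then shared by all neurons.
#' @param trials trials per presentation.
#' @param drive_sd log-scale SD of the per-presentation drive factor.
#' @param seed RNG seed.
#' @return response tibble (`neuron_id`, `stimulus_id`, `trial`, `count`)
#'   with attribute `"expected"` (tibble of expected rates).
#' @export
simulate_responses <- function(neurons, presentations, features,
                               trials = 10, drive_sd = 0.25, seed = 1) {
  set.seed(seed)
  per_neuron <- "neuron_id" %in% names(features)
  fcols <- c("closure", "curvature", "symmetry", "orientation")
  if (!"curvature" %in% names(features) && "curvature_mean" %in% names(features))
    features$curvature <- features$curvature_mean
  has_locals <- "curvatures" %in% names(features)
  meds <- vapply(fcols, function(f) median(features[[f]], na.rm = TRUE),
                 numeric(1))
  out <- vector("list", nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    nr <- neurons[i, ]
    fx <- if (per_neuron)
      features[features$neuron_id == nr$neuron_id, ] else features
    fx <- fx[match(presentations$contour_id, fx$stimulus_id), ]
    rows <- lapply(seq_len(nrow(fx)), function(s) {
      row <- lapply(setNames(fcols, fcols), function(f) {
        v <- fx[[f]][s]
        if (is.na(v)) meds[[f]] else v
      })
      if (has_locals && length(fx$curvatures[[s]]))
        row$curvature <- fx$curvatures[[s]]
      row
    })
    K <- kernel_drive(nr$kernels[[1]], rows, nr$combine %||% "product")
    drive <- exp(rnorm(nrow(presentations), 0, drive_sd) - drive_sd^2 / 2)
    lambda <- nr$baseline + nr$gain * K * drive *
      ifelse(presentations$kind == "natural", nr$ns_gain, 1)
    cnt <- rpois(length(lambda) * trials, rep(lambda, each = trials))
    out[[i]] <- tibble::tibble(
      neuron_id = nr$neuron_id,
      stimulus_id = rep(presentations$stimulus_id, each = trials),
      trial = rep(seq_len(trials), times = length(lambda)),
      count = cnt,
      expected = rep(lambda, each = trials))
  }
  res <- dplyr::bind_rows(out)
  expected <- dplyr::distinct(res, .data$neuron_id, .data$stimulus_id,
                              .data$expected)
  res$expected <- NULL
  attr(res, "expected") <- expected
  res
}

#' Simulate a grating-patch response grid for CRF estimation
#'
#' Responses are the neuron's Gaussian RF profile evaluated at the grid
#' positions, averaged over `n_rep` Poisson repeats (or noiseless).
#'
#' @param crf the neuron's true `"crf"` (amplitude/baseline used as the
#'   expected response profile).
#' @param grid_x,grid_y grid coordinate vectors (default 5 x 5 covering
#'   the patch).
#' @param n_rep repeats per position.
#' @param noise Poisson noise (`FALSE` gives expected values).
#' @param seed RNG seed.
#' @return tibble `x`, `y`, `response`.
#' @export
simulate_grating_grid <- function(crf, grid_x = NULL, grid_y = NULL,
                                  n_rep = 10, noise = TRUE, seed = 1) {
  grid_x <- grid_x %||% seq(crf$center[1] - 24, crf$center[1] + 24,
                            length.out = 5)
  grid_y <- grid_y %||% seq(crf$center[2] - 24, crf$center[2] + 24,
                            length.out = 5)
  g <- tidyr::expand_grid(x = grid_x, y = grid_y)
  lam <- crf_predict(c(cx = unname(crf$center[1]), cy = unname(crf$center[2]),
                       sx = unname(crf$sd[1]), sy = unname(crf$sd[2]),
                       amp = crf$amplitude, base = crf$baseline),
                     g$x, g$y)
  if (noise) {
    set.seed(seed)
    g$response <- vapply(lam, function(l) mean(rpois(n_rep, l)), numeric(1))
  } else {
    g$response <- lam
  }
  g
}

#' Simulate the full synthetic study
#'
#' Generates the stimulus set once, a neuron population, per-neuron
#' features under each neuron's own CRF, and Poisson responses to every
#' presentation (natural and silhouette of each contour).
#'
#' @param cfg [stimulus_set_config()].
#' @param n_neurons population size.
#' @param trials trials per presentation.
#' @param drive_sd per-presentation drive variability
#'   ([simulate_responses()]).
#' @param seed seed for the neuron population and spiking (the stimulus
#'   set uses `cfg$seed`).
#' @param stimuli optionally reuse a previously generated
#'   [generate_contours()] result.
#' @param per_neuron_features compute features under each neuron's own
#'   CRF (`TRUE`, slower) or share the reference-CRF features (`FALSE`).
#' @param ... passed to [neuron_population()].
#' @return list: `stimuli` (generator output), `presentations`,
#'   `neurons`, `features` (per neuron x contour when
#'   `per_neuron_features`), `responses`.
#' @export
simulate_study <- function(cfg = stimulus_set_config(), n_neurons = 72,
                           trials = 10, drive_sd = 0.25, seed = 1,
                           stimuli = NULL, per_neuron_features = TRUE, ...) {
  stimuli <- stimuli %||% generate_contours(cfg)
  pres <- presentation_table(unique(stimuli$features$stimulus_id))
  neurons <- neuron_population(n_neurons = n_neurons,
                               patch_size = cfg$patch_size,
                               seed = seed, ...)
  if (per_neuron_features) {
    crfs <- setNames(neurons$crf, neurons$neuron_id)
    feats <- compute_features(stimuli$contours, crfs)
    feats$curvature <- feats$curvature_mean
  } else {
    feats <- stimuli$features
  }
  responses <- simulate_responses(neurons, pres, feats, trials = trials,
                                  drive_sd = drive_sd, seed = seed + 1L)
  list(stimuli = stimuli, presentations = pres, neurons = neurons,
       features = feats, responses = responses)
}
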