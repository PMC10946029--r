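# Contour data model and readers/writers.
#
# A contour set is an ordinary tibble with one row per contour point:
#   stimulus_id  identifier shared by all points of a contour
#   idx          point order along the polyline (1-based)
#   x, y         0-based pixel coordinates, x rightward, y downward
#   figure_side  +1 / -1: sign s such that s * (ty, -tx) -- the screen-left
#                normal of the local tangent (tx, ty) -- points toward the
#                figure region
#   is_mirror    whether the contour is a mirror-augmented variant
#   patch_size   patch side length in pixels (default 69)

#' Build a contour tibble from point coordinates
#'
#' @param stimulus_id single identifier for the contour.
#' @param x,y numeric vectors of pixel coordinates (0-based, equal length).
#' @param figure_side +1 or -1; sign of the figure-pointing normal (see
#'   [figure_side_from_probe()] to derive it from a known figure point).
#' @param is_mirror logical flag for mirror-augmented variants.
#' @param patch_size patch side length in pixels.
#' @return A tibble with one row per point.
#' @export
contour_tbl <- function(stimulus_id, x, y, figure_side = 1L,
                        is_mirror = FALSE, patch_size = 69L) {
  stopifnot(length(x) == length(y), length(stimulus_id) == 1)
  if (!figure_side %in% c(-1L, 1L)) cc_abort("figure_side must be +1 or -1")
  tibble::tibble(
    stimulus_id = as.character(stimulus_id),
    idx = seq_along(x),
    x = as.numeric(x), y = as.numeric(y),
    figure_side = as.integer(figure_side),
    is_mirror = isTRUE(is_mirror),
    patch_size = as.integer(patch_size)
  )
}

#' Validate a contour set
#'
#' Checks the structural invariants every downstream stage relies on: at
#' least two points per contour, all points inside the patch, the polyline
#' passing within `center_tol` pixels of the patch centre, and finite
#' coordinates in stored order.
#'
#' @param contours contour tibble (see [contour_tbl()]).
#' @param center_tol maximum allowed distance (pixels) from the patch
#'   centre to the nearest contour point.
#' @return `contours`, invisibly; errors describe the offending contour.
#' @export
validate_contours <- function(contours, center_tol = 1) {
  req <- c("stimulus_id", "idx", "x", "y", "figure_side", "is_mirror", "patch_size")
  miss <- setdiff(req, names(contours))
  if (length(miss)) cc_abort(paste0("missing contour columns: ",
                                    paste(miss, collapse = ", ")))
  if (any(!is.finite(contours$x)) || any(!is.finite(contours$y)))
    cc_abort("non-finite contour coordinates")
  bad <- contours |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      patch = .data$patch_size[1],
      ctr = (.data$patch_size[1] - 1) / 2,
      inside = all(.data$x >= 0 & .data$x <= .data$patch - 1 &
                     .data$y >= 0 & .data$y <= .data$patch - 1),
      d_center = min(sqrt((.data$x - .data$ctr)^2 + (.data$y - .data$ctr)^2)),
      ordered = all(diff(.data$idx) == 1),
      fs_ok = all(.data$figure_side %in% c(-1L, 1L)),
      .groups = "drop"
    )
  for (i in seq_len(nrow(bad))) {
    id <- bad$stimulus_id[i]
    if (bad$n[i] < 2) cc_abort(paste0("contour ", id, ": fewer than 2 points"))
    if (!bad$inside[i]) cc_abort(paste0("contour ", id, ": points outside the patch"))
    if (bad$d_center[i] > center_tol)
      cc_abort(paste0("contour ", id, ": misses the patch center by ",
                      signif(bad$d_center[i], 3), " px (> ", center_tol, ")"))
    if (!bad$ordered[i]) cc_abort(paste0("contour ", id, ": point order not consecutive"))
    if (!bad$fs_ok[i]) cc_abort(paste0("contour ", id, ": invalid figure_side"))
  }
  invisible(contours)
}

#' Read / write contour sets
#'
#' Contours are stored as delimited text, one point per row, with the
#' per-contour metadata repeated in columns.
#'
#' @param path CSV file path.
#' @return `read_contours()` returns a validated contour tibble.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) cc_abort(paste0("no such file: ", path))
  ct <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          stimulus_id = readr::col_character(),
                          idx = readr::col_integer(),
                          x = readr::col_double(),
                          y = readr::col_double(),
                          figure_side = readr::col_integer(),
                          is_mirror = readr::col_logical(),
                          patch_size = readr::col_integer()
                        ))
  pr <- readr::problems(ct)
  if (nrow(pr) > 0)
    cc_abort(paste0("malformed contour record at line ", pr$row[1],
                    ": ", pr$expected[1]))
  validate_contours(ct)
  ct
}

#' @rdname read_contours
#' @param contours contour tibble.
#' @export
write_contours <- function(contours, path) {
  validate_contours(contours)
  readr::write_csv(contours, path)
  invisible(path)
}

#' Derive the figure-side sign from a point known to lie in the figure
#'
#' @param x,y contour point coordinates in order.
#' @param probe length-2 vector, a point inside the figure region.
#' @return +1 or -1, the stored sign convention of [contour_tbl()].
#' @export
figure_side_from_probe <- function(x, y, probe) {
  n <- length(x)
  d2 <- (x - probe[1])^2 + (y - probe[2])^2
  i <- which.min(d2)
  i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
  tx <- x[i1] - x[i0]; ty <- y[i1] - y[i0]
  s <- sign((probe[1] - x[i]) * ty - (probe[2] - y[i]) * tx)
  if (s == 0) cc_abort("probe point lies on the contour tangent; move it")
  as.integer(s)
}

# internal: unit tangent at point i of a polyline (central differences)
polyline_tangent <- function(x, y, i) {
  n <- length(x)
  i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
  v <- c(x[i1] - x[i0], y[i1] - y[i0])
  v / sqrt(sum(v^2))
}

#' Mirror contours about the central tangent
#'
#' Each contour is reflected about the line through its point nearest the
#' patch centre, directed along the local tangent -- the augmentation used
#' to balance orientation statistics. Reflection is an exact involution:
#' mirroring twice returns the original point list. The figure-side sign is
#' flipped so the stored convention keeps pointing at the mirrored figure.
#'
#' @param contours contour tibble.
#' @param suffix appended to `stimulus_id` of mirrored contours.
#' @return contour tibble of the mirrored variants (`is_mirror = TRUE`).
#' @export
mirror_contours <- function(contours, suffix = "_m") {
  contours |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::group_map(function(g, key) {
      ctr <- (g$patch_size[1] - 1) / 2
      i <- which.min((g$x - ctr)^2 + (g$y - ctr)^2)
      t <- polyline_tangent(g$x, g$y, i)
      p0 <- c(g$x[i], g$y[i])
      vx <- g$x - p0[1]; vy <- g$y - p0[2]
      dot <- vx * t[1] + vy * t[2]
      tibble::tibble(
        stimulus_id = paste0(key$stimulus_id, suffix),
        idx = g$idx,
        x = p0[1] + 2 * dot * t[1] - vx,
        y = p0[2] + 2 * dot * t[2] - vy,
        figure_side = -g$figure_side,
        is_mirror = !g$is_mirror,
        patch_size = g$patch_size
      )
    }) |>
    dplyr::bind_rows()
}

#' Render a two-tone silhouette image of a contour
#'
#' Pixels are assigned to figure or ground by the sign of their offset
#' along the figure-pointing normal of the nearest contour point; the
#' figure is filled with one intensity extreme and the ground with the
#' other. Contrast is then attenuated toward the patch border with a
#' radial Gaussian envelope so the patch blends into a mid-gray surround.
#'
#' @param contour contour tibble rows of a single contour.
#' @param fg_polarity `"black-figure"` or `"white-figure"`.
#' @param envelope apply the peripheral contrast envelope?
#' @param envelope_sd SD (pixels) of the envelope; default `patch_size / 3`.
#' @return numeric matrix (rows = y, cols = x) of intensities in `[0, 1]`.
#' @export
render_silhouette <- function(contour,
                              fg_polarity = c("black-figure", "white-figure"),
                              envelope = TRUE, envelope_sd = NULL) {
  fg_polarity <- match.arg(fg_polarity)
  if (length(unique(contour$stimulus_id)) != 1)
    cc_abort("render_silhouette() takes a single contour")
  patch <- contour$patch_size[1]
  xs <- contour$x; ys <- contour$y
  n <- length(xs)
  if (n < 2) cc_abort("contour has fewer than 2 points")
  if (sum(sqrt(diff(xs)^2 + diff(ys)^2)) < 2)
    cc_abort("contour does not partition the patch into two regions")
  # figure-pointing normals at every contour point
  i0 <- pmax(1L, seq_len(n) - 1L); i1 <- pmin(n, seq_len(n) + 1L)
  tx <- xs[i1] - xs[i0]; ty <- ys[i1] - ys[i0]
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  nx <- contour$figure_side * ty
  ny <- -contour$figure_side * tx
  gx <- rep(0:(patch - 1), times = patch)           # x for col-major (y fast)
  gy <- rep(0:(patch - 1), each = patch)
  # nearest contour point per pixel (points are ~1 px apart)
  d2 <- outer(gx, xs, `-`)^2 + outer(gy, ys, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  s <- (gx - xs[nearest]) * nx[nearest] + (gy - ys[nearest]) * ny[nearest]
  figure <- s > 0
  if (all(figure) || all(!figure))
    cc_abort("contour does not partition the patch into two regions")
  val <- if (fg_polarity == "black-figure") ifelse(figure, 0, 1) else ifelse(figure, 1, 0)
  if (envelope) {
    ctr <- (patch - 1) / 2
    esd <- envelope_sd %||% (patch / 3)
    env <- exp(-((gx - ctr)^2 + (gy - ctr)^2) / (2 * esd^2))
    val <- 0.5 + (val - 0.5) * env
  }
  matrix(val, nrow = patch, ncol = patch, byrow = TRUE)
}

#' Read / write spike-count tables
#'
#' A response table has one row per (neuron, stimulus, trial) with a
#' non-negative integer spike count.
#'
#' @param path CSV file path.
#' @return `read_responses()` returns a validated tibble sorted by neuron,
#'   stimulus, trial.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) cc_abort(paste0("no such file: ", path))
  rt <- readr::read_csv(path, show_col_types = FALSE)
  validate_responses(rt)
}

#' @rdname read_responses
#' @param responses response tibble.
#' @export
write_responses <- function(responses, path) {
  validate_responses(responses)
  readr::write_csv(responses, path)
  invisible(path)
}

#' @rdname read_responses
#' @export
validate_responses <- function(responses) {
  req <- c("neuron_id", "stimulus_id", "trial", "count")
  miss <- setdiff(req, names(responses))
  if (length(miss))
    cc_abort(paste0("missing response columns: ", paste(miss, collapse = ", ")))
  if (any(!is.finite(responses$count)) || any(responses$count < 0))
    cc_abort("spike counts must be non-negative")
  key <- paste(responses$neuron_id, responses$stimulus_id, responses$trial)
  if (anyDuplicated(key))
    cc_abort(paste0("duplicate (neuron, stimulus, trial) entry: ",
                    key[which(duplicated(key))[1]]))
  responses |>
    dplyr::mutate(neuron_id = as.character(.data$neuron_id),
                  stimulus_id = as.character(.data$stimulus_id)) |>
    dplyr::arrange(.data$neuron_id, .data$stimulus_id, .data$trial)
}

#' Trial-averaged mean spike counts
#'
#' @param responses response tibble.
#' @return tibble with one row per (neuron, stimulus) and column `rate`,
#'   the mean spike count across trials.
#' @export
mean_responses <- function(responses) {
  responses |>
    dplyr::group_by(.data$neuron_id, .data$stimulus_id) |>
    dplyr::summarise(rate = mean(.data$count), n_trials = dplyr::n(),
                     .groups = "drop")
}
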