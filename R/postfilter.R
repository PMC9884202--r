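#' Nearest-neighbour outlier filter
#'
#' For each localization, the mean distance to its first `m` nearest
#' neighbours is compared with the median of those means over all
#' localizations; localizations whose mean exceeds `multiplier` times the
#' median are discarded as significant outliers. When the feature matrix is
#' available its first `m` distance columns are reused instead of recomputing
#' neighbours.
#'
#' @param locs Localization tibble with `x`/`y` columns.
#' @param m Neighbour count (default 10).
#' @param multiplier Outlier threshold as a multiple of the median (default 5).
#' @param nn_means Optional precomputed per-localization mean of the first `m`
#'   neighbour distances (e.g. `rowMeans` of the first `m` feature columns).
#' @return List with `kept` and `discarded` localization tibbles. With fewer
#'   than `m + 1` rows the stage is skipped with a warning and everything is
#'   kept.
#' @export
nn_outlier_filter <- function(locs, m = 10, multiplier = 5, nn_means = NULL) {
  if (nrow(locs) < m + 1) {
    warn("fewer than m + 1 localizations; nearest-neighbour filter skipped")
    return(list(kept = locs, discarded = locs[0, , drop = FALSE]))
  }
  if (is.null(nn_means)) {
    nn_means <- as.numeric(knn_mean_dist_cpp(locs$x, locs$y, as.integer(m)))
  } else if (length(nn_means) != nrow(locs)) {
    abort("`nn_means` length must match rows of `locs`",
      class = "sarcloc_parameter_error"
    )
  }
  med <- median(nn_means)
  keep <- nn_means <= multiplier * med
  list(
    kept = locs[keep, , drop = FALSE],
    discarded = locs[!keep, , drop = FALSE]
  )
}

#' DBSCAN cluster labels
#'
#' Standard density-based clustering (Euclidean): a point is core when its
#' closed eps-neighbourhood holds at least `min_pts` points (itself included);
#' clusters are numbered in order of the first core point by row index, and
#' unreachable points are labelled 0.
#'
#' @param locs Localization tibble with `x`/`y` columns.
#' @param eps Neighbourhood radius, nm (default 50).
#' @param min_pts Core-point threshold (default 5).
#' @return `locs` with an integer `.cluster` column (0 = DBSCAN noise).
#' @export
dbscan_clusters <- function(locs, eps = 50, min_pts = 5) {
  check_number(eps, "eps", 0, strict = TRUE)
  check_number(min_pts, "min_pts", 1)
  locs$.cluster <- as.integer(
    dbscan_cpp(locs$x, locs$y, eps, as.integer(min_pts))
  )
  locs
}

#' Keep the largest DBSCAN cluster as the double-line object
#'
#' Clusters the localizations at (`eps`, `min_pts`) and keeps the cluster
#' with the most members — at the chosen scale one double-line object groups
#' into a single cluster, while adjacent dense regions split off. Ties go to
#' the lowest cluster label (i.e. the cluster whose first point comes first).
#'
#' @inheritParams dbscan_clusters
#' @return List: `object` (kept tibble), `discarded` (smaller clusters and
#'   DBSCAN-noise points), `cluster_label`, `hull` (one-row tibble with
#'   convex-hull `perimeter` and `area`). Signals `sarcloc_no_cluster` when
#'   no cluster forms.
#' @export
dbscan_largest <- function(locs, eps = 50, min_pts = 5) {
  labelled <- dbscan_clusters(locs, eps, min_pts)
  cl <- labelled$.cluster
  if (all(cl == 0)) {
    abort("no DBSCAN cluster formed; object rejected",
      class = "sarcloc_no_cluster"
    )
  }
  counts <- tabulate(cl[cl > 0])
  best <- which.max(counts) # first maximum = lowest label
  keep <- cl == best
  kept <- locs[keep, , drop = FALSE]
  list(
    object = kept,
    discarded = locs[!keep, , drop = FALSE],
    cluster_label = best,
    hull = convex_hull_stats(kept)
  )
}

#' Convex hull perimeter and area of a point set
#'
#' Degenerate (collinear) inputs get area 0 and perimeter twice the maximum
#' pairwise distance (the hull collapses to a doubly-traversed segment).
#'
#' @param points Data frame with `x`/`y` columns or a 2-column matrix, nm.
#' @return One-row tibble: `perimeter` (nm), `area` (nm^2).
#' @export
convex_hull_stats <- function(points) {
  xy <- coord_matrix(points)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 2) {
    abort("need at least 2 points for hull statistics",
      class = "sarcloc_parameter_error"
    )
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]
  hy <- xy[h, 2]
  nh <- length(h)
  area <- if (nh >= 3) {
    abs(sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)) / 2
  } else {
    0
  }
  if (area == 0) {
    per <- 2 * max(stats::dist(xy))
  } else {
    per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  }
  tibble(perimeter = per, area = area)
}

#' Thompson localization precision
#'
#' Closed-form localization uncertainty of a fitted Gaussian spot:
#' `sqrt(s^2/N + a^2/(12 N) + 8 pi s^4 b^2 / (a^2 N^2))` with fitted width
#' `s`, photon count `N`, pixel size `a` and background noise `b` per pixel.
#'
#' @param sigma Fitted Gaussian width, nm.
#' @param photons Photon count.
#' @param pixel_size Camera pixel size, nm (default 160).
#' @param background Background noise per pixel, photons (default 0).
#' @return Precision in nm (vectorized).
#' @export
thompson_precision <- function(sigma, photons, pixel_size = 160,
                               background = 0) {
  if (any(sigma <= 0) || any(photons <= 0) || any(pixel_size <= 0) ||
    any(background < 0)) {
    abort("sigma, photons, pixel_size must be > 0 and background >= 0",
      class = "sarcloc_parameter_error"
    )
  }
  sqrt(
    sigma^2 / photons + pixel_size^2 / (12 * photons) +
      8 * pi * sigma^4 * background^2 / (pixel_size^2 * photons^2)
  )
}

# invert the Thompson relation: photon count giving a target precision
solve_photons <- function(precision, sigma, pixel_size = 160, background = 0) {
  a_term <- sigma^2 + pixel_size^2 / 12
  c_term <- 8 * pi * sigma^4 * background^2 / pixel_size^2
  (a_term + sqrt(a_term^2 + 4 * precision^2 * c_term)) / (2 * precision^2)
}

#' Fit-quality filter on sigma and localization precision
#'
#' Keeps localizations whose fitted Gaussian width lies inside `sigma_range`
#' (closed interval; the window rejects overlapping blinking events) and
#' whose localization precision is at most `precision_max`. When the
#' `precision` column is absent it is computed from `sigma` and `photons`
#' via [thompson_precision()].
#'
#' @param locs Localization tibble with `sigma` and `precision` (or `sigma`
#'   plus `photons`) columns.
#' @param sigma_range Closed interval for sigma, nm (default `c(112, 160)`).
#' @param precision_max Inclusive precision threshold, nm (default 20).
#' @param pixel_size,background Passed to [thompson_precision()] when the
#'   precision has to be derived.
#' @return List with `kept` and `discarded` tibbles.
#' @export
quality_filter <- function(locs, sigma_range = c(112, 160), precision_max = 20,
                           pixel_size = 160, background = 0) {
  if (!"sigma" %in% names(locs)) {
    abort("missing column `sigma` (fitted Gaussian width, nm)",
      class = "sarcloc_parameter_error"
    )
  }
  if (!"precision" %in% names(locs)) {
    if (!"photons" %in% names(locs)) {
      abort(
        "missing columns: `precision`, and `photons` needed to derive it",
        class = "sarcloc_parameter_error"
      )
    }
    locs$precision <- thompson_precision(
      locs$sigma, locs$photons, pixel_size, background
    )
  }
  keep <- locs$sigma >= sigma_range[1] & locs$sigma <= sigma_range[2] &
    locs$precision <= precision_max
  list(
    kept = locs[keep, , drop = FALSE],
    discarded = locs[!keep, , drop = FALSE]
  )
}

#' Per-stage discard report
#'
#' Summarises the filter chain the way discard statistics are usually
#' reported: each stage's discard count as a fraction of the total entering
#' the classification stage, and — since overlapping conventions exist — also
#' as a fraction of that stage's own input.
#'
#' @param stage_counts Tibble with columns `stage`, `n_in`, `n_discarded`,
#'   ordered by pipeline position (classification first).
#' @return Tibble with added `ratio_of_total` and `ratio_of_stage_input`
#'   columns plus a final `kept` row.
#' @export
filter_report <- function(stage_counts) {
  stopifnot(all(c("stage", "n_in", "n_discarded") %in% names(stage_counts)))
  total <- stage_counts$n_in[1]
  kept_final <- tail(stage_counts$n_in, 1) - tail(stage_counts$n_discarded, 1)
  out <- stage_counts |>
    mutate(
      ratio_of_total = .data$n_discarded / total,
      ratio_of_stage_input = if_else(
        .data$n_in > 0, .data$n_discarded / .data$n_in, 0
      )
    )
  bind_rows(
    out,
    tibble(
      stage = "kept", n_in = kept_final, n_discarded = 0L,
      ratio_of_total = kept_final / total, ratio_of_stage_input = NA_real_
    )
  )
}

#' Refine one ROI's classifier-positive localizations into a clean object
#'
#' Runs the post-classification chain in order: nearest-neighbour outlier
#' rule, DBSCAN largest-cluster selection, then (optionally) the sigma /
#' precision quality gate. Stage counts are conserved: kept plus discarded
#' per stage equals that stage's input.
#'
#' @param locs Classifier-positive localizations of one ROI.
#' @param m,multiplier See [nn_outlier_filter()].
#' @param eps,min_pts See [dbscan_largest()].
#' @param sigma_range,precision_max See [quality_filter()]; use
#'   `quality = FALSE` to skip that gate.
#' @param quality Apply the quality filter (default TRUE). The quality gate
#'   is meant for measurement-mode data, not for simulated classifier
#'   evaluation corpora.
#' @param nn_means Optional precomputed neighbour means for the outlier rule.
#' @return List: `object` (kept tibble), `hull`, `counts` (stage-count
#'   tibble), `discarded` (named list of tibbles). `NULL` object and zero
#'   kept counts when no DBSCAN cluster forms.
#' @export
refine_object <- function(locs, m = 10, multiplier = 5, eps = 50, min_pts = 5,
                          sigma_range = c(112, 160), precision_max = 20,
                          quality = TRUE, nn_means = NULL) {
  counts <- tibble(stage = character(), n_in = integer(), n_discarded = integer())
  nn <- nn_outlier_filter(locs, m, multiplier, nn_means)
  counts <- bind_rows(counts, tibble(
    stage = "nearest_neighbour", n_in = nrow(locs),
    n_discarded = nrow(nn$discarded)
  ))
  db <- tryCatch(
    dbscan_largest(nn$kept, eps, min_pts),
    sarcloc_no_cluster = function(e) NULL
  )
  if (is.null(db)) {
    counts <- bind_rows(counts, tibble(
      stage = "dbscan", n_in = nrow(nn$kept),
      n_discarded = nrow(nn$kept)
    ))
    return(list(
      object = NULL, hull = NULL, counts = counts,
      discarded = list(nearest_neighbour = nn$discarded, dbscan = nn$kept)
    ))
  }
  counts <- bind_rows(counts, tibble(
    stage = "dbscan", n_in = nrow(nn$kept), n_discarded = nrow(db$discarded)
  ))
  obj <- db$object
  discarded <- list(
    nearest_neighbour = nn$discarded, dbscan = db$discarded
  )
  if (quality) {
    qf <- quality_filter(obj, sigma_range, precision_max)
    counts <- bind_rows(counts, tibble(
      stage = "sigma_precision", n_in = nrow(obj),
      n_discarded = nrow(qf$discarded)
    ))
    discarded$sigma_precision <- qf$discarded
    obj <- qf$kept
  }
  list(object = obj, hull = db$hull, counts = counts, discarded = discarded)
}
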