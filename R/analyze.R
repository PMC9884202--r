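#' Principal axis of a localization cloud
#'
#' The long axis of a double-line object, taken as the largest-variance
#' principal direction through the centroid. For a double-line object the
#' largest variance runs along the lines (length D), so the signed
#' perpendicular offsets from this axis separate the two lines.
#'
#' @param points Data frame with `x`/`y` columns or 2-column matrix, nm.
#' @return One-row tibble: `angle` (radians, normalized to `[-pi/2, pi/2)`),
#'   `cx`, `cy` (centroid, nm).
#' @export
fit_axis <- function(points) {
  xy <- coord_matrix(points)
  if (nrow(xy) < 10) {
    abort("need at least 10 points to fit an axis",
      class = "sarcloc_parameter_error"
    )
  }
  ev <- eigen(cov(xy), symmetric = TRUE)
  if (ev$values[2] > 0 && ev$values[1] / ev$values[2] < 1.2) {
    warn("point cloud is nearly isotropic; axis direction is poorly defined")
  }
  v <- ev$vectors[, 1]
  angle <- atan2(v[2], v[1])
  if (angle >= pi / 2) angle <- angle - pi
  if (angle < -pi / 2) angle <- angle + pi
  tibble(angle = angle, cx = mean(xy[, 1]), cy = mean(xy[, 2]))
}

# symmetric two-component Gaussian mixture negative log-likelihood
sep_nll <- function(par, t) {
  half <- abs(par[1]) / 2
  s <- exp(par[2])
  -sum(log(0.5 * dnorm(t, half, s) + 0.5 * dnorm(t, -half, s) +
    .Machine$double.xmin))
}

#' Estimate the line separation of a double-line object
#'
#' Signed perpendicular distances of the localizations from the object's long
#' axis are modelled as an equal-weight two-component Gaussian mixture with
#' means at plus/minus d/2 and a shared width, fitted by maximum likelihood;
#' the separation estimate is the distance between the component means. A
#' simplified stand-in for density-profile peak-distance readouts: the axis
#' is straight and no antibody-size/precision correction is applied.
#'
#' @param points Data frame with `x`/`y` columns (at least 30 rows).
#' @param axis Optional axis tibble from [fit_axis()]; fitted when `NULL`.
#' @return One-row tibble: `d_hat` (nm), `axis_angle` (radians), `width`
#'   (shared component sigma, nm), `n_locs`.
#' @export
estimate_separation <- function(points, axis = NULL) {
  xy <- coord_matrix(points)
  if (nrow(xy) < 30) {
    abort("need at least 30 points to estimate a separation",
      class = "sarcloc_parameter_error"
    )
  }
  if (is.null(axis)) axis <- fit_axis(points)
  nvec <- c(-sin(axis$angle), cos(axis$angle))
  t <- (xy[, 1] - axis$cx) * nvec[1] + (xy[, 2] - axis$cy) * nvec[2]

  d0 <- max(2 * mean(abs(t)), 1e-3)
  s0 <- sqrt(max(stats::var(t) - d0^2 / 4, 0.25))
  fit <- optim(
    c(d0, log(s0)), sep_nll,
    t = t, method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-10)
  )
  if (fit$convergence != 0) {
    abort(
      paste0(
        "separation fit did not converge (code ", fit$convergence,
        ", d = ", signif(abs(fit$par[1]), 5), " nm, n = ", nrow(xy), ")"
      ),
      class = "sarcloc_fit_error"
    )
  }
  tibble(
    d_hat = abs(fit$par[1]), axis_angle = axis$angle,
    width = exp(fit$par[2]), n_locs = nrow(xy)
  )
}

#' Line separations for a table of classified objects
#'
#' @param objects Localization tibble with an `object_id` column (e.g. the
#'   kept output of the filter chain).
#' @return Tibble with one row per object: `object_id`, `d_hat`,
#'   `axis_angle`, `width`, `n_locs`.
#' @export
analyze_objects <- function(objects) {
  objects |>
    dplyr::group_split(.data$object_id) |>
    purrr::map_dfr(function(grp) {
      est <- tryCatch(
        estimate_separation(grp),
        error = function(e) {
          tibble(
            d_hat = NA_real_, axis_angle = NA_real_, width = NA_real_,
            n_locs = nrow(grp)
          )
        }
      )
      dplyr::bind_cols(tibble(object_id = grp$object_id[1]), est)
    })
}
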