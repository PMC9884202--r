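#' Render localizations to a pixelated intensity image
#'
#' 2D histogram of localization coordinates at `pixel_size`, contrast-clipped
#' at an upper percentile of the non-zero pixel counts and scaled to [0, 1].
#' The first image axis is x, the second y (pixel `(1,1)` covers
#' `[origin, origin + pixel_size)` on both axes).
#'
#' @param locs Localization tibble with `x`/`y` columns (nm).
#' @param pixel_size Rendering pixel size, nm (default 100).
#' @param contrast_percentile Upper percentile (0-100) of non-zero pixel
#'   counts at which intensities are clipped.
#' @return An object of class `sarcloc_image`: list with `intensity` (matrix,
#'   x by y, clipped and scaled to [0, 1]), `counts` (raw per-pixel counts),
#'   `pixel_size`, `origin` (nm), `contrast_percentile`.
#' @export
render_image <- function(locs, pixel_size = 100, contrast_percentile = 99.5) {
  if (nrow(locs) == 0) {
    abort("cannot render an empty localization set",
      class = "sarcloc_parameter_error"
    )
  }
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  origin <- floor(c(min(locs$x), min(locs$y)) / pixel_size) * pixel_size
  ix <- floor((locs$x - origin[1]) / pixel_size) + 1
  iy <- floor((locs$y - origin[2]) / pixel_size) + 1
  nx <- max(ix)
  ny <- max(iy)
  counts <- matrix(0, nx, ny)
  tab <- tabulate(ix + (iy - 1) * nx, nbins = nx * ny)
  counts[] <- tab
  q <- quantile(counts[counts > 0], contrast_percentile / 100, names = FALSE)
  intensity <- pmin(counts, q) / q
  structure(
    list(
      intensity = intensity, counts = counts, pixel_size = pixel_size,
      origin = origin, contrast_percentile = contrast_percentile
    ),
    class = "sarcloc_image"
  )
}

#' Convert pixel bounds to nm (half-open boxes)
#' @noRd
px_box_to_nm <- function(image, xmin_px, xmax_px, ymin_px, ymax_px) {
  p <- image$pixel_size
  tibble(
    xmin = image$origin[1] + (xmin_px - 1) * p,
    ymin = image$origin[2] + (ymin_px - 1) * p,
    xmax = image$origin[1] + xmax_px * p,
    ymax = image$origin[2] + ymax_px * p
  )
}

#' Detect candidate double-line boxes on a rendered image
#'
#' Classical detector backend: Gaussian blur, Otsu global threshold,
#' morphological closing, connected components; components are kept when
#' their major-axis length falls within `[0.5 D, 2 D]` and their aspect ratio
#' is at least `aspect_min`. The signature is backend-agnostic so a learned
#' detector (e.g. a Mask-RCNN) can be plugged in behind the same contract:
#' boxes in, per-component bounding boxes out.
#'
#' @param image A `sarcloc_image` from [render_image()].
#' @param D Expected projected line length (disc diameter), nm.
#' @param aspect_min Minimum major/minor axis ratio.
#' @param blur_sigma Gaussian blur sigma, pixels.
#' @param backend Only `"classical"` is implemented.
#' @return Tibble of boxes: pixel bounds (`*_px`) and half-open nm bounds
#'   (`xmin`, `ymin`, `xmax`, `ymax`). Zero rows when nothing is found.
#' @export
detect_boxes <- function(image, D = 1500, aspect_min = 2, blur_sigma = 1,
                         backend = "classical") {
  if (backend != "classical") {
    abort("only the 'classical' detector backend is implemented")
  }
  empty <- tibble(
    xmin_px = integer(), xmax_px = integer(), ymin_px = integer(),
    ymax_px = integer(), xmin = numeric(), ymin = numeric(),
    xmax = numeric(), ymax = numeric()
  )
  int <- image$intensity
  if (all(int == 0)) {
    return(empty)
  }
  img <- EBImage::Image(int)
  if (min(dim(int)) >= 5 && blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = blur_sigma)
  }
  th <- EBImage::otsu(img)
  bw <- img > th
  bw <- EBImage::closing(bw, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(bw)
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(empty)
  }
  mom <- EBImage::computeFeatures.moment(lab)
  major_nm <- mom[, "m.majoraxis"] * image$pixel_size
  ecc <- pmin(mom[, "m.eccentricity"], 1 - 1e-12)
  aspect <- 1 / sqrt(1 - ecc^2)
  keep <- which(major_nm >= 0.5 * D & major_nm <= 2 * D & aspect >= aspect_min)
  if (length(keep) == 0) {
    return(empty)
  }
  boxes <- purrr::map_dfr(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    tibble(
      xmin_px = min(w[, 1]), xmax_px = max(w[, 1]),
      ymin_px = min(w[, 2]), ymax_px = max(w[, 2])
    )
  })
  dplyr::bind_cols(
    boxes,
    px_box_to_nm(image, boxes$xmin_px, boxes$xmax_px, boxes$ymin_px, boxes$ymax_px)
  )
}

#' Run detection over a contrast grid and keep the best setting
#'
#' The detectability of double lines depends on the rendering contrast, so
#' detection is run at several upper-percentile clip settings and the one
#' yielding the most boxes — total box area breaking ties, lower percentile
#' breaking remaining ties — wins.
#'
#' @param locs Localization tibble.
#' @param percentile_grid Candidate contrast percentiles.
#' @param pixel_size Rendering pixel size, nm.
#' @param ... Passed to [detect_boxes()].
#' @return List with `contrast_percentile`, `image`, `boxes`.
#' @export
select_contrast <- function(locs, percentile_grid = c(99, 99.5, 99.9),
                            pixel_size = 100, ...) {
  if (length(percentile_grid) == 0) {
    abort("`percentile_grid` must be non-empty",
      class = "sarcloc_parameter_error"
    )
  }
  runs <- purrr::map(percentile_grid, function(p) {
    img <- render_image(locs, pixel_size = pixel_size, contrast_percentile = p)
    boxes <- detect_boxes(img, ...)
    area <- if (nrow(boxes) == 0) {
      0
    } else {
      sum((boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin))
    }
    list(percentile = p, image = img, boxes = boxes, n = nrow(boxes), area = area)
  })
  ranking <- order(
    -vapply(runs, `[[`, numeric(1), "n"),
    -vapply(runs, `[[`, numeric(1), "area"),
    vapply(runs, `[[`, numeric(1), "percentile")
  )
  best <- runs[[ranking[1]]]
  list(
    contrast_percentile = best$percentile, image = best$image,
    boxes = best$boxes
  )
}

in_box <- function(locs, box) {
  # half-open membership, consistent with the simulator's field conventions
  locs$x >= box[1] & locs$x < box[3] & locs$y >= box[2] & locs$y < box[4]
}

#' Expand a detection box into an analysis region of interest
#'
#' The detection box is dilated by `margin_nm` on all sides so it encompasses
#' the whole object plus surrounding noise; the localizations inside are
#' partitioned into random subsets sized from the estimated per-object count.
#' If too few localizations are available for a valid subset the box grows in
#' `increment_nm` steps, up to `max_increments` times, then the ROI is
#' rejected.
#'
#' @param detect_box Numeric `c(xmin, ymin, xmax, ymax)` in nm (or a one-row
#'   tibble with those columns).
#' @param locs Localization tibble.
#' @param margin_nm Initial boundary shift, nm (default 1000).
#' @param increment_nm Growth step, nm (default 500).
#' @param target_per_object,min_subset See [partition_subsets()].
#' @param max_increments Growth attempts before rejection (default 10).
#' @param seed Integer RNG seed for the subset partition.
#' @return An object of class `sarcloc_roi`: `detect_box`, `analysis_box`,
#'   `est_object_locs`, `subsets` (row indices into `locs`), `n_expansions`.
#'   Signals `sarcloc_roi_rejected` when the region never reaches
#'   `min_subset` localizations.
#' @export
expand_roi <- function(detect_box, locs, margin_nm = 1000, increment_nm = 500,
                       target_per_object = 300, min_subset = 351,
                       max_increments = 10, seed = 1L) {
  if (is.data.frame(detect_box)) {
    detect_box <- as.numeric(detect_box[1, c("xmin", "ymin", "xmax", "ymax")])
  }
  est <- sum(in_box(locs, detect_box))
  for (i in 0:max_increments) {
    grow <- margin_nm + i * increment_nm
    analysis_box <- detect_box + c(-grow, -grow, grow, grow)
    idx <- which(in_box(locs, analysis_box))
    subsets <- tryCatch(
      partition_subsets(
        idx, max(1, est),
        target_per_object = target_per_object,
        min_subset = min_subset, seed = seed
      ),
      sarcloc_insufficient_locs = function(e) NULL
    )
    if (!is.null(subsets)) {
      return(structure(
        list(
          detect_box = detect_box, analysis_box = analysis_box,
          est_object_locs = est, subsets = subsets, n_expansions = i
        ),
        class = "sarcloc_roi"
      ))
    }
  }
  abort(
    paste0(
      "ROI rejected: fewer than ", min_subset, " localizations after ",
      max_increments, " expansions (detect box ",
      paste(round(detect_box), collapse = ", "), ")"
    ),
    class = "sarcloc_roi_rejected"
  )
}

#' Merge per-ROI predictions into per-localization labels
#'
#' Overlapping analysis regions can assign different labels to the same
#' localization; a localization is taken as object if any ROI classified it
#' object (logical OR). Spurious positives introduced by the OR are resolved
#' downstream by the largest-cluster filter.
#'
#' @param per_roi_predictions Tibble with columns `.row` (localization row),
#'   `roi` (ROI id) and `.pred` (`"object"`/`"noise"`).
#' @return Tibble with one row per localization: `.row`, `.pred`.
#' @export
merge_roi_labels <- function(per_roi_predictions) {
  per_roi_predictions |>
    group_by(.row = .data$.row) |>
    summarise(
      .pred = if (any(.data$.pred == "object")) "object" else "noise",
      n_rois = dplyr::n()
    ) |>
    ungroup()
}

#' @export
print.sarcloc_roi <- function(x, ...) {
  cat(
    "<sarcloc_roi> detect box [",
    paste(round(x$detect_box), collapse = ", "), "] nm, ",
    length(x$subsets), " subset(s), ", x$n_expansions, " expansion(s)\n",
    sep = ""
  )
  invisible(x)
}
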