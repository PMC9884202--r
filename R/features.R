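#' Partition localization indices into density-normalized random subsets
#'
#' Feature vectors are computed inside random subsets sized so that each
#' double-line structure contributes roughly `target_per_object`
#' localizations, while every subset stays large enough (`min_subset`) for
#' each member to have the full complement of nearest neighbours.
#'
#' @param indices Integer vector of localization row indices.
#' @param object_count_estimate Estimated object-localization count per
#'   structure (e.g. the count inside a detection box).
#' @param target_per_object Target object localizations per structure per
#'   subset (default 300).
#' @param min_subset Minimum subset size (default 351, i.e. 350 neighbours
#'   plus the query point).
#' @param seed Integer RNG seed for the permutation.
#' @return A list of disjoint integer index vectors covering `indices`.
#'   Signals a condition of class `sarcloc_insufficient_locs` when fewer than
#'   `min_subset` indices are available, telling the caller to expand the
#'   region of interest.
#' @export
partition_subsets <- function(indices, object_count_estimate,
                              target_per_object = 300, min_subset = 351,
                              seed = 1L) {
  if (length(indices) == 0) {
    abort("`indices` must be non-empty", class = "sarcloc_parameter_error")
  }
  if (anyDuplicated(indices)) {
    abort("`indices` must be unique", class = "sarcloc_parameter_error")
  }
  check_number(object_count_estimate, "object_count_estimate", 1)
  n <- length(indices)
  if (n < min_subset) {
    abort(
      paste0(
        "insufficient localizations: ", n, " available, ", min_subset,
        " required; expand the region of interest"
      ),
      class = "sarcloc_insufficient_locs"
    )
  }
  n_subsets <- max(1, round(object_count_estimate / target_per_object))
  while (n_subsets > 1 && n %/% n_subsets < min_subset) {
    n_subsets <- n_subsets - 1
  }
  sizes <- rep(n %/% n_subsets, n_subsets)
  extra <- n %% n_subsets
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  withr::with_seed(seed, {
    perm <- sample(indices)
  })
  unname(split(perm, rep(seq_len(n_subsets), sizes)))
}

# neighbour order within a subset: squared distance, ties by position
neighbour_order <- function(xy, query_index, k) {
  n <- nrow(xy)
  if (n < k + 1) {
    abort(paste0("subset of size ", n, " cannot supply ", k, " neighbours"),
      class = "sarcloc_parameter_error"
    )
  }
  d2 <- (xy[, 1] - xy[query_index, 1])^2 + (xy[, 2] - xy[query_index, 2])^2
  others <- setdiff(seq_len(n), query_index)
  ord <- others[order(d2[others], others)]
  list(idx = ord[seq_len(k)], d2 = d2)
}

#' Sorted distances to the k nearest neighbours of one localization
#'
#' Euclidean distances from the query point to its `k` nearest neighbours
#' within the subset (the query itself excluded), ascending; distance ties are
#' broken by point index so the result is deterministic.
#'
#' @param subset_coords Data frame with `x`/`y` columns or a 2-column matrix.
#' @param query_index Row index of the query point within the subset.
#' @param k Number of neighbours (default 350).
#' @return Numeric vector of length `k`, sorted ascending, nm.
#' @export
knn_distances <- function(subset_coords, query_index, k = 350) {
  xy <- coord_matrix(subset_coords)
  nb <- neighbour_order(xy, query_index, k)
  sqrt(nb$d2[nb$idx])
}

#' Smoothed, orientation-aligned neighbour-direction histogram
#'
#' Directions to the `k` nearest neighbours are histogrammed into `n_bins`
#' equal angular bins over the full circle, circularly smoothed with a boxcar
#' kernel, and circularly shifted so that the global-maximum bin lands on the
#' bin whose centre is closest to `align` (default -pi/6). The shift removes
#' the dependence on strand orientation; -pi/6 keeps the characteristic major
#' and minor peaks away from the edges of the unrolled histogram.
#'
#' @inheritParams knn_distances
#' @param n_bins Number of angular bins (default 30, i.e. 12 degrees each).
#' @param smooth_width Boxcar kernel width in bins (default 3).
#' @param align Alignment target angle, radians.
#' @param normalize Normalize the histogram to sum 1 (default TRUE).
#' @return Numeric vector of length `n_bins`.
#' @export
direction_histogram <- function(subset_coords, query_index, k = 350,
                                n_bins = 30, smooth_width = 3,
                                align = -pi / 6, normalize = TRUE) {
  xy <- coord_matrix(subset_coords)
  nb <- neighbour_order(xy, query_index, k)
  theta <- atan2(
    xy[nb$idx, 2] - xy[query_index, 2],
    xy[nb$idx, 1] - xy[query_index, 1]
  )
  theta[theta >= pi] <- -pi # angles live in [-pi, pi)
  delta <- 2 * pi / n_bins
  bins <- pmin(pmax(floor((theta + pi) / delta), 0), n_bins - 1) + 1
  counts <- tabulate(bins, nbins = n_bins)

  # circular boxcar smoothing
  half <- smooth_width %/% 2
  sm <- vapply(seq_len(n_bins), function(b) {
    sum(counts[((b - 1 + (-half:half)) %% n_bins) + 1]) / smooth_width
  }, numeric(1))

  # shift the global maximum (ties: lowest bin) onto the bin whose centre is
  # closest to `align`
  max_bin <- which.max(sm)
  centres <- -pi + (seq_len(n_bins) - 0.5) * delta
  target <- which.min(abs(centres - align))
  out <- numeric(n_bins)
  dest <- ((seq_len(n_bins) - max_bin + target - 1) %% n_bins) + 1
  out[dest] <- sm
  if (normalize && sum(out) > 0) out <- out / sum(out)
  out
}

#' Full per-localization feature vector
#'
#' Concatenation of [knn_distances()] (350 values) and
#' [direction_histogram()] (30 values): the 380-element descriptor fed to the
#' classifier.
#'
#' @inheritParams direction_histogram
#' @return Numeric vector of length `k + n_bins`.
#' @export
feature_vector <- function(subset_coords, query_index, k = 350, n_bins = 30,
                           smooth_width = 3, align = -pi / 6,
                           normalize = TRUE) {
  c(
    knn_distances(subset_coords, query_index, k),
    direction_histogram(
      subset_coords, query_index, k, n_bins, smooth_width, align, normalize
    )
  )
}

feature_col_names <- function(k = 350, n_bins = 30) {
  c(
    sprintf("nn_dist_%03d", seq_len(k)),
    sprintf("dir_bin_%02d", seq_len(n_bins))
  )
}

#' Names of the feature columns for a feature set
#'
#' @param set `"combined"` (all 380), `"distances"` (350 sorted neighbour
#'   distances) or `"directions"` (30 direction-histogram bins).
#' @param k,n_bins Feature dimensions.
#' @return Character vector of column names as produced by [featurize()].
#' @export
feature_cols <- function(set = c("combined", "distances", "directions"),
                         k = 350, n_bins = 30) {
  set <- match.arg(set)
  nm <- feature_col_names(k, n_bins)
  switch(set,
    combined = nm,
    distances = nm[seq_len(k)],
    directions = nm[k + seq_len(n_bins)]
  )
}

#' Compute feature vectors for all localizations of given subsets
#'
#' Batched feature extraction: every localization in every subset receives its
#' sorted nearest-neighbour distance vector and aligned direction histogram,
#' computed within its own subset.
#'
#' @param locs Localization tibble with `x`/`y` columns.
#' @param subsets List of row-index vectors (from [partition_subsets()]).
#' @param k,n_bins,smooth_width,align,normalize As in [feature_vector()].
#' @return A tibble with columns `.row` (row index into `locs`), `.subset`,
#'   then `nn_dist_001` ... `nn_dist_<k>` and `dir_bin_01` ... `dir_bin_<n_bins>`.
#' @export
featurize <- function(locs, subsets, k = 350, n_bins = 30, smooth_width = 3,
                      align = -pi / 6, normalize = TRUE) {
  if (!is.list(subsets)) subsets <- list(subsets)
  blocks <- purrr::imap(subsets, function(idx, s) {
    # the C++ kernel returns one contiguous column per point; transpose back
    block <- t(feature_block_cpp(
      locs$x[idx], locs$y[idx], as.integer(k), as.integer(n_bins),
      as.integer(smooth_width), align, normalize
    ))
    list(row = idx, subset = rep(s, length(idx)), block = block)
  })
  X <- do.call(rbind, purrr::map(blocks, "block"))
  colnames(X) <- feature_col_names(k, n_bins)
  dplyr::bind_cols(
    tibble(
      .row = unlist(purrr::map(blocks, "row")),
      .subset = unlist(purrr::map(blocks, "subset"))
    ),
    as_tibble(X)
  )
}

#' Featurize a whole labelled corpus field by field
#'
#' Convenience wrapper for training data: localizations are partitioned per
#' field with the per-structure object-localization count as the density
#' estimate, then featurized. Row order of the output follows subset order;
#' use `.row` to join back to `locs`.
#'
#' @param locs Corpus tibble from [simulate_training_corpus()] (must carry
#'   `label`, `object_id` and optionally `field`).
#' @param seed Integer RNG seed for the subset partitions.
#' @param target_per_object,k,n_bins,smooth_width,align,normalize See
#'   [featurize()] and [partition_subsets()].
#' @return A feature tibble as from [featurize()].
#' @export
featurize_corpus <- function(locs, seed = 1L, target_per_object = 300,
                             k = 350, n_bins = 30, smooth_width = 3,
                             align = -pi / 6, normalize = TRUE) {
  fields <- if ("field" %in% names(locs)) unique(locs$field) else 1L
  subset_offset <- 0L
  out <- purrr::map(fields, function(f) {
    rows <- if ("field" %in% names(locs)) which(locs$field == f) else seq_len(nrow(locs))
    is_obj <- locs$label[rows] == "object"
    n_struct <- max(1, dplyr::n_distinct(locs$object_id[rows][is_obj], na.rm = TRUE))
    est <- max(1, sum(is_obj) / n_struct)
    subsets <- partition_subsets(
      rows, est,
      target_per_object = target_per_object,
      seed = sub_seed(seed, "partition") + f
    )
    feats <- featurize(locs, subsets, k, n_bins, smooth_width, align, normalize)
    feats$.subset <- feats$.subset + subset_offset # ids unique across fields
    subset_offset <<- subset_offset + length(subsets)
    feats
  })
  bind_rows(out)
}
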