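# Post-classification filter chain: NN outlier rule, DBSCAN, hull
# statistics, Thompson precision, quality gates, stage accounting.

test_that("the NN outlier rule keeps regular grids and drops lone outliers", {
  grid <- expand.grid(x = seq(0, 90, by = 10), y = seq(0, 90, by = 10))
  res <- nn_outlier_filter(tibble::as_tibble(grid))
  expect_equal(nrow(res$discarded), 0)

  # dense cluster + one point ~10x the grid pitch away
  withr::with_seed(41, {
    cluster <- tibble::tibble(x = runif(100, 0, 100), y = runif(100, 0, 100))
  })
  outlier <- tibble::tibble(x = 1500, y = 1500)
  locs <- dplyr::bind_rows(cluster, outlier)
  res2 <- nn_outlier_filter(locs)
  expect_equal(nrow(res2$discarded), 1)
  expect_equal(res2$discarded$x, 1500)
  # oracle: recompute the means and median by brute force
  D <- as.matrix(stats::dist(cbind(locs$x, locs$y)))
  means <- vapply(seq_len(nrow(locs)), function(i) {
    mean(sort(D[i, -i])[1:10])
  }, numeric(1))
  expect_identical(
    which(means > 5 * stats::median(means)),
    101L
  )

  # infinite multiplier: nothing discarded
  res3 <- nn_outlier_filter(locs, multiplier = Inf)
  expect_equal(nrow(res3$discarded), 0)

  # too few points: stage skipped with a warning
  expect_warning(
    small <- nn_outlier_filter(locs[1:5, ]),
    "skipped"
  )
  expect_equal(nrow(small$kept), 5)
})

test_that("DBSCAN keeps the largest cluster and rejects pure noise", {
  withr::with_seed(42, {
    big <- tibble::tibble(x = rnorm(60, 0, 15), y = rnorm(60, 0, 15))
    small <- tibble::tibble(x = rnorm(40, 1000, 15), y = rnorm(40, 1000, 15))
  })
  res <- dbscan_largest(dplyr::bind_rows(big, small))
  expect_equal(nrow(res$object), 60)
  expect_equal(nrow(res$discarded), 40)
  expect_true(res$hull$area > 0)

  # all pairwise distances > eps: every point is DBSCAN noise
  spread <- tibble::tibble(x = seq(0, 2000, by = 100), y = 0)
  expect_error(dbscan_largest(spread), class = "sarcloc_no_cluster")
})

test_that("DBSCAN labels match the O(n^2) oracle on random instances", {
  for (s in 1:100) {
    withr::with_seed(s, {
      n_clust <- sample(2:5, 1)
      centres <- cbind(runif(n_clust, 0, 2000), runif(n_clust, 0, 2000))
      pts <- do.call(rbind, lapply(seq_len(n_clust), function(i) {
        m <- sample(10:60, 1)
        cbind(rnorm(m, centres[i, 1], 20), rnorm(m, centres[i, 2], 20))
      }))
      pts <- rbind(pts, cbind(runif(40, 0, 2000), runif(40, 0, 2000)))
    })
    locs <- tibble::tibble(x = pts[, 1], y = pts[, 2])
    got <- dbscan_clusters(locs, eps = 50, min_pts = 5)$.cluster
    expect_identical(got, oracle_dbscan(pts, eps = 50, min_pts = 5))
  }
})

test_that("vesicle-only noise clusters are recovered by DBSCAN", {
  locs <- simulate_noise(
    noise_spec(
      vesicle_density = 0.05, vesicle_locs_mean = 20, uniform_density = 0,
      field_width = 20000, field_height = 20000
    ),
    seed = 51
  )
  got <- dbscan_clusters(locs, eps = 50, min_pts = 5)$.cluster
  oracle <- oracle_dbscan(cbind(locs$x, locs$y), eps = 50, min_pts = 5)
  expect_identical(got, oracle)
  expect_gt(max(got), 0)
})

test_that("convex hull statistics are exact on canonical shapes", {
  square <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  h <- convex_hull_stats(square)
  expect_equal(h$perimeter, 4)
  expect_equal(h$area, 1)

  collinear <- tibble::tibble(x = c(0, 4, 10), y = 0)
  h2 <- convex_hull_stats(collinear)
  expect_equal(h2$perimeter, 20) # twice the 10-nm span
  expect_equal(h2$area, 0)

  expect_error(convex_hull_stats(tibble::tibble(x = 1, y = 1)),
    class = "sarcloc_parameter_error"
  )

  # containment: every input point lies inside (or on) its own hull
  withr::with_seed(43, {
    pts <- tibble::tibble(x = runif(100, 0, 500), y = runif(100, 0, 500))
  })
  hull_idx <- grDevices::chull(pts$x, pts$y)
  expect_true(all(vapply(seq_len(100), function(i) {
    in_convex_polygon(pts$x[i], pts$y[i], pts$x[hull_idx], pts$y[hull_idx])
  }, logical(1))))
  expect_gt(convex_hull_stats(pts)$area, 0)
})

test_that("Thompson precision matches the closed form and its limits", {
  # independent arithmetic for sigma = 130, N = 1000, a = 160, b = 0
  expect_equal(
    thompson_precision(130, 1000, 160, 0),
    sqrt(130^2 / 1000 + 160^2 / 12000)
  )
  # precision strictly decreases with photon count
  ns <- c(100, 500, 1000, 5000, 2e4)
  p <- thompson_precision(130, ns, 160, 10)
  expect_true(all(diff(p) < 0))
  # b = 0, a -> 0: precision -> sigma / sqrt(N)
  expect_equal(thompson_precision(130, 1000, 1e-6, 0), 130 / sqrt(1000),
    tolerance = 1e-9
  )
  expect_error(thompson_precision(-1, 100), class = "sarcloc_parameter_error")
})

test_that("quality filter applies the closed sigma window and precision cap", {
  locs <- tibble::tibble(
    sigma = c(130, 161, 111, 120, 150, 140),
    precision = c(15, 15, 15, 25, 10, 20),
    photons = 1000
  )
  res <- quality_filter(locs)
  # two sigma violations (161, 111), one precision violation (25);
  # precision exactly 20 is kept (inclusive threshold)
  expect_equal(nrow(res$kept), 3)
  expect_setequal(res$kept$sigma, c(130, 150, 140))

  # precision derived from sigma and photons when absent
  no_prec <- locs[, c("sigma", "photons")]
  res2 <- quality_filter(no_prec)
  expect_true("precision" %in% names(res2$kept))

  expect_error(quality_filter(tibble::tibble(sigma = 130)),
    class = "sarcloc_parameter_error"
  )
})

test_that("the filter report computes both ratio conventions", {
  counts <- tibble::tibble(
    stage = c("classification", "nearest_neighbour", "dbscan"),
    n_in = c(1000L, 429L, 421L),
    n_discarded = c(571L, 8L, 195L)
  )
  rep <- filter_report(counts)
  expect_equal(
    rep$ratio_of_total[1:3] * 100,
    c(57.1, 0.8, 19.5)
  )
  expect_equal(rep$stage[4], "kept")
  # conservation: kept + all discards = total entering classification
  expect_equal(rep$n_in[4] + sum(rep$n_discarded), 1000L)

  none <- filter_report(tibble::tibble(
    stage = "classification", n_in = 100L, n_discarded = 0L
  ))
  expect_equal(none$ratio_of_total, c(0, 1))
})

test_that("refine_object conserves counts at every stage", {
  locs <- small_field()
  obj <- locs[locs$label == "object" & locs$object_id == 2, ]
  ref <- refine_object(obj)
  for (i in seq_len(nrow(ref$counts))) {
    n_in <- ref$counts$n_in[i]
    n_out <- if (i < nrow(ref$counts)) ref$counts$n_in[i + 1] else nrow(ref$object)
    expect_equal(n_in - ref$counts$n_discarded[i], n_out)
  }
  # pass-through configuration keeps every input localization
  passthrough <- refine_object(obj,
    multiplier = Inf, eps = 1e7, min_pts = 5,
    quality = FALSE
  )
  expect_equal(nrow(passthrough$object), nrow(obj))
})
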