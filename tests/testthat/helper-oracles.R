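# Independent brute-force oracles used to cross-check the compiled
# implementations. Deliberately written in plain base R against the
# definitions, not against the package code paths.

# exhaustive kNN: full distance sort with (distance, index) tie-break
oracle_knn <- function(xy, query, k) {
  d2 <- (xy[, 1] - xy[query, 1])^2 + (xy[, 2] - xy[query, 2])^2
  others <- setdiff(seq_len(nrow(xy)), query)
  ord <- others[order(d2[others], others)]
  sqrt(d2[ord[seq_len(k)]])
}

# textbook DBSCAN with O(n^2) region queries; closed eps-neighbourhood
# includes the point itself; clusters numbered by first core point in index
# order (the same deterministic convention the package documents)
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    neigh <- which(D[i, ] <= eps)
    if (length(neigh) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neigh
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (visited[j]) next
      visited[j] <- TRUE
      nj <- which(D[j, ] <= eps)
      if (length(nj) >= min_pts) queue <- c(queue, nj)
    }
  }
  labels
}

# all-pairs exclusion check: which noise points survive a strict < radius rule
oracle_exclusion_keep <- function(noise_xy, object_xy, radius) {
  vapply(seq_len(nrow(noise_xy)), function(i) {
    d2 <- (object_xy[, 1] - noise_xy[i, 1])^2 +
      (object_xy[, 2] - noise_xy[i, 2])^2
    all(d2 >= radius^2)
  }, logical(1))
}

# point-in-convex-polygon via cross products (vertices in hull order)
in_convex_polygon <- function(px, py, hx, hy, tol = 1e-9) {
  nh <- length(hx)
  s <- vapply(seq_len(nh), function(i) {
    j <- if (i == nh) 1 else i + 1
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(1))
  all(s >= -tol) || all(s <= tol)
}
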