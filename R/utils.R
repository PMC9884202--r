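# Internal helpers shared across modules.

# Named RNG substreams derived from one global seed, so that individual
# pipeline stages can be re-run in isolation and still reproduce. Kept below
# 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stage) {
  stages <- c(
    structure = 1, noise = 2, merge = 3, split = 4, partition = 5,
    features = 6, train = 7, roi = 8, measurement = 9, pipeline = 10
  )
  if (!stage %in% names(stages)) {
    abort(paste0("unknown RNG substream '", stage, "'"))
  }
  as.integer((as.numeric(seed) * 7919 + stages[[stage]] * 104729) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  ok <- is.numeric(x) && length(x) == len && all(is.finite(x)) &&
    (if (strict) all(x > lower) else all(x >= lower))
  if (!ok) {
    abort(paste0(
      "`", name, "` must be ", len, " finite numeric value(s) ",
      if (strict) "> " else ">= ", lower
    ), class = "sarcloc_parameter_error")
  }
  invisible(x)
}

# positive-truncated normal draws via the inverse CDF
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd <= 0) {
    return(rep(max(mean, .Machine$double.eps), n))
  }
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

# coordinates as a two-column matrix from a data frame or matrix
coord_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("`points` must have `x` and `y` columns")
    }
    cbind(points$x, points$y)
  } else if (is.matrix(points) && ncol(points) >= 2) {
    points[, 1:2, drop = FALSE]
  } else {
    abort("`points` must be a data frame with x/y columns or a 2-column matrix")
  }
}

localization_columns <- c(
  "frame", "x", "y", "sigma", "photons", "precision", "label", "object_id"
)

empty_localizations <- function() {
  tibble(
    frame = integer(), x = numeric(), y = numeric(), sigma = numeric(),
    photons = numeric(), precision = numeric(), label = character(),
    object_id = integer()
  )
}
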