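#' Specification of a simulated sarcomeric double-line field
#'
#' Parameters of the localization-level simulator that emulates a dSTORM
#' measurement of disc-pair ("double-line") structures along a myofibril
#' strand. Each disc pair projects to two parallel line segments of length `D`
#' (the disc diameter) separated by `d` along the strand; pairs repeat every
#' `L` along the strand. Epitopes are placed on the projected segments, each
#' epitope carries a random number of fluorescent labels displaced by the
#' linker, and each label blinks one or more times; every blink becomes one
#' localization jittered by its localization precision.
#'
#' @param L Disc-pair spacing along the strand, nm.
#' @param D Disc diameter (projected line length), nm.
#' @param d Line separation within a pair, nm.
#' @param epitope_density Epitopes per square micron of disc face.
#' @param n_pairs Number of double-line objects on the strand.
#' @param strand_angle Strand orientation, radians.
#' @param labels_per_epitope_mean,labels_per_epitope_var Mean and variance of
#'   the per-epitope label count (drawn as a rounded normal, clipped at 0).
#' @param linker_length Label displacement magnitude, nm (antibody linker).
#' @param blinks_per_label_mean Mean blink count per label; drawn Poisson and
#'   clipped to at least 1.
#' @param loc_precision_mean,loc_precision_sd Localization precision draw
#'   (truncated-positive normal), nm.
#' @param sigma_range Range of the fitted PSF width draw, nm. The default
#'   brackets the 112-160 nm window used by the downstream quality filter so
#'   that filter stage stays exercisable.
#' @param pixel_size Camera pixel size used for the photon-count model, nm.
#' @param background_photons Background level (photons per pixel) used when
#'   deriving photon counts from the drawn precision.
#' @param n_frames Number of camera frames localizations are spread over.
#' @param origin Strand start point (x, y), nm; field origin is lower-left.
#' @param projection `"chord"` weights epitope positions by the projected
#'   chord length of the disc face (denser line centres); `"uniform"` samples
#'   plainly along the segment.
#'
#' @return A list of class `double_line_spec`.
#' @export
double_line_spec <- function(L = 3400, D = 1500, d = 120, epitope_density = 40,
                             n_pairs = 27, strand_angle = 0,
                             labels_per_epitope_mean = 5,
                             labels_per_epitope_var = 2,
                             linker_length = 25, blinks_per_label_mean = 1.5,
                             loc_precision_mean = 10, loc_precision_sd = 4,
                             sigma_range = c(100, 170), pixel_size = 160,
                             background_photons = 19, n_frames = 15000,
                             origin = c(1000, 4000),
                             projection = c("chord", "uniform")) {
  spec <- list(
    L = L, D = D, d = d, epitope_density = epitope_density, n_pairs = n_pairs,
    strand_angle = strand_angle,
    labels_per_epitope_mean = labels_per_epitope_mean,
    labels_per_epitope_var = labels_per_epitope_var,
    linker_length = linker_length,
    blinks_per_label_mean = blinks_per_label_mean,
    loc_precision_mean = loc_precision_mean,
    loc_precision_sd = loc_precision_sd,
    sigma_range = sigma_range, pixel_size = pixel_size,
    background_photons = background_photons, n_frames = n_frames,
    origin = origin, projection = match.arg(projection)
  )
  check_number(spec$L, "L", 0, strict = TRUE)
  check_number(spec$D, "D", 0, strict = TRUE)
  check_number(spec$d, "d", 0, strict = TRUE)
  if (!(spec$L > spec$d)) {
    abort("need L > d > 0", class = "sarcloc_parameter_error")
  }
  check_number(spec$epitope_density, "epitope_density", 0)
  check_number(spec$n_pairs, "n_pairs", 1)
  check_number(spec$labels_per_epitope_mean, "labels_per_epitope_mean", 0)
  check_number(spec$labels_per_epitope_var, "labels_per_epitope_var", 0)
  check_number(spec$linker_length, "linker_length", 0)
  check_number(spec$blinks_per_label_mean, "blinks_per_label_mean", 0)
  check_number(spec$loc_precision_mean, "loc_precision_mean", 0, strict = TRUE)
  check_number(spec$loc_precision_sd, "loc_precision_sd", 0)
  check_number(spec$sigma_range, "sigma_range", 0, strict = TRUE, len = 2L)
  check_number(spec$origin, "origin", -Inf, len = 2L)
  structure(spec, class = "double_line_spec")
}

#' Specification of the simulated background noise
#'
#' Two noise components are emulated at the localization level: randomly
#' placed vesicles, each yielding a tight localization cluster, and uniformly
#' distributed non-specific labelling.
#'
#' @param vesicle_density Vesicle clusters per square micron.
#' @param vesicle_locs_mean Mean localizations per vesicle cluster (Poisson).
#' @param vesicle_sigma Gaussian spread of a vesicle cluster, nm.
#' @param uniform_density Uniform non-specific localizations per square micron.
#' @param field_width,field_height Field extent, nm (origin at lower-left).
#' @param loc_precision_mean,loc_precision_sd,sigma_range,pixel_size,
#'   background_photons,n_frames As in [double_line_spec()].
#'
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(vesicle_density = 2, vesicle_locs_mean = 8.5,
                       vesicle_sigma = 15, uniform_density = 17,
                       field_width = 94000, field_height = 8000,
                       loc_precision_mean = 10, loc_precision_sd = 4,
                       sigma_range = c(100, 170), pixel_size = 160,
                       background_photons = 19, n_frames = 15000) {
  spec <- list(
    vesicle_density = vesicle_density, vesicle_locs_mean = vesicle_locs_mean,
    vesicle_sigma = vesicle_sigma, uniform_density = uniform_density,
    field_width = field_width, field_height = field_height,
    loc_precision_mean = loc_precision_mean,
    loc_precision_sd = loc_precision_sd, sigma_range = sigma_range,
    pixel_size = pixel_size, background_photons = background_photons,
    n_frames = n_frames
  )
  check_number(spec$vesicle_density, "vesicle_density", 0)
  check_number(spec$vesicle_locs_mean, "vesicle_locs_mean", 0)
  check_number(spec$vesicle_sigma, "vesicle_sigma", 0)
  check_number(spec$uniform_density, "uniform_density", 0)
  check_number(spec$field_width, "field_width", 0, strict = TRUE)
  check_number(spec$field_height, "field_height", 0, strict = TRUE)
  structure(spec, class = "noise_spec")
}

# fill sigma / photons / precision / frame metadata for freshly drawn points
localization_metadata <- function(xy, spec) {
  n <- nrow(xy)
  precision <- rtruncnorm_pos(n, spec$loc_precision_mean, spec$loc_precision_sd)
  sigma <- runif(n, spec$sigma_range[1], spec$sigma_range[2])
  photons <- round(solve_photons(
    precision, sigma, spec$pixel_size, spec$background_photons
  ))
  tibble(
    frame = sample.int(spec$n_frames, n, replace = TRUE),
    x = xy[, 1], y = xy[, 2],
    sigma = sigma, photons = photons, precision = precision
  )
}

#' Simulate double-line object localizations
#'
#' Draws the labelled ("object") localizations of `n_pairs` double-line
#' structures on one strand. Epitope counts per projected line segment are
#' Poisson with mean `epitope_density` times the disc face area; each epitope
#' spawns a rounded-normal number of labels, each label is displaced by the
#' linker length in a uniformly random direction and blinks `max(1, Poisson)`
#' times; each blink is jittered isotropically by its drawn localization
#' precision.
#'
#' @param spec A [double_line_spec()].
#' @param seed Integer RNG seed.
#' @return A tibble of localizations with `label = "object"` and `object_id`
#'   indexing the disc pair.
#' @export
simulate_double_lines <- function(spec, seed = 1L) {
  if (!inherits(spec, "double_line_spec")) spec <- do.call(double_line_spec, spec)
  withr::with_seed(seed, {
    u <- c(cos(spec$strand_angle), sin(spec$strand_angle)) # along strand
    v <- c(-u[2], u[1]) # along the lines
    disc_area_um2 <- pi * (spec$D / 2000)^2
    mean_epitopes <- spec$epitope_density * disc_area_um2

    pieces <- vector("list", spec$n_pairs)
    for (pair in seq_len(spec$n_pairs)) {
      centre <- spec$origin + (pair - 0.5) * spec$L * u
      line_offsets <- c(-spec$d / 2, spec$d / 2)
      epi <- lapply(line_offsets, function(off) {
        n_epi <- rpois(1, mean_epitopes)
        if (n_epi == 0) {
          return(NULL)
        }
        t <- if (spec$projection == "chord") {
          (2 * rbeta(n_epi, 1.5, 1.5) - 1) * spec$D / 2
        } else {
          runif(n_epi, -spec$D / 2, spec$D / 2)
        }
        cbind(
          centre[1] + off * u[1] + t * v[1],
          centre[2] + off * u[2] + t * v[2]
        )
      })
      epi <- do.call(rbind, epi)
      if (is.null(epi) || nrow(epi) == 0) next

      n_labels <- pmax(0L, as.integer(round(rnorm(
        nrow(epi), spec$labels_per_epitope_mean,
        sqrt(spec$labels_per_epitope_var)
      ))))
      if (sum(n_labels) == 0) next
      lab_xy <- epi[rep(seq_len(nrow(epi)), n_labels), , drop = FALSE]
      phi <- runif(nrow(lab_xy), 0, 2 * pi)
      lab_xy <- lab_xy + spec$linker_length * cbind(cos(phi), sin(phi))

      n_blinks <- pmax(1L, rpois(nrow(lab_xy), spec$blinks_per_label_mean))
      blink_xy <- lab_xy[rep(seq_len(nrow(lab_xy)), n_blinks), , drop = FALSE]
      meta <- localization_metadata(blink_xy, spec)
      meta$x <- meta$x + rnorm(nrow(meta)) * meta$precision
      meta$y <- meta$y + rnorm(nrow(meta)) * meta$precision
      meta$object_id <- pair
      pieces[[pair]] <- meta
    }
    out <- bind_rows(pieces)
    if (nrow(out) == 0) {
      return(empty_localizations())
    }
    out$label <- "object"
    out[, localization_columns]
  })
}

#' Simulate background noise localizations
#'
#' Vesicle clusters have Poisson-distributed counts and centres uniform in the
#' field; each cluster's localizations are Gaussian around the centre with the
#' vesicle spread plus the localization-precision jitter. The uniform
#' component is a homogeneous Poisson process over the field.
#'
#' @param spec A [noise_spec()].
#' @param seed Integer RNG seed.
#' @return A tibble of localizations with `label = "noise"`.
#' @export
simulate_noise <- function(spec, seed = 1L) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, spec)
  withr::with_seed(seed, {
    area_um2 <- spec$field_width * spec$field_height / 1e6

    n_ves <- rpois(1, spec$vesicle_density * area_um2)
    ves_xy <- NULL
    if (n_ves > 0) {
      centres <- cbind(
        runif(n_ves, 0, spec$field_width),
        runif(n_ves, 0, spec$field_height)
      )
      counts <- rpois(n_ves, spec$vesicle_locs_mean)
      if (sum(counts) > 0) {
        ves_xy <- centres[rep(seq_len(n_ves), counts), , drop = FALSE] +
          rnorm(2 * sum(counts)) * spec$vesicle_sigma
      }
    }

    n_uni <- rpois(1, spec$uniform_density * area_um2)
    uni_xy <- if (n_uni > 0) {
      cbind(
        runif(n_uni, 0, spec$field_width),
        runif(n_uni, 0, spec$field_height)
      )
    } else {
      NULL
    }

    xy <- rbind(ves_xy, uni_xy)
    if (is.null(xy) || nrow(xy) == 0) {
      return(empty_localizations())
    }
    out <- localization_metadata(xy, spec)
    out$x <- out$x + rnorm(nrow(out)) * out$precision
    out$y <- out$y + rnorm(nrow(out)) * out$precision
    out$label <- "noise"
    out$object_id <- NA_integer_
    out[, localization_columns]
  })
}

#' Merge object and noise localizations with an exclusion radius
#'
#' Noise localizations closer than `radius` to any object localization are
#' removed before concatenation: inside that radius simulated noise would be
#' indistinguishable from specific labelling and would confuse training.
#'
#' @param objects,noise Localization tibbles carrying a `label` column.
#' @param radius Exclusion radius, nm (default 50).
#' @return A tibble: all object rows followed by the surviving noise rows,
#'   input order preserved.
#' @export
merge_with_exclusion <- function(objects, noise, radius = 50) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0) {
    abort("`radius` must be a single non-negative number",
      class = "sarcloc_parameter_error"
    )
  }
  if (nrow(noise) == 0 || nrow(objects) == 0 || radius == 0) {
    return(bind_rows(objects, noise))
  }
  keep <- exclusion_keep_cpp(noise$x, noise$y, objects$x, objects$y, radius)
  bind_rows(objects, noise[keep, , drop = FALSE])
}

#' Stratified train/validation/test split
#'
#' Splits row indices into disjoint, exhaustive sets, stratified by the
#' `label` column when present so each split keeps the global object:noise
#' ratio to within one row per stratum.
#'
#' @param data Localization tibble (or any data frame; a `label` column is
#'   used for stratification when present).
#' @param fractions Length-3 numeric summing to 1: train, validation, test.
#' @param seed Integer RNG seed.
#' @return Named list of integer row indices: `train`, `val`, `test`.
#' @export
split_train_val_test <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (!is.numeric(fractions) || length(fractions) != 3 ||
    any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be 3 non-negative numbers summing to 1",
      class = "sarcloc_parameter_error"
    )
  }
  n <- nrow(data)
  strata <- if ("label" %in% names(data)) data$label else rep("all", n)
  out <- list(train = integer(), val = integer(), test = integer())
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      cuts <- floor(cumsum(fractions) * length(idx))
      out$train <- c(out$train, idx[seq_len(cuts[1])])
      out$val <- c(out$val, idx[seq_len(cuts[2] - cuts[1]) + cuts[1]])
      out$test <- c(out$test, idx[seq_len(cuts[3] - cuts[2]) + cuts[2]])
    }
  })
  lapply(out, sort)
}

#' Simulate one labelled field (objects + noise, exclusion-merged)
#'
#' @param structure_spec A [double_line_spec()].
#' @param noise_spec A [noise_spec()].
#' @param seed Integer RNG seed; object and noise draws use distinct
#'   substreams derived from it.
#' @param exclusion_radius Radius for [merge_with_exclusion()], nm.
#' @return A localization tibble.
#' @export
simulate_field <- function(structure_spec = double_line_spec(),
                           noise_spec = sarcloc::noise_spec(),
                           seed = 1L, exclusion_radius = 50) {
  objects <- simulate_double_lines(structure_spec, sub_seed(seed, "structure"))
  noise <- simulate_noise(noise_spec, sub_seed(seed, "noise"))
  merge_with_exclusion(objects, noise, exclusion_radius)
}

#' Simulate the standard training corpus
#'
#' The default corpus used throughout for classifier training and evaluation:
#' two fields of 27 double-line objects each, spanning the simulated epitope
#' density range (30 and 50 per square micron of disc face) and the line
#' separation range (120 and 128 nm), with vesicle and uniform noise merged
#' under the 50-nm exclusion rule. At the default multiplicities this yields
#' roughly 60,000 object and 50,000 noise localizations.
#'
#' @param seed Integer RNG seed.
#' @param densities Epitope densities per field, 1/um^2 of disc face.
#' @param d Line separations per field, nm (recycled against `densities`).
#' @param n_pairs Double-line objects per field.
#' @param ... Further arguments passed to [double_line_spec()].
#' @return A localization tibble with an extra `field` column.
#' @export
simulate_training_corpus <- function(seed = 1L, densities = c(30, 50),
                                     d = c(120, 128), n_pairs = 27, ...) {
  d <- rep_len(d, length(densities))
  fields <- purrr::map2(seq_along(densities), densities, function(i, dens) {
    dspec <- double_line_spec(
      d = d[i], epitope_density = dens, n_pairs = n_pairs, ...
    )
    fld <- simulate_field(
      dspec,
      strand_noise_spec(dspec),
      seed = sub_seed(seed, "pipeline") + i
    )
    fld$field <- i
    fld
  })
  bind_rows(fields)
}

#' Noise field sized to a strand
#'
#' The default noise field spans the strand of a [double_line_spec()] plus a
#' 1-um margin on each side, at the standard 8-um height.
#'
#' @param structure_spec A [double_line_spec()].
#' @param field_height Field height, nm.
#' @param ... Passed to [noise_spec()].
#' @return A [noise_spec()].
#' @export
strand_noise_spec <- function(structure_spec, field_height = 8000, ...) {
  noise_spec(
    field_width = structure_spec$n_pairs * structure_spec$L + 2000,
    field_height = field_height, ...
  )
}
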