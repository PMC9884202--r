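# Localization table I/O and configuration handling.

# alias table for common localization-file dialects; names are compared after
# lower-casing and stripping non-alphanumerics
column_aliases <- list(
  x = c("x", "xnm", "xposition", "xpositionnm", "positionx"),
  y = c("y", "ynm", "yposition", "ypositionnm", "positiony"),
  frame = c("frame", "framenumber", "frameidx", "t"),
  sigma = c("sigma", "sigmanm", "sd", "sdnm", "sigmax", "sigmaxnm", "psfsigma"),
  photons = c(
    "photons", "intensity", "intensityphoton", "nphotons", "photoncount",
    "photonscount"
  ),
  precision = c(
    "precision", "precisionnm", "uncertainty", "uncertaintynm",
    "uncertaintyxynm", "locprecision", "localizationprecision"
  ),
  label = c("label", "class", "truth"),
  object_id = c("objectid", "object", "structureid")
)

normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a localization table
#'
#' Reads CSV localization tables in common dialects, mapping column aliases
#' (`x [nm]`/`x_nm`/`X position`, `intensity`/`photons`,
#' `uncertainty`/`precision`, ...) onto the standard columns. When the
#' precision column is absent but `sigma` and `photons` are present, the
#' Thompson precision is computed and the result is flagged with the
#' attribute `derived_precision = TRUE`.
#'
#' @param path CSV file with a header row.
#' @param pixel_size,background Used only when the precision is derived.
#' @return A localization tibble (columns among `frame`, `x`, `y`, `sigma`,
#'   `photons`, `precision`, `label`, `object_id`).
#' @export
read_localizations <- function(path, pixel_size = 160, background = 0) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  norm <- normalize_name(names(raw))
  mapped <- list()
  for (std in names(column_aliases)) {
    hit <- which(norm %in% column_aliases[[std]])
    if (length(hit) > 0) mapped[[std]] <- raw[[hit[1]]]
  }
  for (req in c("x", "y")) {
    if (is.null(mapped[[req]])) {
      abort(paste0(
        "required column `", req, "` not found; recognised aliases: ",
        paste(column_aliases[[req]], collapse = ", ")
      ), class = "sarcloc_parameter_error")
    }
  }
  out <- as_tibble(mapped)
  derived <- FALSE
  if (!"precision" %in% names(out) &&
    all(c("sigma", "photons") %in% names(out))) {
    out$precision <- thompson_precision(
      out$sigma, out$photons, pixel_size, background
    )
    derived <- TRUE
    inform("precision column derived from sigma and photons (Thompson)")
  }
  if (nrow(out) == 0) warn(paste0("no localizations in ", path))
  attr(out, "derived_precision") <- derived
  out
}

#' Write a localization table
#'
#' Writes the standard CSV contract (`frame,x_nm,y_nm,sigma_nm,photons,
#' precision_nm,label,object_id`); in measurement-like mode the ground-truth
#' columns are omitted.
#'
#' @param locs Localization tibble.
#' @param path Output CSV path.
#' @param measurement_mode Drop `label` and `object_id` (default FALSE).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, measurement_mode = FALSE) {
  out <- tibble(
    frame = locs$frame %||% NA_integer_,
    x_nm = locs$x, y_nm = locs$y,
    sigma_nm = locs$sigma %||% NA_real_,
    photons = locs$photons %||% NA_real_,
    precision_nm = locs$precision %||% NA_real_
  )
  if (!measurement_mode) {
    out$label <- locs$label %||% NA_character_
    out$object_id <- locs$object_id %||% NA_integer_
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' One nested list with a block per module; every default equals the
#' workflow's standard value. Round-trips losslessly through YAML.
#'
#' @param seed Global seed; every stage derives its own substream from it.
#' @param ... Named blocks overriding defaults, merged recursively.
#' @return A list of class `sarcloc_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(
      densities = c(30, 50), d = c(120, 128), n_pairs = 27,
      exclusion_radius = 50
    ),
    features = list(
      k = 350, n_bins = 30, smooth_width = 3, align = -pi / 6,
      normalize = TRUE, target_per_object = 300, min_subset = 351
    ),
    classify = list(
      hidden_units = 32, epochs = 10, batch_size = 32, learning_rate = 1e-3,
      threshold = 0.5, standardize = FALSE
    ),
    roi = list(
      pixel_size = 100, contrast_grid = c(99, 99.5, 99.9), D = 1500,
      aspect_min = 2, margin_nm = 1000, increment_nm = 500,
      max_increments = 10
    ),
    postfilter = list(
      m = 10, multiplier = 5, eps = 50, min_pts = 5,
      sigma_range = c(112, 160), precision_max = 20, quality = TRUE
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = c("sarcloc_config", "list"))
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @return For `read_config`, a `sarcloc_config` (defaults filled in for
#'   missing entries).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = raw$seed %||% 1L),
    raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_config
#' @param config A `sarcloc_config`.
#' @return For `write_config`, `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Save / load a fitted classifier
#'
#' Portable JSON serialization: weights plus the classifier spec and a hash
#' of the feature-column layout, so predictions are reproducible across
#' sessions and feature mismatches are caught at load time.
#'
#' @param model A `sarcloc_mlp`.
#' @param path JSON file.
#' @return `path` invisibly; `load_classifier` returns the model.
#' @export
save_classifier <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    feature_names = model$feature_names,
    feature_hash = rlang::hash(model$feature_names),
    seed = model$seed,
    history = as.list(model$history),
    centre = model$centre,
    scale = model$scale,
    weights = list(
      W1 = as.numeric(model$weights$W1),
      dim_W1 = dim(model$weights$W1),
      b1 = model$weights$b1, w2 = model$weights$w2, b2 = model$weights$b2
    )
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rlang::hash(p$feature_names), p$feature_hash)) {
    abort("feature layout hash mismatch in saved model")
  }
  structure(
    list(
      weights = list(
        W1 = matrix(p$weights$W1, p$weights$dim_W1[1], p$weights$dim_W1[2]),
        b1 = p$weights$b1, w2 = p$weights$w2, b2 = p$weights$b2
      ),
      spec = do.call(classifier_spec, p$spec[c(
        "hidden_units", "epochs", "batch_size", "learning_rate", "beta1",
        "beta2", "adam_eps", "threshold", "standardize"
      )]),
      history = as_tibble(p$history),
      feature_names = p$feature_names,
      centre = if (length(p$centre) > 0) as.numeric(p$centre) else NULL,
      scale = if (length(p$scale) > 0) as.numeric(p$scale) else NULL,
      seed = p$seed
    ),
    class = "sarcloc_mlp"
  )
}
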