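#' Run the end-to-end segmentation pipeline
#'
#' Executes the full workflow: (optionally) train a classifier on a simulated
#' labelled corpus, then take a measurement-like localization table, detect
#' candidate double-line regions on rendered images over a contrast grid,
#' expand each detection into an analysis ROI with density-normalized random
#' subsets, compute feature vectors only inside those ROIs, classify every
#' localization, merge per-ROI labels (logical OR), refine the positives of
#' each ROI through the nearest-neighbour outlier / DBSCAN largest-cluster /
#' quality filter chain, and estimate each object's line separation.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts (created if missing);
#'   `NULL` skips writing.
#' @param input Path to a measurement localization CSV; when `NULL` a fresh
#'   measurement-like field is simulated from the config's generator block.
#' @param model A fitted `sarcloc_mlp` (or path to one saved with
#'   [save_classifier()]); when `NULL` a model is trained on the standard
#'   simulated corpus.
#' @return List with elements `model`, `measurement` (localizations),
#'   `contrast`, `rois`, `predictions` (merged per-localization labels),
#'   `objects` (kept localizations, `object_id` = ROI index), `hulls`,
#'   `report` (stage-count tibble from [filter_report()]), `separations`,
#'   `manifest`, and `paths` of written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         input = NULL, model = NULL) {
  seed <- config$seed
  fcfg <- config$features
  stage_log <- list()

  # -- model -----------------------------------------------------------------
  if (is.character(model)) model <- load_classifier(model)
  if (is.null(model)) {
    corpus <- simulate_training_corpus(
      seed = seed,
      densities = config$simulate$densities, d = config$simulate$d,
      n_pairs = config$simulate$n_pairs
    )
    feats <- featurize_corpus(
      corpus,
      seed = seed, target_per_object = fcfg$target_per_object,
      k = fcfg$k, n_bins = fcfg$n_bins, smooth_width = fcfg$smooth_width,
      align = fcfg$align, normalize = fcfg$normalize
    )
    labels <- corpus$label[feats$.row]
    split <- split_train_val_test(
      tibble(label = labels),
      seed = sub_seed(seed, "split")
    )
    spec <- do.call(classifier_spec, config$classify)
    model <- fit_classifier(
      feats[split$train, ], labels[split$train],
      spec = spec,
      val_features = feats[split$val, ], val_labels = labels[split$val],
      seed = sub_seed(seed, "train")
    )
    stage_log$training_corpus <- nrow(corpus)
  }

  # -- measurement data ------------------------------------------------------
  measurement <- if (!is.null(input)) {
    read_localizations(input)
  } else {
    dspec <- double_line_spec(
      d = config$simulate$d[1],
      epitope_density = config$simulate$densities[1],
      n_pairs = config$simulate$n_pairs
    )
    simulate_field(
      dspec,
      strand_noise_spec(dspec),
      seed = sub_seed(seed, "measurement"),
      exclusion_radius = 0 # measurement mode: no ground-truth merge trickery
    )
  }

  # -- ROI detection ---------------------------------------------------------
  rcfg <- config$roi
  contrast <- select_contrast(
    measurement,
    percentile_grid = rcfg$contrast_grid,
    pixel_size = rcfg$pixel_size, D = rcfg$D, aspect_min = rcfg$aspect_min
  )
  boxes <- contrast$boxes
  rois <- list()
  for (b in seq_len(nrow(boxes))) {
    roi <- tryCatch(
      expand_roi(
        as.numeric(boxes[b, c("xmin", "ymin", "xmax", "ymax")]),
        measurement,
        margin_nm = rcfg$margin_nm, increment_nm = rcfg$increment_nm,
        target_per_object = fcfg$target_per_object,
        min_subset = fcfg$min_subset,
        max_increments = rcfg$max_increments,
        seed = sub_seed(seed, "roi") + b
      ),
      sarcloc_roi_rejected = function(e) {
        inform(conditionMessage(e))
        NULL
      }
    )
    if (!is.null(roi)) rois[[length(rois) + 1]] <- roi
  }

  # -- featurize + classify per ROI -----------------------------------------
  per_roi <- purrr::imap(rois, function(roi, r) {
    feats <- featurize(
      measurement, roi$subsets,
      k = fcfg$k, n_bins = fcfg$n_bins,
      smooth_width = fcfg$smooth_width, align = fcfg$align,
      normalize = fcfg$normalize
    )
    pred <- predict(model, feats)
    dplyr::bind_cols(
      tibble(roi = r), pred,
      tibble(nn_mean = rowMeans(as.matrix(
        feats[feature_col_names(fcfg$k, fcfg$n_bins)[seq_len(config$postfilter$m)]]
      )))
    )
  })
  roi_pred <- bind_rows(per_roi)
  merged <- if (nrow(roi_pred) > 0) {
    merge_roi_labels(roi_pred)
  } else {
    tibble(.row = integer(), .pred = character(), n_rois = integer())
  }

  # -- post-filter chain -----------------------------------------------------
  n_classified <- nrow(merged)
  n_neg <- sum(merged$.pred == "noise")
  class_counts <- tibble(
    stage = "classification", n_in = n_classified, n_discarded = n_neg
  )
  pcfg <- config$postfilter
  objects <- list()
  hulls <- list()
  chain_counts <- list()
  # each positive localization is refined within exactly one ROI (the first
  # that featurized it), so the stage counts stay conserved even when
  # analysis boxes overlap
  pos_rows <- merged$.row[merged$.pred == "object"]
  assignment <- roi_pred |>
    filter(.data$.row %in% pos_rows) |>
    group_by(.data$.row) |>
    dplyr::slice_min(.data$roi, n = 1, with_ties = FALSE) |>
    ungroup()
  for (r in seq_along(rois)) {
    members <- assignment |> filter(.data$roi == r)
    if (nrow(members) == 0) next
    locs_r <- measurement[members$.row, , drop = FALSE]
    ref <- refine_object(
      locs_r,
      m = pcfg$m, multiplier = pcfg$multiplier, eps = pcfg$eps,
      min_pts = pcfg$min_pts, sigma_range = pcfg$sigma_range,
      precision_max = pcfg$precision_max, quality = pcfg$quality,
      nn_means = members$nn_mean
    )
    chain_counts[[r]] <- ref$counts
    if (!is.null(ref$object) && nrow(ref$object) > 0) {
      obj <- ref$object
      obj$object_id <- r
      objects[[length(objects) + 1]] <- obj
      hulls[[length(hulls) + 1]] <- dplyr::bind_cols(
        tibble(object_id = r), ref$hull
      )
    }
  }
  objects <- bind_rows(objects)
  hulls <- bind_rows(hulls)
  chain <- bind_rows(chain_counts)
  chain_sum <- if (nrow(chain) > 0) {
    chain |>
      group_by(.data$stage) |>
      summarise(
        n_in = sum(.data$n_in), n_discarded = sum(.data$n_discarded)
      ) |>
      dplyr::arrange(match(
        .data$stage,
        c("nearest_neighbour", "dbscan", "sigma_precision")
      ))
  } else {
    tibble(stage = character(), n_in = integer(), n_discarded = integer())
  }
  report <- filter_report(bind_rows(class_counts, chain_sum))

  # -- separation estimates --------------------------------------------------
  separations <- if (nrow(objects) > 0) {
    analyze_objects(objects)
  } else {
    tibble(
      object_id = integer(), d_hat = numeric(), axis_angle = numeric(),
      width = numeric(), n_locs = integer()
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sarcloc")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_measurement_locs = nrow(measurement),
    n_rois_detected = nrow(boxes),
    n_rois_accepted = length(rois),
    n_featurized = n_classified,
    n_objects = if (nrow(objects) > 0) dplyr::n_distinct(objects$object_id) else 0L,
    stage_counts = as.list(setNames(report$n_discarded, report$stage)),
    stage_log = stage_log
  )

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$measurement <- write_localizations(
      measurement, file.path(out_dir, "measurement.csv"),
      measurement_mode = !is.null(input)
    )
    paths$model <- save_classifier(model, file.path(out_dir, "model.json"))
    paths$rois <- file.path(out_dir, "rois.json")
    jsonlite::write_json(
      purrr::map(rois, function(r) {
        list(
          detect_box = r$detect_box, analysis_box = r$analysis_box,
          est_object_locs = r$est_object_locs,
          subset_sizes = lengths(r$subsets), n_expansions = r$n_expansions
        )
      }),
      paths$rois,
      digits = NA
    )
    paths$filtered <- file.path(out_dir, "filtered.csv")
    readr::write_csv(objects, paths$filtered, progress = FALSE)
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, paths$report, digits = NA, dataframe = "rows")
    paths$separations <- file.path(out_dir, "separations.csv")
    readr::write_csv(separations, paths$separations, progress = FALSE)
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest,
      digits = NA, auto_unbox = TRUE
    )
  }

  list(
    model = model, measurement = measurement, contrast = contrast,
    rois = rois, predictions = merged, objects = objects, hulls = hulls,
    report = report, separations = separations, manifest = manifest,
    paths = paths
  )
}

#' Fraction of true objects covered by exactly one accepted ROI
#'
#' Diagnostic for the detector on simulated fields with known structure
#' positions: an object counts as covered when its localization centroid
#' falls inside exactly one ROI's detection box.
#'
#' @param locs Simulated localization tibble with `label`/`object_id`.
#' @param rois List of `sarcloc_roi` objects.
#' @return A single number in [0, 1].
#' @export
detection_recall <- function(locs, rois) {
  centroids <- locs |>
    filter(.data$label == "object") |>
    group_by(.data$object_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y))
  if (nrow(centroids) == 0) {
    return(NA_real_)
  }
  hits <- vapply(seq_len(nrow(centroids)), function(i) {
    sum(vapply(rois, function(r) {
      in_box(centroids[i, ], r$detect_box)
    }, logical(1)))
  }, numeric(1))
  mean(hits == 1)
}
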