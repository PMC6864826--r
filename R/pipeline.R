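#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Validation of children
#' happens at construction; `r >= d` triggers a warning (the index disc is
#' meant to stay inside one seeding cell).
#'
#' @param segmentation an [ms_params].
#' @param classifier `"mlc"`, `"mdm"` or `"sam"`.
#' @param priors `"uniform"` or `"empirical"` (MLC only).
#' @param d seeding distance, meters.
#' @param r health-index disc radius, meters.
#' @param row_pitch,row_y0 row-banding model for [partition_rows()]; `row_y0
#'   = NULL` uses the topmost component.
#' @param tile,margin tiling for [segment_tiled()]; `tile = Inf` disables
#'   tiling.
#' @param seed integer master seed.
#' @param worker_count workers for the clustering stage.
#' @param health a [health_params]; default uses `r`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = ms_params(), classifier = c("mlc", "mdm", "sam"),
                            priors = c("uniform", "empirical"), d = 0.3, r = 0.075,
                            row_pitch = 2.0, row_y0 = NULL, tile = 512L,
                            margin = NULL, seed = 1L, worker_count = 1L,
                            health = NULL) {
  classifier <- match.arg(classifier)
  priors <- match.arg(priors)
  stopifnot(d > 0, r > 0)
  if (r >= d) warning("r >= d: index discs span neighboring seeding points")
  if (is.null(health)) health <- health_params(r = r)
  structure(list(segmentation = segmentation, classifier = classifier,
                 priors = priors, d = d, r = r, row_pitch = row_pitch,
                 row_y0 = row_y0, tile = tile, margin = margin,
                 seed = as.integer(seed), worker_count = as.integer(worker_count),
                 health = health),
            class = "pipeline_config")
}

#' Run the full plant-health pipeline
#'
#' Executes the object-based chain on a multispectral raster: tiled
#' mean-shift segmentation, classifier training from labeled signatures,
#' segment classification, per-row seeding-point detection, health indexing,
#' and (when a reference layout is supplied) validation. Artifacts are
#' written under `out_dir` when given; the run log records every effective
#' parameter and per-stage counts and durations.
#'
#' @param raster an [ms_raster] (or a path readable by [read_raster()]).
#' @param training either a signatures data.frame (`x`, `y`, `label`; labels
#'   are transferred to the segments containing the points) or a named
#'   vector segment-label -> class token.
#' @param cfg a [pipeline_config].
#' @param reference optional reference seeding-point layout (data.frame with
#'   `x`, `y` and optionally `class`) for validation.
#' @param out_dir optional output directory for the artifact files
#'   (segments, classified layer, seeding points, NDVI raster, summary
#'   tables, log).
#' @return list with `segmap`, `labels`, `model`, `points` (indexed seeding
#'   points), `ndvi`, `validation` (or NULL), `log`.
#' @export
run_pipeline <- function(raster, training, cfg = pipeline_config(),
                         reference = NULL, out_dir = NULL) {
  if (is.character(raster)) raster <- read_raster(raster)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  segmap <- stage("segmentation", {
    if (is.finite(cfg$tile) && cfg$tile < max(raster_dim(raster)))
      segment_tiled(raster, cfg$segmentation, tile = cfg$tile, margin = cfg$margin)
    else segment_raster(raster, cfg$segmentation)
  })
  log$segmentation$segments <- nrow(segmap$segments)
  log$segmentation$params <- unclass(cfg$segmentation)

  seg_labels <- stage("training", {
    if (is.data.frame(training)) {
      model_labels <- assign_labels(training, segmap)
      model_labels
    } else training
  })
  model <- stage("fit", {
    feats <- segment_features(segmap)
    rownames(feats) <- as.character(segmap$segments$label)
    train_feats <- feats[names(seg_labels), , drop = FALSE]
    fit_mlc(train_feats, unname(seg_labels), priors = cfg$priors)
  })
  labels <- stage("classification", {
    if (cfg$classifier == "mlc") classify_segments(model, segmap)$label
    else classify_baseline(cfg$classifier, model, segmap)
  })
  log$classification$by_class <- as.list(table(labels))

  detection <- stage("clustering", {
    mask <- vegetation_mask(segmap, labels)
    comps <- connected_components(mask, segmap)
    part <- partition_rows(comps, row_pitch = cfg$row_pitch, y0 = cfg$row_y0)
    run_parallel(part$groups, worker_count = cfg$worker_count, d = cfg$d,
                 seed = cfg$seed)
  })
  log$clustering$points <- nrow(detection$points)

  points <- stage("indexing",
                  index_all(detection$points, segmap, labels, cfg$health))
  nd <- stage("ndvi", ndvi(raster))

  validation <- NULL
  if (!is.null(reference)) {
    validation <- stage("validation",
                        validate_run(points, reference, tol = cfg$d / 2))
  }

  out <- list(segmap = segmap, labels = labels, model = model, points = points,
              ndvi = nd, validation = validation, log = log,
              config = cfg)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, raster, out_dir)
  out
}

#' Validate detected health indices against a reference layout
#'
#' Produces the seeding-point confusion matrix over the no-plant marker and
#' levels 1-5, the per-class precision column, and summary agreement rates
#' (exact and within one level, over truth points carrying a class).
#'
#' @param points indexed seeding points (`x`, `y`, `health_class`).
#' @param reference data.frame with `x`, `y` and `class` (integer 1-5 or NA
#'   for no plant; a `class` column with HL tokens or `"none"` is accepted).
#' @param tol pairing tolerance, meters.
#' @return list: `confusion` ([confusion_and_precision()] output),
#'   `recovered` (share of plant-bearing truth points matched), `exact`,
#'   `within_one` (class agreement over matched plant points).
#' @export
validate_run <- function(points, reference, tol = 0.15) {
  ref_cls <- reference$class
  if (is.character(ref_cls))
    ref_cls <- ifelse(ref_cls == "none", NA_integer_, health_value(ref_cls))
  m <- match_to_reference(points, reference, tol)
  truth_tok <- ifelse(is.na(ref_cls), "\u2205", as.character(ref_cls))
  pred_tok <- rep("\u2205", nrow(reference))
  if (nrow(m$pairs)) {
    pc <- points$health_class[m$pairs$det]
    pred_tok[m$pairs$ref] <- ifelse(is.na(pc), "\u2205", as.character(pc))
  }
  cm <- confusion_and_precision(truth_tok, pred_tok,
                                classes = c("\u2205", as.character(1:5)))
  alive <- which(!is.na(ref_cls))
  matched_alive <- intersect(m$pairs$ref, alive)
  recovered <- length(matched_alive) / max(length(alive), 1L)
  pidx <- m$pairs$det[match(matched_alive, m$pairs$ref)]
  dc <- points$health_class[pidx]
  tc <- ref_cls[matched_alive]
  ok <- !is.na(dc)
  exact <- if (length(tc)) mean(ok & dc == tc) else NA_real_
  within_one <- if (length(tc)) mean(ok & abs(dc - tc) <= 1) else NA_real_
  list(confusion = cm, recovered = recovered, exact = exact,
       within_one = within_one, matching = m)
}

write_pipeline_artifacts <- function(result, raster, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_vector(segments_to_layer(result$segmap, result$labels),
               file.path(out_dir, "segments.geojson"))
  pts <- result$points
  feats <- lapply(seq_len(nrow(pts)), function(i)
    point_feature(pts$x[i], pts$y[i],
                  component_id = pts$component_id[i], row_id = pts$row_id[i],
                  health_index = pts$health_index[i],
                  health_class = pts$health_class[i]))
  write_vector(vector_layer(feats, result$segmap$crs_id),
               file.path(out_dir, "seeding_points.geojson"), allow_empty = TRUE)
  write_raster(result$ndvi, file.path(out_dir, "ndvi"), dialect = "asc")
  utils::write.csv(health_count_table(pts),
                   file.path(out_dir, "health_by_row.csv"))
  if (!is.null(result$validation))
    write_confusion_csv(result$validation$confusion,
                        file.path(out_dir, "validation_confusion.csv"))
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
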