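#' Synthetic row-crop scene configuration
#'
#' Describes the emulated field: parallel double rows of roughly circular
#' plants on a soil background, seeded at regular spacing, with per-class
#' 4-band spectral means, additive Gaussian noise, and a shadow fringe ring
#' at plant edges. The defaults emulate the crop layout the pipeline targets:
#' 0.3 m between seeding points arranged in double rows with 0.5 m internal
#' and 1.5 m external separation, 4 cm pixels.
#'
#' @param rows number of plowing (double) rows; default 10.
#' @param points_per_row seeding points per plowing row (split between its
#'   two lines); default 30.
#' @param d seeding distance along a line, meters; default 0.3.
#' @param double_row_gap,inter_row_gap internal / external row separation in
#'   meters; defaults 0.5 and 1.5.
#' @param pixel_size meters per pixel; default 0.04.
#' @param margin soil border around the planted area, meters; default 0.75.
#' @param plant_radius_by_class named list `HL1`..`HL5` -> `c(mean, sd)`
#'   canopy radius in meters; defaults grow with health level and keep
#'   neighboring canopies mostly non-overlapping at 0.3 m spacing.
#' @param class_mix named probability vector over `none` (no surviving
#'   plant), `HL1`..`HL5`; must sum to 1.
#' @param band_means 7 x 4 matrix (rows `Soil`, `Shadow`, `HL1`..`HL5`;
#'   columns `G`, `R`, `RE`, `NIR`): per-class band means. The defaults keep
#'   soil flat and moderate, shadow low and flat, and separate health classes
#'   mainly in the red-edge and near-infrared bands, the strongest stress
#'   signal in this sensor range.
#' @param noise_sd additive per-band Gaussian noise sd (scalar or length 4).
#'   The default is 2\% of the mean across bands of the spread of class
#'   means.
#' @param shadow_fringe_px width of the shadow ring around plants, pixels.
#' @param jitter_sd planting-position jitter sd in meters; default 0.01.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return a `scene_config` object.
#' @export
scene_config <- function(rows = 10L, points_per_row = 30L, d = 0.3,
                         double_row_gap = 0.5, inter_row_gap = 1.5,
                         pixel_size = 0.04, margin = 0.75,
                         plant_radius_by_class = NULL, class_mix = NULL,
                         band_means = NULL, noise_sd = NULL,
                         shadow_fringe_px = 1L, jitter_sd = 0.01, seed = 1L) {
  if (double_row_gap <= 0 || inter_row_gap <= 0)
    stop("configuration error: row gaps must be positive (rows overlap)",
         call. = FALSE)
  stopifnot(rows >= 1, points_per_row >= 1, d > 0, pixel_size > 0, margin >= 0)
  if (is.null(plant_radius_by_class))
    plant_radius_by_class <- list(HL1 = c(0.07, 0.010), HL2 = c(0.09, 0.010),
                                  HL3 = c(0.11, 0.012), HL4 = c(0.12, 0.012),
                                  HL5 = c(0.13, 0.012))
  if (is.null(class_mix))
    class_mix <- c(none = 0.10, HL1 = 0.18, HL2 = 0.18, HL3 = 0.18,
                   HL4 = 0.18, HL5 = 0.18)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1", call. = FALSE)
  if (is.null(band_means)) band_means <- default_band_means()
  if (any(unlist(plant_radius_by_class)[c(TRUE, FALSE)] <= 0))
    stop("plant radii must be positive", call. = FALSE)
  if (is.null(noise_sd)) {
    spread <- mean(apply(band_means, 2, function(v) diff(range(v))))
    noise_sd <- 0.02 * spread
  }
  structure(list(rows = as.integer(rows), points_per_row = as.integer(points_per_row),
                 d = d, double_row_gap = double_row_gap,
                 inter_row_gap = inter_row_gap, pixel_size = pixel_size,
                 margin = margin, plant_radius_by_class = plant_radius_by_class,
                 class_mix = class_mix, band_means = band_means,
                 noise_sd = rep_len(noise_sd, 4L),
                 shadow_fringe_px = as.integer(shadow_fringe_px),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "scene_config")
}

default_band_means <- function() {
  m <- rbind(Soil   = c(28, 30, 32, 34),
             Shadow = c( 8,  8,  9, 10),
             HL1    = c(18, 16, 28, 38),
             HL2    = c(19, 15, 34, 46),
             HL3    = c(20, 14, 40, 54),
             HL4    = c(21, 13, 46, 62),
             HL5    = c(22, 12, 52, 70))
  colnames(m) <- c("G", "R", "RE", "NIR")
  m
}

# run expr with a locally seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sample_classes <- function(n, class_mix, seed) {
  with_local_seed(seed, sample(names(class_mix), n, replace = TRUE,
                               prob = class_mix))
}

scene_extent <- function(cfg) {
  per_line <- ceiling(cfg$points_per_row / 2)
  pitch <- cfg$double_row_gap + cfg$inter_row_gap
  list(width = 2 * cfg$margin + (per_line - 1) * cfg$d,
       height = 2 * cfg$margin + (cfg$rows - 1) * pitch + cfg$double_row_gap,
       pitch = pitch, per_line = per_line)
}

#' Row-banding model matching a synthetic scene
#'
#' @param cfg a [scene_config].
#' @return list with `row_pitch` and `y0` suitable for [partition_rows()]:
#'   band 1 starts just above the first double row.
#' @export
scene_row_model <- function(cfg) {
  ext <- scene_extent(cfg)
  list(row_pitch = ext$pitch, y0 = ext$height - cfg$margin + cfg$inter_row_gap / 2)
}

#' Generate a synthetic row-crop scene with ground truth
#'
#' Builds the soil background, draws a class for every seeding point from
#' `class_mix` (a `none` draw leaves the point bare), paints each plant as a
#' disc of class-dependent radius, rings plants with a shadow fringe, adds
#' per-band Gaussian noise, and returns the raster together with the full
#' truth: per-point positions/classes and the per-pixel label grid.
#'
#' @param cfg a [scene_config].
#' @return a `synthetic_scene`: list with `raster` ([ms_raster]),
#'   `truth_points` (data.frame: `x`, `y`, `class` token or `"none"`,
#'   `row_id`, `radius`), `truth_pixel_labels` (character matrix) and `cfg`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  ext <- scene_extent(cfg)
  nc <- ceiling(ext$width / cfg$pixel_size)
  nr <- ceiling(ext$height / cfg$pixel_size)
  classes_all <- rownames(cfg$band_means)

  # seeding grid: per plowing row, an upper and lower line
  pts <- list()
  for (i in seq_len(cfg$rows)) {
    y_up <- ext$height - cfg$margin - (i - 1) * ext$pitch
    y_lo <- y_up - cfg$double_row_gap
    n_up <- ceiling(cfg$points_per_row / 2)
    n_lo <- cfg$points_per_row - n_up
    xs_up <- cfg$margin + (seq_len(n_up) - 1) * cfg$d
    xs_lo <- cfg$margin + (seq_len(n_lo) - 1) * cfg$d
    pts[[i]] <- data.frame(x = c(xs_up, xs_lo),
                           y = c(rep(y_up, n_up), rep(y_lo, n_lo)),
                           row_id = i)
  }
  pts <- do.call(rbind, pts)
  n <- nrow(pts)

  truth <- with_local_seed(cfg$seed, {
    cls <- sample(names(cfg$class_mix), n, replace = TRUE, prob = cfg$class_mix)
    jit <- matrix(stats::rnorm(2 * n, 0, cfg$jitter_sd), n, 2)
    rad <- vapply(cls, function(cl) {
      if (cl == "none") return(NA_real_)
      p <- cfg$plant_radius_by_class[[cl]]
      max(stats::rnorm(1, p[1], p[2]), 1.5 * cfg$pixel_size)
    }, 0)
    list(cls = cls, jit = jit, rad = rad)
  })
  pts$x <- pts$x + truth$jit[, 1]
  pts$y <- pts$y + truth$jit[, 2]
  pts$class <- truth$cls
  pts$radius <- truth$rad

  lab <- matrix("Soil", nr, nc)
  # pixel-center world coordinates
  px_x <- function(col0) (col0 + 0.5) * cfg$pixel_size
  px_y <- function(row0) ext$height - (row0 + 0.5) * cfg$pixel_size

  paint <- function(lab, cx, cy, radius, value, only_soil = FALSE) {
    c0 <- max(0, floor((cx - radius) / cfg$pixel_size) - 1)
    c1 <- min(nc - 1, ceiling((cx + radius) / cfg$pixel_size))
    r0 <- max(0, floor((ext$height - cy - radius) / cfg$pixel_size) - 1)
    r1 <- min(nr - 1, ceiling((ext$height - cy + radius) / cfg$pixel_size))
    if (c0 > c1 || r0 > r1) return(lab)
    cols <- c0:c1; rows <- r0:r1
    g <- expand.grid(row = rows, col = cols)
    d2 <- (px_x(g$col) - cx)^2 + (px_y(g$row) - cy)^2
    sel <- d2 <= radius^2
    if (only_soil) {
      cur <- lab[cbind(g$row + 1L, g$col + 1L)]
      sel <- sel & cur == "Soil"
    }
    lab[cbind(g$row[sel] + 1L, g$col[sel] + 1L)] <- value
    lab
  }

  alive <- which(pts$class != "none")
  for (i in alive)
    lab <- paint(lab, pts$x[i], pts$y[i], pts$radius[i], pts$class[i])
  if (cfg$shadow_fringe_px > 0L) {
    fr <- cfg$shadow_fringe_px * cfg$pixel_size
    for (i in alive)
      lab <- paint(lab, pts$x[i], pts$y[i], pts$radius[i] + fr, "Shadow",
                   only_soil = TRUE)
  }

  bands <- with_local_seed(cfg$seed + 1L, {
    lapply(seq_len(4L), function(b) {
      v <- cfg$band_means[match(lab, classes_all), b]
      m <- matrix(v, nr, nc)
      if (cfg$noise_sd[b] > 0)
        m <- m + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd[b]), nr, nc)
      pmax(m, 0)
    })
  })
  names(bands) <- colnames(cfg$band_means)

  raster <- ms_raster(bands, origin = c(0, ext$height),
                      pixel_size = cfg$pixel_size, crs_id = "local-metric")
  structure(list(raster = raster, truth_points = pts,
                 truth_pixel_labels = lab, cfg = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d seeding point(s) (%d alive)\n",
              nrow(x$truth_pixel_labels), ncol(x$truth_pixel_labels),
              nrow(x$truth_points), sum(x$truth_points$class != "none")))
  invisible(x)
}

#' Sample labeled training signatures from scene truth
#'
#' Emulates the field procedure of collecting georeferenced labeled spectra:
#' picks pixel centers whose truth label is known, spread over every class
#' present, and returns them as a signatures table usable by
#' [assign_labels()].
#'
#' @param scene a `synthetic_scene`.
#' @param per_class signatures per class; default 40.
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `label`.
#' @export
scene_training_signatures <- function(scene, per_class = 40L, seed = 1L) {
  lab <- scene$truth_pixel_labels
  nr <- nrow(lab); nc <- ncol(lab)
  ext_h <- scene$raster$origin[2]
  with_local_seed(seed, {
    out <- lapply(unique(as.vector(lab)), function(cl) {
      idx <- which(lab == cl)
      take <- sample(idx, min(per_class, length(idx)))
      row0 <- (take - 1L) %% nr
      col0 <- (take - 1L) %/% nr
      data.frame(x = (col0 + 0.5) * scene$raster$pixel_size[1],
                 y = ext_h - (row0 + 0.5) * scene$raster$pixel_size[2],
                 label = cl)
    })
    do.call(rbind, out)
  })
}

#' Confusion matrix of pipeline predictions against scene truth
#'
#' Pairs predicted seeding points to the truth layout with
#' [match_to_reference()] and tabulates truth class against predicted class
#' over the no-plant marker and levels 1-5: an unmatched truth point counts
#' as predicted no-plant; a truth `none` point matched by a detection counts
#' in the no-plant truth row under the detection's class.
#'
#' @param scene a `synthetic_scene`.
#' @param predicted data.frame with `x`, `y`, `health_class`.
#' @param tol pairing tolerance in meters; default `d / 2`.
#' @return a [confusion_and_precision()]-style list (`matrix`, `precision`).
#' @export
truth_confusion <- function(scene, predicted, tol = scene$cfg$d / 2) {
  truth_cls <- ifelse(scene$truth_points$class == "none", "\u2205",
                      as.character(health_value(scene$truth_points$class)))
  m <- match_to_reference(predicted, scene$truth_points, tol)
  pred_cls <- rep("\u2205", nrow(scene$truth_points))
  if (nrow(m$pairs)) {
    pc <- predicted$health_class[m$pairs$det]
    pred_cls[m$pairs$ref] <- ifelse(is.na(pc), "\u2205", as.character(pc))
  }
  confusion_and_precision(truth_cls, pred_cls,
                          classes = c("\u2205", as.character(1:5)))
}
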