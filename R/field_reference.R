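#' Spectrometer wavelength polynomial
#'
#' Maps a 288-channel spectrometer's pixel index to a wavelength via a
#' degree-5 polynomial with factory-calibrated coefficients. The default
#' coefficients are those of the C12880MA unit used to collect field
#' signatures; evaluation is rounded half-up to the nearest integer
#' nanometer.
#'
#' @param coef named numeric: `A0`, `B1`..`B5`.
#' @return a `wavelength_poly` object.
#' @export
wavelength_poly <- function(coef = c(A0 = 3.17926058e2, B1 = 2.69726310,
                                     B2 = -1.32864319e-3, B3 = -5.39983110e-6,
                                     B4 = -7.95625547e-10, B5 = 2.01449675e-11)) {
  stopifnot(all(c("A0", "B1", "B2", "B3", "B4", "B5") %in% names(coef)))
  structure(list(coef = coef, valid_range = c(0L, 287L)),
            class = "wavelength_poly")
}

#' @rdname wavelength_poly
#' @param x integer channel index (0..287; vectorized).
#' @param poly a `wavelength_poly`.
#' @return integer wavelength(s) in nm.
#' @export
wavelength_of_pixel <- function(x, poly = wavelength_poly()) {
  if (any(x < poly$valid_range[1] | x > poly$valid_range[2]))
    stop("validation error: channel index outside ", poly$valid_range[1], "..",
         poly$valid_range[2], call. = FALSE)
  cf <- poly$coef
  p <- cf["A0"] + cf["B1"] * x + cf["B2"] * x^2 + cf["B3"] * x^3 +
    cf["B4"] * x^4 + cf["B5"] * x^5
  as.integer(round_half_up(unname(p)))
}

#' Linear reflectance calibration for raw spectrometer counts
#'
#' An explicit linear contract: `reflectance = (raw / light_level) /
#' panel_reference` per channel, clipped to `[0, 1.5]`. Channels whose panel
#' reference is zero are masked (NA) with a warning.
#'
#' @param raw numeric vector of raw channel counts.
#' @param panel_reference reflectance-panel counts, same length.
#' @param light_level scalar irradiance normalizer (> 0).
#' @return numeric reflectance vector (NA at masked channels).
#' @export
calibrate_reflectance <- function(raw, panel_reference, light_level = 1) {
  stopifnot(length(raw) == length(panel_reference), light_level > 0)
  zero <- panel_reference == 0
  if (any(zero))
    warning(sum(zero), " channel(s) with zero panel reference masked")
  out <- (raw / light_level) / panel_reference
  out[zero] <- NA_real_
  pmin(pmax(out, 0), 1.5)
}

#' Transfer signature labels to segments
#'
#' Each georeferenced signature labels the segment whose footprint contains
#' its point (containment is evaluated on the label grid — exact for the
#' rectilinear footprints). Conflicting labels for one segment resolve by
#' majority; ties leave the segment unlabeled with a warning. Points outside
#' the raster (or on nodata) are reported.
#'
#' @param signatures data.frame with `x`, `y`, `label` (see
#'   [read_signatures()]).
#' @param segmap a `segment_map`.
#' @return named character vector: segment label (character) -> class token,
#'   with attribute `outside` listing signature row indices that hit no
#'   segment.
#' @export
assign_labels <- function(signatures, segmap) {
  nr <- nrow(segmap$label_grid); nc <- ncol(segmap$label_grid)
  col <- floor((signatures$x - segmap$origin[1]) / segmap$pixel_size[1])
  row <- floor((segmap$origin[2] - signatures$y) / segmap$pixel_size[2])
  inside <- col >= 0 & col < nc & row >= 0 & row < nr
  seg <- rep(NA_integer_, nrow(signatures))
  seg[inside] <- segmap$label_grid[cbind(row[inside] + 1L, col[inside] + 1L)]
  seg[!is.na(seg) & seg < 0L] <- NA_integer_
  outside <- which(is.na(seg))
  if (length(outside) == nrow(signatures))
    warning("all signature points fall outside the segmented raster")
  out <- character(0)
  ok <- !is.na(seg)
  for (s in unique(seg[ok])) {
    votes <- table(signatures$label[ok & seg == s])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      warning("tied labels for segment ", s, "; left unlabeled")
      next
    }
    out[as.character(s)] <- top
  }
  attr(out, "outside") <- outside
  out
}

# Per-trait level bins. Lower bounds inclusive, upper bounds exclusive,
# except: the best height/surface bins are open above, the worst
# symptom-percentage bins are closed below (so the bins tile the whole range),
# and a symptom percentage of exactly 0 imposes no constraint (level 5).
trait_level <- function(trait, value) {
  switch(trait,
    height = {
      fi <- findInterval(value, c(30, 40, 50, 60))
      fi[value == 60] <- 3L                 # "50 to 60" is closed at 60
      fi + 1L
    },
    surface = {
      fi <- findInterval(value, c(0.10, 0.15, 0.20, 0.25))
      fi[value == 0.25] <- 3L               # "0.20 to 0.25" closed at 0.25
      fi + 1L
    },
    curly = c(5L, 4L, 3L, 2L, 1L)[findInterval(value, c(10, 15, 30, 60)) + 1L],
    spotted = ifelse(value == 0, 5L,
                     c(3L, 2L, 1L)[findInterval(value, c(10, 20)) + 1L]),
    chlorotic = ifelse(value == 0, 5L,
                       c(3L, 2L, 1L)[findInterval(value, c(20, 40)) + 1L]),
    stop("unknown trait: ", trait))
}

#' Categorize a plant phenotype into a health level
#'
#' Each of the five phenotypic traits (height in cm, canopy surface in m2,
#' and the percentages of curly, spotted and chlorotic leaves) maps to a
#' level 1-5 via its trait bins; the plant's category is, by default, the
#' minimum (worst) per-trait level — a single severe symptom caps the
#' category. `rule = "majority"` takes the most frequent level instead (ties
#' resolve to the worse level).
#'
#' @param height_cm,surface_m2,curly_pct,spotted_pct,chlorotic_pct trait
#'   values (percentages in 0-100).
#' @param rule `"min"` (default) or `"majority"`.
#' @return class token `"HL1"`..`"HL5"`.
#' @export
categorize_phenotype <- function(height_cm, surface_m2, curly_pct, spotted_pct,
                                 chlorotic_pct, rule = c("min", "majority")) {
  rule <- match.arg(rule)
  stopifnot(height_cm >= 0, surface_m2 >= 0,
            all(c(curly_pct, spotted_pct, chlorotic_pct) >= 0),
            all(c(curly_pct, spotted_pct, chlorotic_pct) <= 100))
  lv <- c(trait_level("height", height_cm),
          trait_level("surface", surface_m2),
          trait_level("curly", curly_pct),
          trait_level("spotted", spotted_pct),
          trait_level("chlorotic", chlorotic_pct))
  level <- if (rule == "min") min(lv) else {
    tab <- table(lv)
    as.integer(names(tab)[tab == max(tab)][1])
  }
  paste0("HL", level)
}
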