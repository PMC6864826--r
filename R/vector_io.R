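#' Vector layer of points or polygons
#'
#' Lightweight in-memory feature collection: each feature couples a geometry
#' (point or single-ring polygon, world coordinates in meters) with a flat
#' attribute table. Serialized as GeoJSON (default) or as a WKT-CSV table.
#'
#' @param features list of features; each is `list(geometry = g, attributes =
#'   list(...))` where `g` is `list(type = "Point", coords = c(x, y))` or
#'   `list(type = "Polygon", coords = <n x 2 matrix, closed ring>)`.
#' @param crs_id CRS identifier shared by all features.
#' @return an object of class `vector_layer`.
#' @export
vector_layer <- function(features = list(), crs_id = "unknown") {
  structure(list(features = features, crs_id = as.character(crs_id)[1]),
            class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type, "")
  cat(sprintf("<vector_layer> %d feature(s) [%s], crs '%s'\n", length(x$features),
              paste(names(table(types)), table(types), collapse = ", ", sep = ":"),
              x$crs_id))
  invisible(x)
}

point_feature <- function(x, y, ...) {
  list(geometry = list(type = "Point", coords = c(x, y)), attributes = list(...))
}

polygon_feature <- function(ring, ...) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("polygon ring needs >= 3 vertices", call. = FALSE)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  list(geometry = list(type = "Polygon", coords = ring), attributes = list(...))
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-15) return(FALSE)      # parallel: treated as non-crossing
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L                      # closed ring: last vertex repeats first
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jj <- seq.int(i + 2L, n)
    jj <- jj[!(i == 1L & jj == n)]          # edges sharing a vertex are fine
    for (j in jj) {
      if (segments_intersect(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

validate_layer <- function(layer) {
  for (i in seq_along(layer$features)) {
    g <- layer$features[[i]]$geometry
    if (g$type == "Polygon" && ring_self_intersects(g$coords))
      stop("validation error: self-intersecting polygon at feature index ", i,
           call. = FALSE)
    if (g$type == "Point" && any(!is.finite(g$coords)))
      stop("validation error: non-finite point at feature index ", i, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a vector layer
#'
#' @param layer a [vector_layer].
#' @param path output file path.
#' @param dialect `"geojson"` (default) or `"wkt-csv"` (WKT geometry column
#'   plus one column per attribute).
#' @param allow_empty write a layer with zero features instead of erroring.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path, dialect = c("geojson", "wkt-csv"),
                         allow_empty = FALSE) {
  dialect <- match.arg(dialect)
  if (!length(layer$features) && !allow_empty)
    stop("validation error: empty layer (set allow_empty = TRUE to permit)",
         call. = FALSE)
  validate_layer(layer)
  if (dialect == "geojson") {
    feats <- lapply(layer$features, function(f) {
      g <- f$geometry
      coords <- if (g$type == "Point") as.list(unname(g$coords)) else
        list(lapply(seq_len(nrow(g$coords)), function(i) as.list(unname(g$coords[i, ]))))
      list(type = "Feature",
           geometry = list(type = g$type, coordinates = coords),
           properties = if (length(f$attributes)) f$attributes else
             structure(list(), names = character()))
    })
    doc <- list(type = "FeatureCollection",
                crs = list(type = "name", properties = list(name = layer$crs_id)),
                features = feats)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    rows <- lapply(layer$features, function(f) {
      g <- f$geometry
      wkt <- if (g$type == "Point")
        sprintf("POINT (%.17g %.17g)", g$coords[1], g$coords[2])
      else sprintf("POLYGON ((%s))",
                   paste(sprintf("%.17g %.17g", g$coords[, 1], g$coords[, 2]),
                         collapse = ", "))
      c(list(wkt = wkt), f$attributes)
    })
    keys <- unique(unlist(lapply(rows, names)))
    tab <- as.data.frame(do.call(rbind, lapply(rows, function(r)
      vapply(keys, function(k) as.character(r[[k]] %||% NA), ""))),
      stringsAsFactors = FALSE)
    names(tab) <- keys
    utils::write.csv(cbind(crs = layer$crs_id, tab), path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a vector layer written by [write_vector()]
#'
#' @param path file path; dialect inferred from extension (`.geojson`/`.json`
#'   vs `.csv`).
#' @return a [vector_layer].
#' @export
read_vector <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(read_vector_wktcsv(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  crs_id <- doc$crs$properties$name %||% "unknown"
  feats <- lapply(doc$features, function(f) {
    ty <- f$geometry$type
    coords <- if (ty == "Point") unlist(f$geometry$coordinates) else
      do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    list(geometry = list(type = ty, coords = coords),
         attributes = f$properties %||% list())
  })
  vector_layer(feats, crs_id)
}

read_vector_wktcsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"wkt" %in% names(tab)) stop("WKT-CSV layer lacks a 'wkt' column", call. = FALSE)
  crs_id <- if ("crs" %in% names(tab) && nrow(tab)) tab$crs[1] else "unknown"
  attr_cols <- setdiff(names(tab), c("wkt", "crs"))
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    wkt <- tab$wkt[i]
    if (grepl("^POINT", wkt)) {
      xy <- as.numeric(strsplit(gsub("^POINT \\(|\\)$", "", wkt), " ")[[1]])
      g <- list(type = "Point", coords = xy)
    } else {
      body <- gsub("^POLYGON \\(\\(|\\)\\)$", "", wkt)
      pts <- do.call(rbind, lapply(strsplit(body, ", ")[[1]], function(s)
        as.numeric(strsplit(s, " ")[[1]])))
      g <- list(type = "Polygon", coords = pts)
    }
    list(geometry = g, attributes = as.list(tab[i, attr_cols, drop = FALSE]))
  })
  vector_layer(feats, crs_id)
}

#' Read georeferenced signature records
#'
#' Parses a delimited table of georeferenced, labeled field measurements:
#' coordinate columns (`lon`/`lat`, or `x`/`y` for a projected/local metric
#' frame), a `label` column, and optionally a block of numeric channel
#' columns (e.g. 288 spectrometer channels) forming each record's payload.
#'
#' @param path CSV file path.
#' @param channel_prefix columns whose names start with this prefix (default
#'   `"ch"`) are collected, in order, into the record payload vector.
#' @return data.frame with columns `x`, `y`, `projected` (logical), `label`,
#'   and a `payload` list-column (NULL when no channel columns exist).
#' @export
read_signatures <- function(path, channel_prefix = "ch") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  has_ll <- all(c("lon", "lat") %in% nm)
  has_xy <- all(c("x", "y") %in% nm)
  if (!has_ll && !has_xy)
    stop("schema error: need coordinate columns lon/lat or x/y", call. = FALSE)
  if (!"label" %in% nm) stop("schema error: missing 'label' column", call. = FALSE)
  cx <- if (has_xy) which(nm == "x") else which(nm == "lon")
  cy <- if (has_xy) which(nm == "y") else which(nm == "lat")
  xs <- suppressWarnings(as.numeric(tab[[cx]]))
  ys <- suppressWarnings(as.numeric(tab[[cy]]))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop("malformed coordinate(s) at data row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  chan_cols <- which(startsWith(names(tab), channel_prefix) &
                       !nm %in% c("x", "y", "lon", "lat", "label"))
  payload <- if (length(chan_cols)) {
    lapply(seq_len(nrow(tab)), function(i) as.numeric(tab[i, chan_cols]))
  } else rep(list(NULL), nrow(tab))
  out <- data.frame(x = xs, y = ys, projected = has_xy,
                    label = as.character(tab[[which(nm == "label")]]),
                    stringsAsFactors = FALSE)
  out$payload <- payload
  out
}
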