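#' Round half away from zero
#'
#' Commercial rounding (0.5 goes up) used wherever a real-valued quantity is
#' discretized: cluster counts, health classes, wavelengths.
#'
#' @param x numeric.
#' @return numeric of the same length.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Binary vegetation mask from classified segments
#'
#' @param segmap a `segment_map`.
#' @param labels named character vector: segment label (as character) ->
#'   class token; every segment must be covered.
#' @return logical matrix, TRUE exactly at pixels of HL1..HL5 segments.
#' @export
vegetation_mask <- function(segmap, labels) {
  seglab <- as.character(segmap$segments$label)
  if (!all(seglab %in% names(labels)))
    stop("every segment must be labeled", call. = FALSE)
  veg <- seglab[is_vegetation_label(labels[seglab])]
  matrix(segmap$label_grid %in% as.integer(veg),
         nrow(segmap$label_grid), ncol(segmap$label_grid))
}

# 4-connected component labels of TRUE cells: 0 for FALSE, 1..n for components
connected_true_regions <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  v <- as.vector(mask)
  pair_block <- function(a, b) {
    keep <- v[a] & v[b]
    cbind(a[keep], b[keep])
  }
  e <- NULL
  if (nr > 1L) e <- pair_block(as.vector(idx[-nr, ]), as.vector(idx[-1L, ]))
  if (nc > 1L) e <- rbind(e, pair_block(as.vector(idx[, -nc]), as.vector(idx[, -1L])))
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (!is.null(e) && nrow(e)) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  comp[!v] <- 0L
  if (any(v)) {
    tru <- unique(comp[v])
    comp[v] <- match(comp[v], tru)
  }
  matrix(as.integer(comp), nr, nc)
}

#' Connected components of a vegetation mask
#'
#' 4-connected TRUE regions with dense ids; each component carries its member
#' pixels' world coordinates and its area in square meters (pixel count times
#' pixel area).
#'
#' @param mask logical matrix from [vegetation_mask()].
#' @param segmap the `segment_map` the mask came from (georeferencing source);
#'   alternatively any object with `origin` and `pixel_size` fields.
#' @return list of components: each `list(component_id, pixel_idx, coords
#'   (n x 2 world matrix), area)`. Empty mask gives an empty list.
#' @export
connected_components <- function(mask, segmap) {
  comp <- connected_true_regions(mask)
  n <- max(comp)
  if (n == 0L) return(list())
  px_area <- prod(segmap$pixel_size)
  out <- vector("list", n)
  cells <- which(comp > 0L, arr.ind = TRUE)
  ids <- comp[comp > 0L]
  for (i in seq_len(n)) {
    sel <- cells[ids == i, , drop = FALSE]
    col0 <- sel[, 2] - 1L; row0 <- sel[, 1] - 1L
    coords <- cbind(x = segmap$origin[1] + (col0 + 0.5) * segmap$pixel_size[1],
                    y = segmap$origin[2] - (row0 + 0.5) * segmap$pixel_size[2])
    out[[i]] <- list(component_id = i, pixel_idx = sel, coords = coords,
                     area = nrow(sel) * px_area)
  }
  out
}

#' Cluster count for a vegetation region
#'
#' The number of seeding points expected in a connected vegetation region of
#' area `a` is the number of inscribed circles of diameter `d` that fit by
#' area: `k = 4 a / (pi d^2)`, rounded half-up with a floor of 1.
#'
#' @param area_m2 region area in square meters (> 0).
#' @param d seeding-point separation in meters (> 0); default 0.3.
#' @return positive integer k.
#' @export
estimate_k <- function(area_m2, d = 0.3) {
  if (!is.finite(area_m2) || area_m2 <= 0 || !is.finite(d) || d <= 0)
    stop("validation error: area and d must be positive", call. = FALSE)
  max(1L, as.integer(round_half_up(4 * area_m2 / (pi * d^2))))
}

#' Seeded Lloyd KMeans on spatial coordinates
#'
#' Deterministic k-means++-style initialization driven by an integer seed,
#' followed by at most `max_iter` Lloyd iterations. A cluster that empties is
#' re-seeded to the point farthest from its assigned center. The final
#' assignment is the Voronoi partition of the centers.
#'
#' @param coords n x 2 numeric matrix of point coordinates.
#' @param k number of clusters; if `k > n` it is reduced to `n` with a
#'   warning.
#' @param max_iter Lloyd iteration cap; default 20.
#' @param seed integer seed for the initialization.
#' @return list with `centers` (k x 2), `assignment` (integer in 1..k) and
#'   `wss` (total within-cluster sum of squares).
#' @export
kmeans_centers <- function(coords, k, max_iter = 20L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n) {
    warning("k reduced from ", k, " to the point count ", n)
    k <- n
  }
  stopifnot(k >= 1L)
  centers <- kpp_init(coords, k, seed)
  assign_pts <- function(centers) {
    d2 <- outer(rowSums(coords^2), rep(1, nrow(centers))) -
      2 * coords %*% t(centers) + outer(rep(1, n), rowSums(centers^2))
    max.col(-d2, ties.method = "first")
  }
  asg <- assign_pts(centers)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      sel <- asg == j
      if (!any(sel)) {
        # re-seed an empty cluster to the point farthest from its center
        far <- which.max(rowSums((coords - centers[asg, , drop = FALSE])^2))
        centers[j, ] <- coords[far, ]
      } else {
        centers[j, ] <- colMeans(coords[sel, , drop = FALSE])
      }
    }
    new_asg <- assign_pts(centers)
    if (all(new_asg == asg)) { asg <- new_asg; break }
    asg <- new_asg
  }
  wss <- sum((coords - centers[asg, , drop = FALSE])^2)
  list(centers = centers, assignment = asg, wss = wss)
}

# deterministic k-means++ initialization from an integer seed (own RNG stream;
# global RNG state untouched)
kpp_init <- function(coords, k, seed) {
  n <- nrow(coords)
  rng <- seeded_rng(seed)
  centers <- matrix(NA_real_, k, ncol(coords))
  centers[1, ] <- coords[floor(rng() * n) + 1L, ]
  if (k > 1L) {
    d2 <- rowSums((coords - matrix(centers[1, ], n, 2, byrow = TRUE))^2)
    for (j in 2L:k) {
      tot <- sum(d2)
      if (tot <= 0) {
        pick <- floor(rng() * n) + 1L
      } else {
        cum <- cumsum(d2) / tot
        pick <- findInterval(rng(), cum) + 1L
        pick <- min(pick, n)
      }
      centers[j, ] <- coords[pick, ]
      d2 <- pmin(d2, rowSums((coords - matrix(centers[j, ], n, 2, byrow = TRUE))^2))
    }
  }
  centers
}

# tiny splittable LCG: all package randomness flows from integer seeds through
# this, leaving R's global RNG untouched
seeded_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

#' Detect seeding points in vegetation components
#'
#' Per component: `k = estimate_k(area, d)` and `k` KMeans centers on the
#' component's member-pixel world coordinates. Components with fewer than 3
#' pixels yield one point at their pixel centroid.
#'
#' @param components list from [connected_components()].
#' @param d seeding distance in meters; default 0.3.
#' @param max_iter Lloyd cap per component; default 20.
#' @param seed integer seed; each component derives its own deterministic
#'   stream from `seed` and its component id.
#' @param row_ids optional integer vector of plowing-row ids per component.
#' @return data.frame of seeding points: `x`, `y`, `component_id`,
#'   `cluster_size`, `row_id`.
#' @export
detect_seeding_points <- function(components, d = 0.3, max_iter = 20L,
                                  seed = 1L, row_ids = NULL) {
  if (!length(components))
    return(data.frame(x = numeric(), y = numeric(), component_id = integer(),
                      cluster_size = integer(), row_id = integer()))
  res <- lapply(seq_along(components), function(ci) {
    comp <- components[[ci]]
    rid <- if (is.null(row_ids)) NA_integer_ else row_ids[[ci]]
    if (nrow(comp$coords) < 3L) {
      ctr <- colMeans(comp$coords)
      return(data.frame(x = ctr[1], y = ctr[2], component_id = comp$component_id,
                        cluster_size = nrow(comp$coords), row_id = rid))
    }
    k <- estimate_k(comp$area, d)
    km <- suppressWarnings(
      kmeans_centers(comp$coords, k, max_iter,
                     seed = (as.numeric(seed) * 10007 + comp$component_id) %% 2147483647))
    sizes <- tabulate(km$assignment, nbins = nrow(km$centers))
    data.frame(x = km$centers[, 1], y = km$centers[, 2],
               component_id = comp$component_id, cluster_size = sizes,
               row_id = rid)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partition components into plowing-row groups
#'
#' Groups vegetation components by plowing row so each group can be clustered
#' independently (components in different groups share no pixels, hence no
#' data dependency). The default model bands the y world coordinate with a
#' fixed pitch; explicit row polygons (y-intervals) override.
#'
#' @param components list from [connected_components()].
#' @param row_pitch row spacing in meters (banding model).
#' @param y0 y coordinate of the first band's upper edge; defaults to the
#'   maximum component y.
#' @param row_intervals optional matrix/data.frame with columns `ymin`,
#'   `ymax`: explicit row extents (overrides banding). A component straddling
#'   rows goes to the row containing its centroid.
#' @return list with `groups` (list: row id -> list of components) and
#'   `row_id` (integer per component).
#' @export
partition_rows <- function(components, row_pitch = 2.0, y0 = NULL,
                           row_intervals = NULL) {
  if (!length(components)) return(list(groups = list(), row_id = integer()))
  cy <- vapply(components, function(c) mean(c$coords[, 2]), 0)
  if (!is.null(row_intervals)) {
    ri <- as.data.frame(row_intervals)
    rid <- vapply(cy, function(y) {
      hit <- which(y >= ri$ymin & y <= ri$ymax)
      if (!length(hit)) NA_integer_ else hit[1]
    }, 0L)
    if (any(is.na(rid)))
      stop("row model does not cover all components", call. = FALSE)
  } else {
    if (is.null(y0)) y0 <- max(vapply(components, function(c) max(c$coords[, 2]), 0))
    rid <- as.integer(floor((y0 - cy) / row_pitch)) + 1L
  }
  groups <- split(components, rid)
  list(groups = groups, row_id = rid)
}
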