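# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Direct per-pixel mean-shift iteration: plain R double loop over all pixels.
# bands: npix x nb (column-major pixel order), dims c(nr, nc).
oracle_mean_shift <- function(bands, dims, hs, hr, kernel = "epanechnikov",
                              max_iter = 100L, tol = 0.1) {
  nr <- dims[1]; nc <- dims[2]
  npix <- nr * nc
  nb <- ncol(bands)
  sp <- matrix(NA_real_, npix, 2)
  scm <- matrix(NA_real_, npix, nb)
  coords <- cbind(col = rep(0:(nc - 1), each = nr), row = rep(0:(nr - 1), nc))
  for (p in seq_len(npix)) {
    y_s <- coords[p, ]
    y_r <- bands[p, ]
    for (j in seq_len(max_iter)) {
      ds2 <- ((coords[, 1] - y_s[1])^2 + (coords[, 2] - y_s[2])^2) / hs^2
      dr2 <- rowSums((bands - matrix(y_r, npix, nb, byrow = TRUE))^2) / hr^2
      inside <- ds2 <= 1 & dr2 <= 1
      u2 <- ds2[inside] + dr2[inside]
      w <- if (kernel == "epanechnikov") pmax(1 - u2, 0) else exp(-u2 / 2)
      if (sum(w) <= 0) break
      new_s <- c(sum(w * coords[inside, 1]), sum(w * coords[inside, 2])) / sum(w)
      new_r <- colSums(w * bands[inside, , drop = FALSE]) / sum(w)
      disp <- sqrt(sum((new_s - y_s)^2) / hs^2 + sum((new_r - y_r)^2) / hr^2)
      y_s <- new_s; y_r <- new_r
      if (disp < tol) break
    }
    sp[p, ] <- y_s
    scm[p, ] <- y_r
  }
  list(spatial = sp, spectral = scm)
}

# Flood-fill (BFS) 4-connected components of TRUE cells; 0 elsewhere.
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- q[1] + dd[1]; jj <- q[2] + dd[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Gaussian log-density evaluated the long way (explicit solve + det).
oracle_mlc_scores <- function(mu_list, sigma_list, priors, x) {
  d <- length(x)
  vapply(seq_along(mu_list), function(i) {
    S <- sigma_list[[i]]
    diff <- x - mu_list[[i]]
    as.numeric(-0.5 * t(diff) %*% solve(S) %*% diff - 0.5 * log(det(S)) -
                 d / 2 * log(2 * pi) + log(priors[i]))
  }, 0)
}

# Exact rectangle-disc intersection: closed-form distance from a point to an
# axis-aligned rectangle [x0,x1] x [y0,y1].
oracle_rect_disc <- function(x0, x1, y0, y1, px, py, r) {
  dx <- max(x0 - px, px - x1, 0)
  dy <- max(y0 - py, py - y1, 0)
  dx^2 + dy^2 <= r^2 + 1e-15
}

# Brute-force optimal one-to-one assignment (minimizing total distance) for
# tiny instances; returns matched (ref, det) pairs within tol.
oracle_optimal_pairing <- function(reference, detected, tol) {
  nr <- nrow(reference); nd <- nrow(detected)
  dist <- sqrt(outer(reference$x, detected$x, `-`)^2 +
                 outer(reference$y, detected$y, `-`)^2)
  k <- min(nr, nd)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  det_perms <- function(v, m) {
    if (m == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in det_perms(v[-i], m - 1)) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  ref_sets <- utils::combn(nr, k, simplify = FALSE)
  for (rs in ref_sets) {
    for (dp in det_perms(seq_len(nd), k)) {
      dd <- dist[cbind(rs, dp)]
      okpairs <- dd <= tol
      n_ok <- sum(okpairs)
      cost <- sum(dd[okpairs])
      if (n_ok > best_n || (n_ok == best_n && cost < best_cost)) {
        best_n <- n_ok; best_cost <- cost
        best <- cbind(ref = rs[okpairs], det = dp[okpairs])
      }
    }
  }
  best[order(best[, 1]), , drop = FALSE]
}

band_matrix_of <- function(r) do.call(cbind, lapply(r$bands, as.vector))

# small helper: constant-band raster
make_raster <- function(values, nr = NULL, nc = NULL, bands = c("G", "R", "RE", "NIR"),
                        pixel_size = 1, origin = NULL) {
  if (is.matrix(values)) { nr <- nrow(values); nc <- ncol(values) }
  if (is.null(origin)) origin <- c(0, nr * pixel_size)
  b <- lapply(seq_along(bands), function(i)
    if (is.matrix(values)) values else matrix(values[i], nr, nc))
  names(b) <- bands
  ms_raster(b, origin = origin, pixel_size = pixel_size)
}

rand_raster <- function(nr, nc, nb = 1, lo = 0, hi = 100, seed = 1) {
  set.seed(seed)
  b <- lapply(seq_len(nb), function(i) matrix(runif(nr * nc, lo, hi), nr, nc))
  names(b) <- c("G", "R", "RE", "NIR")[seq_len(nb)]
  ms_raster(b, origin = c(0, nr), pixel_size = 1)
}
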