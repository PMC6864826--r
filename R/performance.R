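#' Amdahl's-law speedup
#'
#' `S(Np) = 1 / ((1 - P) + P / Np)` for a program whose fraction `P` of the
#' work parallelizes perfectly over `Np` processors.
#'
#' @param P parallel fraction in `[0, 1]`.
#' @param n_procs processor count (>= 1).
#' @return the speedup (>= 1).
#' @export
amdahl_speedup <- function(P, n_procs) {
  if (any(P < 0 | P > 1)) stop("validation error: P must lie in [0, 1]",
                               call. = FALSE)
  stopifnot(n_procs >= 1)
  1 / ((1 - P) + P / n_procs)
}

#' Parallel fraction from a measured speedup
#'
#' Inverts Amdahl's law: `P = (1 - 1/S) / (1 - 1/Np)`, reported to 4
#' decimals (the rounding used in published speedup tables). A super-linear
#' `S > Np` yields a warning but still returns the value.
#'
#' @param S measured speedup (>= 1).
#' @param n_procs processor count (>= 2).
#' @param digits rounding; default 4, `NA` for unrounded.
#' @return the parallel fraction.
#' @export
parallel_fraction <- function(S, n_procs, digits = 4) {
  stopifnot(S >= 1, n_procs >= 2)
  if (S > n_procs) warning("super-linear speedup: S exceeds n_procs")
  P <- (1 - 1 / S) / (1 - 1 / n_procs)
  if (is.na(digits)) P else round(P, digits)
}

#' Speedup table from measured times
#'
#' Builds the standard performance table for a strong-scaling experiment:
#' speedup against the 1-process time and the implied parallel fraction.
#'
#' @param n_procs integer vector including 1.
#' @param time_min measured wall times (same order).
#' @return data.frame with `n_procs`, `time_min`, `speedup`, `P`, `serial`
#'   (1 - P).
#' @export
speedup_table <- function(n_procs, time_min) {
  stopifnot(length(n_procs) == length(time_min), 1 %in% n_procs)
  t1 <- time_min[n_procs == 1][1]
  S <- t1 / time_min
  P <- rep(NA_real_, length(S))
  multi <- n_procs >= 2
  P[multi] <- mapply(parallel_fraction, S[multi], n_procs[multi])
  P[!multi & abs(S - 1) < 1e-12] <- 1
  data.frame(n_procs = n_procs, time_min = time_min,
             speedup = round(S, 4), P = P, serial = round(1 - P, 4))
}

#' Run seeding-point detection over row groups, optionally in parallel
#'
#' Row groups share no pixels, so detection per group is independent; the
#' merged output is set-equal to a serial run over all components. Timings
#' per group are returned for user-side scaling analysis.
#'
#' @param groups list of component groups from [partition_rows()] (`$groups`).
#' @param worker_count forked workers; 1 runs serially. (On platforms without
#'   fork the pool degrades to serial execution.)
#' @param d,max_iter,seed forwarded to [detect_seeding_points()].
#' @return list with `points` (merged data.frame, `row_id` filled from group
#'   names) and `timing` (data.frame: group, seconds).
#' @export
run_parallel <- function(groups, worker_count = 1L, d = 0.3, max_iter = 20L,
                         seed = 1L) {
  if (!length(groups))
    return(list(points = detect_seeding_points(list(), d, max_iter, seed),
                timing = data.frame(group = character(), seconds = numeric())))
  run_group <- function(gname) {
    t0 <- proc.time()[["elapsed"]]
    comps <- groups[[gname]]
    pts <- detect_seeding_points(comps, d, max_iter, seed,
                                 row_ids = rep(as.integer(gname), length(comps)))
    list(points = pts, seconds = proc.time()[["elapsed"]] - t0)
  }
  nm <- names(groups)
  res <- if (worker_count > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(nm, run_group, mc.cores = worker_count)
    fail <- vapply(out, inherits, TRUE, "try-error")
    if (any(fail)) stop("worker failure in group(s): ",
                        paste(nm[fail], collapse = ", "), call. = FALSE)
    out
  } else lapply(nm, run_group)
  pts <- do.call(rbind, lapply(res, `[[`, "points"))
  rownames(pts) <- NULL
  list(points = pts,
       timing = data.frame(group = nm,
                           seconds = vapply(res, `[[`, 0, "seconds")))
}
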