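#' Class vocabulary for crop-scene segments
#'
#' The default vocabulary: `Soil`, `Shadow` and five plant health levels
#' `HL1` (worst) to `HL5` (best). `health_value()` maps HL tokens to their
#' integer level 1-5 and returns `NA` for non-vegetation classes.
#'
#' @export
CLASS_TOKENS <- c("Soil", "Shadow", "HL1", "HL2", "HL3", "HL4", "HL5")

#' @rdname CLASS_TOKENS
#' @param label character vector of class tokens.
#' @return integer vector of health levels (NA for Soil/Shadow).
#' @export
health_value <- function(label) {
  v <- suppressWarnings(as.integer(sub("^HL", "", label)))
  v[!grepl("^HL[1-5]$", label)] <- NA_integer_
  v
}

#' @rdname CLASS_TOKENS
#' @export
is_vegetation_label <- function(label) grepl("^HL[1-5]$", label)

#' Fit a Gaussian maximum-likelihood classifier
#'
#' Per class, the model stores the sample mean vector, the
#' maximum-likelihood (1/n) covariance matrix, and a prior. Near-singular
#' covariances (smallest eigenvalue below `1e-10 * trace`) receive a ridge of
#' `1e-6 * trace / d` on the diagonal so the model stays positive definite.
#'
#' @param features numeric matrix, one row per training segment (the segment
#'   spectral modes), d columns (the bands).
#' @param labels character vector of class tokens, one per row.
#' @param priors `"uniform"` (default) or `"empirical"` (class frequencies).
#' @param classes class order; defaults to the order of first appearance.
#'   Every declared class needs at least one training sample.
#' @return an `mlc_model`: list of `classes`, `mu` (list of d-vectors),
#'   `sigma` (list of d x d matrices), `prior` (numeric, sums to 1).
#' @export
fit_mlc <- function(features, labels, priors = c("uniform", "empirical"),
                    classes = NULL) {
  priors <- match.arg(priors)
  features <- as.matrix(features)
  if (is.null(classes)) classes <- unique(labels)
  missing <- setdiff(classes, labels)
  if (length(missing))
    stop("training error: no samples for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- ncol(features)
  mu <- sigma <- stats::setNames(vector("list", length(classes)), classes)
  n_by <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    xi <- features[labels == cl, , drop = FALSE]
    n <- nrow(xi)
    n_by[cl] <- n
    m <- colMeans(xi)
    xc <- sweep(xi, 2, m)
    S <- crossprod(xc) / n                       # ML (1/n) covariance
    tr <- sum(diag(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (tr <= 0 || min(ev) < 1e-10 * tr) {
      eps <- if (tr > 0) 1e-6 * tr / d else 1e-6
      S <- S + diag(eps, d)
    }
    mu[[cl]] <- m
    sigma[[cl]] <- S
  }
  prior <- if (priors == "uniform") rep(1 / length(classes), length(classes))
  else as.numeric(n_by / sum(n_by))
  structure(list(classes = classes, mu = mu, sigma = sigma,
                 prior = stats::setNames(prior, classes), d = d),
            class = "mlc_model")
}

#' @export
print.mlc_model <- function(x, ...) {
  cat(sprintf("<mlc_model> %d class(es) in %d-band feature space: %s\n",
              length(x$classes), x$d, paste(x$classes, collapse = ", ")))
  invisible(x)
}

mlc_log_scores <- function(model, features) {
  features <- as.matrix(features)
  d <- ncol(features)
  scores <- matrix(NA_real_, nrow(features), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    S <- model$sigma[[cl]]
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    xc <- sweep(features, 2, model$mu[[cl]])
    z <- backsolve(ch, t(xc), transpose = TRUE)   # solves t(ch) %*% z = t(xc)
    maha <- colSums(z^2)
    scores[, cl] <- -0.5 * maha - 0.5 * logdet - d / 2 * log(2 * pi) +
      log(model$prior[cl])
  }
  scores
}

#' Classify segments by maximum likelihood
#'
#' Each segment's spectral mode is scored against every class's Gaussian
#' density; the segment is assigned the class maximizing prior times density
#' (log-domain), with ties broken by class order. Posteriors are the
#' Bayes-normalized class probabilities.
#'
#' @param model an `mlc_model` from [fit_mlc()].
#' @param segmap a `segment_map`, or a plain numeric feature matrix.
#' @return list with `label` (character, one per segment, named by segment
#'   label when a segment_map is given) and `posterior` (matrix, rows sum
#'   to 1).
#' @export
classify_segments <- function(model, segmap) {
  features <- segment_features(segmap)
  if (any(!is.finite(features)))
    stop("segment spectral modes must be finite", call. = FALSE)
  scores <- mlc_log_scores(model, features)
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  idx <- max.col(scores, ties.method = "first")
  lab <- model$classes[idx]
  if (inherits(segmap, "segment_map")) names(lab) <- segmap$segments$label
  list(label = lab, posterior = post)
}

segment_features <- function(segmap) {
  if (inherits(segmap, "segment_map")) {
    as.matrix(segmap$segments[paste0("mode_", segmap$band_names)])
  } else as.matrix(segmap)
}

#' Baseline classifiers: minimum distance to means and spectral angle
#'
#' `mdm` assigns the class whose mean vector is nearest in Euclidean
#' distance; `sam` the class minimizing the spectral angle
#' `acos(<w, mu> / (|w| |mu|))` (scale-invariant). Ties break by class order.
#'
#' @param method `"mdm"` or `"sam"`.
#' @param model an `mlc_model` (only the means are used) or a named list of
#'   per-class mean vectors.
#' @param segmap a `segment_map` or feature matrix.
#' @return character vector of class labels.
#' @export
classify_baseline <- function(method = c("mdm", "sam"), model, segmap) {
  method <- match.arg(method)
  mu <- if (inherits(model, "mlc_model")) model$mu else model
  classes <- names(mu)
  features <- segment_features(segmap)
  M <- do.call(rbind, mu)
  if (method == "mdm") {
    d2 <- outer(rowSums(features^2), rep(1, length(classes))) -
      2 * features %*% t(M) + outer(rep(1, nrow(features)), rowSums(M^2))
    lab <- classes[max.col(-d2, ties.method = "first")]
  } else {
    nf <- sqrt(rowSums(features^2))
    nm <- sqrt(rowSums(M^2))
    if (any(nf == 0) || any(nm == 0))
      stop("undefined-angle error: zero-norm vector in spectral angle mapping",
           call. = FALSE)
    cosang <- (features %*% t(M)) / outer(nf, nm)
    cosang <- pmin(pmax(cosang, -1), 1)
    lab <- classes[max.col(cosang, ties.method = "first")]
  }
  if (inherits(segmap, "segment_map")) names(lab) <- segmap$segments$label
  lab
}

#' Confusion matrix and per-class precision
#'
#' Builds the truth-by-predicted count matrix and a per-class precision
#' vector. The default `"row"` mode reports the diagonal count divided by its
#' row total (the share of each truth class predicted correctly); mode
#' `"tp_tn"` reports TP / (TP + TN). Values are reported to 4 decimals.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class order for rows/columns.
#' @param mode `"row"` (default) or `"tp_tn"`.
#' @return list with `matrix` (integer, truth rows x predicted columns) and
#'   `precision` (named numeric, 4 dp).
#' @export
confusion_and_precision <- function(truth, predicted, classes = NULL,
                                    mode = c("row", "tp_tn")) {
  mode <- match.arg(mode)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- unique(c(truth, predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("validation error: label(s) outside class list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  m <- table(truth = tf, predicted = pf)
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  prec <- precision_from_matrix(m, mode)
  list(matrix = m, precision = prec)
}

#' @rdname confusion_and_precision
#' @param counts a square confusion-count matrix (truth rows x predicted
#'   columns).
#' @export
precision_from_matrix <- function(counts, mode = c("row", "tp_tn")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  diagc <- diag(counts)
  total <- sum(counts)
  prec <- if (mode == "row") {
    diagc / rowSums(counts)
  } else {
    tn <- vapply(seq_len(nrow(counts)), function(i)
      total - sum(counts[i, ]) - sum(counts[, i]) + counts[i, i], 0)
    diagc / (diagc + tn)
  }
  round(stats::setNames(as.numeric(prec), rownames(counts)), 4)
}

#' Serialize / restore a fitted MLC model as JSON
#'
#' @param model an `mlc_model`.
#' @param path JSON file path.
#' @return `write_mlc_model`: `path` invisibly; `read_mlc_model`: the model.
#' @export
write_mlc_model <- function(model, path) {
  doc <- list(classes = model$classes,
              mu = lapply(model$mu, as.numeric),
              sigma = lapply(model$sigma, function(S) as.numeric(S)),
              d = model$d,
              prior = as.numeric(model$prior))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlc_model
#' @export
read_mlc_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  d <- doc$d
  structure(list(classes = doc$classes,
                 mu = stats::setNames(lapply(doc$mu, as.numeric), doc$classes),
                 sigma = stats::setNames(lapply(doc$sigma, function(v)
                   matrix(as.numeric(v), d, d)), doc$classes),
                 prior = stats::setNames(as.numeric(doc$prior), doc$classes),
                 d = d),
            class = "mlc_model")
}

#' Write a confusion matrix as CSV (truth rows, predicted columns)
#'
#' @param cm result of [confusion_and_precision()] (or a bare count matrix).
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- if (is.list(cm)) cm$matrix else cm
  tab <- as.data.frame(m)
  tab <- cbind(truth = rownames(m), tab)
  if (is.list(cm)) tab$precision <- sprintf("%.4f", cm$precision)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
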