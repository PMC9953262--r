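#' Z-score standardize a feature matrix
#'
#' Centers every feature column to mean 0 and scales to unit standard
#' deviation (n-1 denominator). The transform parameters are returned so
#' new data can be projected with the same scaling. A zero-variance column
#' is an error naming the column -- it is never silently dropped, because a
#' constant feature standardized to 0/0 would corrupt downstream PCA.
#'
#' @param x A `feature_matrix` or a plain numeric matrix.
#' @param params Optional list with `means` and `sds` from a previous call,
#'   to reuse a stored transform.
#' @return List with `values` (standardized matrix), `means`, `sds`.
#' @export
standardize <- function(x, params = NULL) {
  m <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (is.null(params)) {
    means <- colMeans(m)
    sds <- apply(m, 2L, stats::sd)
    zero <- sds < .Machine$double.eps * 1e3 * pmax(1, abs(means))
    if (any(zero)) {
      nm <- colnames(m)[zero]
      if (is.null(nm)) nm <- which(zero)
      stop("zero-variance feature column(s): ", paste(nm, collapse = ", "))
    }
  } else {
    means <- params$means; sds <- params$sds
  }
  list(values = sweep(sweep(m, 2L, means, "-"), 2L, sds, "/"),
       means = means, sds = sds)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Eigendecomposition of the sample covariance of an (already
#' standardized) matrix. Components are ordered by decreasing eigenvalue;
#' each loading column is flipped so its largest-magnitude entry is
#' positive, making results bit-stable across platforms. Scores are the
#' data projected onto the loadings.
#'
#' @param x Standardized numeric matrix (rows = measurements) or the list
#'   returned by [standardize()].
#' @param n_components Number of components to keep; defaults to the full
#'   rank bound `min(nrow - 1, ncol)`. Requests beyond the rank bound are
#'   truncated with a warning recorded in the result.
#' @return An object of class `pca_result`: `scores`, `loadings`
#'   (orthonormal columns), `explained_variance`,
#'   `explained_variance_ratio` (sums to 1 over all possible components),
#'   `feature_means`, `feature_sds`, `warnings`.
#' @export
pca <- function(x, n_components = NULL) {
  means <- NULL; sds <- NULL
  if (is.list(x) && !is.null(x$values)) {
    means <- x$means; sds <- x$sds; x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows")
  warn <- character()
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    warn <- c(warn, sprintf(
      "n_components=%d exceeds rank bound %d; truncated", n_components, max_comp))
    n_components <- max_comp
  }
  xc <- sweep(x, 2L, colMeans(x), "-")
  # SVD route: numerically safer than forming the covariance explicitly
  sv <- svd(xc, nu = 0, nv = max_comp)
  ev <- sv$d[seq_len(max_comp)]^2 / (nrow(x) - 1L)
  total_var <- sum(apply(x, 2L, stats::var))
  loadings <- sv$v
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  keep <- seq_len(n_components)
  scores <- xc %*% loadings[, keep, drop = FALSE]
  colnames(scores) <- paste0("PC", keep)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  if (!is.null(colnames(x))) rownames(loadings) <- colnames(x)
  structure(list(scores = scores,
                 loadings = loadings[, keep, drop = FALSE],
                 explained_variance = ev[keep],
                 explained_variance_ratio = ev[keep] / total_var,
                 all_explained_variance_ratio = ev / total_var,
                 feature_means = means, feature_sds = sds,
                 warnings = warn),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d scores x %d components; var ratio: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " ")))
  invisible(x)
}

#' Scree: ordered explained-variance proportions
#'
#' @param result A [pca()] result.
#' @return Nonincreasing numeric vector of explained-variance ratios over
#'   all computable components (sums to 1).
#' @export
scree <- function(result) {
  stopifnot(inherits(result, "pca_result"))
  result$all_explained_variance_ratio
}

#' Silhouette-based cluster separation on selected components
#'
#' Mean silhouette width over measurements, computed with Euclidean
#' distance on the selected score components. A label with a single member
#' contributes silhouette 0 for that point and is flagged. The paper-style
#' default looks at components 1 and 3: with drift-dominated PC2 excluded,
#' this is the plane in which the sample groups separate.
#'
#' @param scores Score matrix from [pca()] (or any numeric matrix).
#' @param labels Group label per row.
#' @param components Columns of `scores` to use (default `c(1, 3)`).
#' @return List with `mean_silhouette`, `silhouettes` (per point),
#'   `flagged_singletons` (labels with one member).
#' @export
cluster_separation <- function(scores, labels, components = c(1, 3)) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 distinct labels")
  scores <- as.matrix(scores)
  if (max(components) > ncol(scores))
    stop("components exceed the available score columns")
  s <- scores[, components, drop = FALSE]
  n <- nrow(s)
  d <- as.matrix(stats::dist(s))
  tab <- table(labels)
  singletons <- names(tab)[tab == 1L]
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { sil[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  list(mean_silhouette = mean(sil), silhouettes = sil,
       flagged_singletons = singletons)
}
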