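#' Silhouette average width
#'
#' Mean over points of s(i) = (b(i) - a(i)) / max(a(i), b(i)), where a(i) is
#' the mean Euclidean distance from point i to the other members of its own
#' cluster and b(i) the smallest mean distance to any other cluster.
#' Singleton clusters contribute s(i) = 0 (the usual convention).
#'
#' @param x numeric matrix (observations x variables); ignored when `dmat`
#'   is supplied.
#' @param labels cluster labels, one per observation (>= 2 distinct values).
#' @param dmat optional precomputed distance matrix (full square form), which
#'   makes repeated evaluation over candidate partitions cheap.
#' @return The average silhouette width, in \[-1, 1\].
#' @export
silhouette_avg_width <- function(x = NULL, labels, dmat = NULL) {
  if (is.null(dmat)) {
    stopifnot(!is.null(x))
    dmat <- as.matrix(stats::dist(x))
  } else {
    dmat <- as.matrix(dmat)
  }
  labels <- as.integer(factor(labels))
  n <- length(labels)
  stopifnot(nrow(dmat) == n)
  k <- max(labels)
  if (k < 2L) stop("silhouette is undefined for a single cluster")

  z <- matrix(0, n, k)
  z[cbind(seq_len(n), labels)] <- 1
  sums <- dmat %*% z                      # n x k: summed distance to each cluster
  sizes <- colSums(z)

  own <- sums[cbind(seq_len(n), labels)]
  a <- own / pmax(sizes[labels] - 1, 1)
  other <- sweep(sums, 2, sizes, "/")
  other[cbind(seq_len(n), labels)] <- Inf
  b <- apply(other, 1, min)

  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1L] <- 0             # singleton convention
  s[a == 0 & b == 0] <- 0
  mean(s)
}

#' Normalized Hubert Gamma coefficient of a partition
#'
#' Pearson correlation, over all unordered pairs of observations, between the
#' pairwise distance and the 0/1 indicator "pair belongs to different
#' clusters". Large positive values mean within-cluster pairs are close and
#' between-cluster pairs far: a good partition.
#'
#' @param dmat distance matrix (`dist` object or square matrix).
#' @param labels cluster labels with >= 2 distinct values.
#' @return Gamma, in \[-1, 1\].
#' @export
hubert_gamma <- function(dmat, labels) {
  d <- as.vector(stats::as.dist(dmat))
  labels <- as.integer(factor(labels))
  if (max(labels) < 2L) stop("Hubert Gamma is undefined for a single cluster")
  sep <- as.vector(stats::as.dist(outer(labels, labels, `!=`))) * 1
  if (stats::sd(d) == 0) stop("Hubert Gamma undefined: all pairwise distances equal")
  if (stats::sd(sep) == 0) stop("Hubert Gamma undefined: indicator has zero variance")
  stats::cor(d, sep)
}

#' L-method knee of an evaluation curve
#'
#' Fits two straight lines to the left and right parts of the curve
#' (y against x) at every admissible breakpoint and returns the breakpoint
#' minimizing the length-weighted total root-mean-square error. Each segment
#' must contain at least two points; the left segment is `x <= c`. Ties are
#' broken towards the smallest breakpoint, so a perfectly straight curve
#' yields the smallest admissible c.
#'
#' @param x strictly increasing numeric vector (candidate cluster counts).
#' @param y criterion values, same length as `x` (>= 4 points).
#' @return The x value at the knee.
#' @export
l_method_knee <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) stop("L-method needs at least 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")

  seg_rmse <- function(xx, yy) {
    fit <- stats::lm.fit(cbind(1, xx), yy)
    sqrt(mean(fit$residuals^2))
  }
  cut_idx <- 2:(n - 2)                    # left gets >= 2 points, right too
  total <- vapply(cut_idx, function(ci) {
    nl <- ci
    nr <- n - ci
    (nl * seg_rmse(x[1:ci], y[1:ci]) +
       nr * seg_rmse(x[(ci + 1):n], y[(ci + 1):n])) / n
  }, numeric(1))
  ## numeric ties (e.g. an exactly straight curve) go to the smallest c
  best <- min(total)
  x[cut_idx[which(total <= best + 1e-10 * (1 + abs(best)))[1]]]
}
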