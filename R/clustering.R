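# K-means++ seeding (roulette-wheel D^2 sampling), Lloyd iterations with
# restarts, elbow-based choice of k, and the 2-D principal-axis embedding
# applied to the unit covariates before clustering.

#' Two-dimensional embedding of unit covariates
#'
#' Standardizes the selected feature columns (zero mean, unit variance) and
#' projects the units onto the two leading principal axes. The sign of each
#' axis is fixed so its largest-magnitude loading is positive, making the
#' embedding deterministic.
#'
#' @param table Data frame of units (e.g. from [aggregate_truth()]).
#' @param features Character vector (>= 2) of feature columns to embed.
#' @return An n x 2 matrix of coordinates with attributes `rotation`
#'   (loadings), `sdev` (all singular-value sdevs) and
#'   `reconstruction_error` (sum of trailing eigenvalues).
#' @export
embed_2d <- function(table, features) {
  if (length(features) < 2L) stop("need at least 2 features to embed")
  X <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(X)) stop("features contain missing values")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 1L) stop("no non-constant features left")
  }
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k_avail <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (k_avail < 2L) {
    warning("fewer than 2 informative axes; padding second axis with zeros")
    co <- cbind(pc$x[, 1], 0)
    rot <- cbind(pc$rotation[, 1], 0)
  } else {
    co <- pc$x[, 1:2]
    rot <- pc$rotation[, 1:2]
  }
  for (j in 1:2) {
    lead <- which.max(abs(rot[, j]))
    if (length(lead) && rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      co[, j] <- -co[, j]
    }
  }
  colnames(co) <- c("axis1", "axis2")
  attr(co, "rotation") <- rot
  attr(co, "sdev") <- pc$sdev
  attr(co, "reconstruction_error") <- sum(ev[-(1:2)][ev[-(1:2)] > 0]) *
    (nrow(Z) - 1)
  co
}

#' K-means++ seeding by squared-distance roulette
#'
#' The first center is uniform over the points; each subsequent center is a
#' data point drawn with probability proportional to its squared distance to
#' the nearest center already chosen (roulette-wheel over D^2). With
#' `deterministic_max = TRUE` the literal argmax of D^2 is taken instead of
#' sampling.
#'
#' @param points Numeric matrix of coordinates (rows = points).
#' @param k Number of centers, at most the number of distinct points.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @param deterministic_max Take the farthest point instead of sampling.
#' @return A k x ncol(points) matrix of centers (rows of `points`), with
#'   attribute `index` giving the chosen row indices.
#' @export
kmeanspp_seed <- function(points, k, seed = NULL, deterministic_max = FALSE) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (k > n_distinct) stop("k exceeds the number of distinct points")
  with_seed_or_current(seed, {
    n <- nrow(points)
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    if (k > 1) {
      d2 <- rowSums((points - matrix(points[idx[1], ], n, ncol(points),
                                     byrow = TRUE))^2)
      for (j in 2:k) {
        idx[j] <- if (deterministic_max) {
          which.max(d2)
        } else {
          sample.int(n, 1L, prob = d2 / sum(d2))
        }
        d2 <- pmin(d2, rowSums((points - matrix(points[idx[j], ], n,
                                                ncol(points), byrow = TRUE))^2))
      }
    }
    centers <- points[idx, , drop = FALSE]
    attr(centers, "index") <- idx
    centers
  })
}

# squared distances from every point to every center: n x k
dist2_to_centers <- function(points, centers) {
  cross <- points %*% t(centers)
  pn <- rowSums(points^2); cn <- rowSums(centers^2)
  d2 <- outer(pn, cn, "+") - 2 * cross
  pmax(d2, 0)
}

#' K-means clustering with K-means++ initialization
#'
#' Lloyd iterations from [kmeanspp_seed()]; the best of `n_init` seeded
#' restarts by within-cluster sum of squares (SSE) is returned. Iterations
#' stop when the largest center shift is below `tol` or after `max_iter`
#' rounds. A cluster that empties is re-seeded at the point farthest from
#' its nearest center. At convergence every point is assigned to its nearest
#' center and the SSE trace is non-increasing.
#'
#' @param points Numeric matrix (rows = points).
#' @param k Number of clusters.
#' @param seed Optional integer seed.
#' @param max_iter,tol,n_init Lloyd controls.
#' @param deterministic_max Passed to [kmeanspp_seed()].
#' @return An object of class `cluster_model`: `k`, `centers`, `assignment`,
#'   `sse`, `sse_trace`, `seed`.
#' @export
kmeans_fit <- function(points, k, seed = NULL, max_iter = 300, tol = 1e-6,
                       n_init = 10, deterministic_max = FALSE) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite coordinates")
  best <- NULL
  with_seed_or_current(seed, {
    for (init in seq_len(n_init)) {
      centers <- kmeanspp_seed(points, k, seed = NULL,
                               deterministic_max = deterministic_max)
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        d2 <- dist2_to_centers(points, centers)
        assign_ <- max.col(-d2, ties.method = "first")
        # re-seed empty clusters at the farthest point
        for (j in which(tabulate(assign_, nbins = k) == 0L)) {
          far <- which.max(d2[cbind(seq_len(nrow(points)), assign_)])
          centers[j, ] <- points[far, ]
          d2 <- dist2_to_centers(points, centers)
          assign_ <- max.col(-d2, ties.method = "first")
        }
        trace <- c(trace, sum(d2[cbind(seq_len(nrow(points)), assign_)]))
        new_centers <- centers
        for (j in seq_len(k))
          new_centers[j, ] <- colMeans(points[assign_ == j, , drop = FALSE])
        shift <- max(sqrt(rowSums((new_centers - centers)^2)))
        centers <- new_centers
        if (shift < tol) break
      }
      d2 <- dist2_to_centers(points, centers)
      assign_ <- max.col(-d2, ties.method = "first")
      sse <- sum(d2[cbind(seq_len(nrow(points)), assign_)])
      if (is.null(best) || sse < best$sse) {
        best <- list(k = k, centers = centers, assignment = assign_,
                     sse = sse, sse_trace = trace, seed = seed)
      }
    }
  })
  structure(best, class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, SSE = %.4g, sizes: %s\n", x$k, x$sse,
              paste(tabulate(x$assignment, nbins = x$k), collapse = " ")))
  invisible(x)
}

#' Elbow-based choice of the number of clusters
#'
#' Fits [kmeans_fit()] for every k in the range, then picks the k with the
#' largest discrete second difference (curvature) of the SSE-vs-k curve.
#' A non-monotone curve (restart noise) is smoothed by cumulative minimum
#' first, with a warning. The full curve is returned so the choice can be
#' overridden.
#'
#' @param points Numeric matrix (rows = points).
#' @param k_min,k_max Range of k (defaults 2..13).
#' @param seed Optional integer seed.
#' @param ... Passed to [kmeans_fit()].
#' @return List with `k` (chosen), `sse` (named curve), `models` (one
#'   `cluster_model` per k).
#' @export
choose_k_elbow <- function(points, k_min = 2, k_max = 13, seed = NULL, ...) {
  points <- as.matrix(points)
  if (k_max > nrow(unique(points)))
    stop("k_max exceeds the number of distinct points")
  ks <- k_min:k_max
  models <- with_seed_or_current(seed, {
    lapply(ks, function(k) kmeans_fit(points, k, seed = NULL, ...))
  })
  sse <- vapply(models, `[[`, numeric(1), "sse")
  names(sse) <- ks
  if (is.unsorted(rev(sse))) {
    warning("SSE curve not monotone (restart noise); smoothing by cummin")
    sse_s <- cummin(sse)
  } else sse_s <- sse
  if (length(ks) >= 3) {
    d2 <- sse_s[1:(length(ks) - 2)] - 2 * sse_s[2:(length(ks) - 1)] +
      sse_s[3:length(ks)]
    k_star <- ks[which.max(d2) + 1L]
  } else k_star <- ks[which.min(sse_s)]
  list(k = k_star, sse = sse, models = stats::setNames(models, ks))
}
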