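# Maximal information coefficient (MIC): normalized maximum grid-partition
# mutual information between two variables. The search follows the standard
# MINE strategy: for each admissible grid shape, one axis is partitioned into
# equal-frequency bins and the other axis is optimized exactly by dynamic
# programming over clump boundaries; both orientations are scored and the
# maximum taken. For tiny samples the equal-frequency step is replaced by
# exhaustive enumeration of that axis's partitions, making the search exact.
# A separate brute-force mode (exact_mode) enumerates cut placements on both
# axes directly and scores each grid with grid_mutual_information().

#' MIC search configuration
#'
#' @param alpha Exponent of the grid-size budget: only grid shapes with
#'   `a * b <= max(n^alpha, 4)` are scored (the floor keeps the smallest
#'   informative 2x2 grid admissible at small n).
#' @param c Clump multiplier: the dynamic programme searches over at most
#'   `c * a` candidate cut positions (superclumps) for an `a`-bin axis.
#' @param exact_mode Brute-force enumeration of both axes' cut placements
#'   (feasible only for n <= 16 and grids up to 3x3); used as an in-package
#'   oracle for the heuristic search.
#' @param exhaustive_budget When the number of admissible partitions of the
#'   equal-frequency axis is at most this, all of them are enumerated instead
#'   (the search is then exact for that shape).
#' @return A list of class `mic_config`.
#' @export
mic_config <- function(alpha = 0.6, c = 15, exact_mode = FALSE,
                       exhaustive_budget = 60) {
  stopifnot(alpha > 0, c > 0, exhaustive_budget >= 0)
  structure(list(alpha = alpha, c = c, exact_mode = exact_mode,
                 exhaustive_budget = exhaustive_budget),
            class = "mic_config")
}

#' Grid-partition mutual information
#'
#' Empirical mutual information (in bits) of two variables over a fixed
#' rectangular grid: cells are defined by interior cut points on each axis,
#' cell probabilities are empirical frequencies, and empty cells contribute
#' zero (the limit p log p -> 0).
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param row_edges Sorted interior cut points partitioning `y` (grid rows).
#' @param col_edges Sorted interior cut points partitioning `x` (grid cols).
#' @return Mutual information in bits, >= 0.
#' @export
#' @examples
#' grid_mutual_information(1:4, 1:4, row_edges = 2.5, col_edges = 2.5)  # 1 bit
grid_mutual_information <- function(x, y, row_edges, col_edges) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (is.unsorted(row_edges, strictly = TRUE) ||
      is.unsorted(col_edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  ri <- findInterval(y, row_edges) + 1L
  ci <- findInterval(x, col_edges) + 1L
  counts <- table(factor(ri, levels = seq_len(length(row_edges) + 1L)),
                  factor(ci, levels = seq_len(length(col_edges) + 1L)))
  mi_from_counts(unclass(counts))
}

# Mutual information in bits from a joint count table; empty cells skipped.
mi_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  pr <- rowSums(p); pc <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  i_val <- sum(p[nz] * log2(p[nz] / (pr[nz[, 1]] * pc[nz[, 2]])))
  max(i_val, 0)
}

# Equal-frequency bin assignment of `v` into (at most) `b` bins; cuts are
# placed at value boundaries nearest the target cumulative counts, so ties
# never straddle a cut. Returns integer bin indices.
equal_freq_bins <- function(v, b) {
  n <- length(v)
  sv <- sort(v)
  bnd <- which(diff(sv) != 0)           # cut after position bnd[k]
  if (length(bnd) == 0L) return(rep(1L, n))
  targets <- (1:(b - 1)) * n / b
  picks <- unique(vapply(targets, function(t) bnd[which.min(abs(bnd - t))],
                         numeric(1)))
  cuts <- (sv[picks] + sv[picks + 1]) / 2
  findInterval(v, sort(cuts)) + 1L
}

# All partitions of `v` into exactly `b` nonempty contiguous bins (by value),
# as a list of bin-index vectors. Count = choose(D-1, b-1), D distinct values.
enumerate_bins <- function(v, b) {
  sv <- sort(unique(v))
  gaps <- length(sv) - 1L
  if (b - 1L > gaps) return(list())
  if (b == 1L) return(list(rep(1L, length(v))))
  combs <- utils::combn(gaps, b - 1L)
  lapply(seq_len(ncol(combs)), function(k) {
    cuts <- (sv[combs[, k]] + sv[combs[, k] + 1]) / 2
    findInterval(v, cuts) + 1L
  })
}

# Dynamic programme: given fixed bins `yb` (1..b) on one axis and values `xo`
# on the other, returns I_l (bits) of the best partition of the x axis into
# exactly l contiguous nonempty bins, for l = 1..l_max. Candidate cuts are
# clump boundaries (runs of equal x are never split), thinned to ~c*l_max
# superclumps when numerous.
optimize_axis <- function(xo, yb, b, l_max, clump_mult) {
  n <- length(xo)
  ord <- order(xo)
  xs <- xo[ord]; ys <- yb[ord]
  clump <- cumsum(c(1L, as.integer(diff(xs) != 0)))
  K <- clump[n]
  # counts per clump x ybin
  cnt <- matrix(0, K, b)
  for (q in seq_len(b)) cnt[, q] <- tabulate(clump[ys == q], nbins = K)
  # superclump thinning
  cap <- max(2L, ceiling(clump_mult * l_max))
  if (K > cap) {
    ce <- cumsum(rowSums(cnt))                   # cumulative points at clump ends
    targets <- (1:(cap - 1)) * n / cap
    picks <- sort(unique(vapply(targets, function(t) which.min(abs(ce - t)),
                                numeric(1))))
    picks <- picks[picks < K]
    grp <- findInterval(seq_len(K), picks + 0.5) + 1L
    cnt <- rowsum(cnt, grp)
    K <- nrow(cnt)
  }
  cum <- rbind(0, apply(cnt, 2, cumsum))         # (K+1) x b
  mq <- cum[K + 1, ]
  lgmq <- ifelse(mq > 0, log2(mq), 0)
  lgn <- log2(n)
  # contrib[s+1, t]: bin covering superclumps (s+1)..t
  contrib <- matrix(-Inf, K, K)
  for (s in 0:(K - 1)) {
    V <- cum[(s + 2):(K + 1), , drop = FALSE] -
      matrix(cum[s + 1, ], K - s, b, byrow = TRUE)
    lt <- V / n * (ifelse(V > 0, log2(V), 0) + lgn -
                     ifelse(rowSums(V) > 0, log2(rowSums(V)), 0) -
                     matrix(lgmq, K - s, b, byrow = TRUE))
    lt[V == 0] <- 0
    contrib[s + 1, (s + 1):K] <- rowSums(lt)
  }
  l_max <- min(l_max, K)
  dp <- matrix(-Inf, l_max, K)
  dp[1, ] <- contrib[1, ]
  if (l_max >= 2) for (l in 2:l_max) {
    for (t in l:K) {
      s_range <- (l - 1):(t - 1)
      dp[l, t] <- max(dp[l - 1, s_range] + contrib[s_range + 1, t])
    }
  }
  pmax(dp[, K], 0)
}

#' Maximal information coefficient of two variables
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param config A [mic_config()].
#' @return MIC in \[0, 1\].
#' @export
#' @examples
#' mic_score(1:20, (1:20)^2)  # noiseless functional relation -> 1
mic_score <- function(x, y, config = mic_config()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("mic_score needs n >= 4 (no admissible grid)")
  B <- max(n^config$alpha, 4)
  if (isTRUE(config$exact_mode)) return(mic_exact(x, y, B, n))
  best <- 0
  for (orient in 1:2) {
    u <- if (orient == 1) x else y   # axis optimized by DP
    v <- if (orient == 1) y else x   # axis partitioned by equal frequency
    if (length(unique(v)) < 2L || length(unique(u)) < 2L) next
    for (b in 2:max(2, floor(B / 2))) {
      l_max <- floor(B / b)
      if (l_max < 2) break
      d <- length(unique(v))
      n_part <- if (d - 1 >= b - 1) choose(d - 1, b - 1) else 0
      parts <- if (n_part >= 1 && n_part <= config$exhaustive_budget) {
        enumerate_bins(v, b)
      } else {
        list(equal_freq_bins(v, b))
      }
      for (yb in parts) {
        bb <- max(yb)
        ivals <- optimize_axis(u, yb, bb, l_max, config$c)
        if (length(ivals) >= 2) for (l in 2:length(ivals)) {
          cand <- ivals[l] / log2(min(l, bb))
          if (cand > best) best <- cand
        }
      }
    }
  }
  min(max(best, 0), 1)
}

# Brute-force MIC: enumerate all interior-cut placements on both axes for
# every admissible shape (a, b <= 3), score via grid_mutual_information.
mic_exact <- function(x, y, B, n) {
  if (n > 16L) stop("exact_mode is feasible only for small n (<= 16)")
  cut_cands <- function(v) {
    sv <- sort(unique(v))
    if (length(sv) < 2) return(numeric(0))
    (sv[-length(sv)] + sv[-1]) / 2
  }
  cx <- cut_cands(x); cy <- cut_cands(y)
  best <- 0
  for (a in 2:3) for (b in 2:3) {
    if (a * b > B) next
    if (length(cx) < a - 1 || length(cy) < b - 1) next
    xcuts <- utils::combn(length(cx), a - 1)
    ycuts <- utils::combn(length(cy), b - 1)
    for (ix in seq_len(ncol(xcuts))) for (iy in seq_len(ncol(ycuts))) {
      i_val <- grid_mutual_information(x, y, row_edges = cy[ycuts[, iy]],
                                       col_edges = cx[xcuts[, ix]])
      cand <- i_val / log2(min(a, b))
      if (cand > best) best <- cand
    }
  }
  min(max(best, 0), 1)
}
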