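#' ReliefF feature ranking
#'
#' Weights features by how well they separate closely neighbored instances
#' of different classes: for every (sampled) instance the k nearest hits
#' (same class) and k nearest misses (other class) under a
#' range-normalized Manhattan distance are found, and each feature's
#' weight accumulates the mean normalized value difference to the misses
#' minus that to the hits, averaged over instances.
#'
#' @param x numeric matrix or data frame of features (instances in rows).
#' @param y binary labels (0/1, logical, or a two-level factor).
#' @param k_neighbors number of hits/misses per instance (default 10).
#' @param n_sample number of instances to sample, `NULL` for all (the
#'   default; the computation is then fully deterministic).
#' @param seed RNG seed used only when `n_sample` is smaller than the
#'   table.
#' @return data frame with columns `feature` and `score`, sorted by
#'   decreasing score (ties broken lexicographically by feature name).
#' @export
relieff_rank <- function(x, y, k_neighbors = 10L, n_sample = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1  # constant feature: all diffs are 0
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  d <- as.matrix(dist(xs, method = "manhattan")) / p
  idx <- seq_len(n)
  if (!is.null(n_sample) && n_sample < n) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    idx <- sort(sample.int(n, n_sample))
  }
  w <- numeric(p)
  for (i in idx) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cls <- which(y != y[i])
    if (!length(same) || !length(diff_cls)) stop("a class has a single instance")
    hits <- same[order(d[i, same], same)][seq_len(min(k_neighbors, length(same)))]
    miss <- diff_cls[order(d[i, diff_cls], diff_cls)][seq_len(min(k_neighbors, length(diff_cls)))]
    dh <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))
    dm <- abs(sweep(xs[miss, , drop = FALSE], 2, xs[i, ]))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w <- w / length(idx)
  nm <- colnames(x); if (is.null(nm)) nm <- paste0("f", seq_len(p))
  out <- data.frame(feature = nm, score = w, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(y)
}

# equal-frequency discretization into min(10, floor(sqrt(n))) bins
discretize_ef <- function(v, n_bins) {
  br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1L), names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = br, include.lowest = TRUE))
}

entropy <- function(f) {
  p <- table(f); p <- p / sum(p)
  -sum(p * log2(p))
}

# symmetrical uncertainty between two discrete vectors
symmetrical_uncertainty <- function(a, b) {
  ha <- entropy(a); hb <- entropy(b)
  if (ha + hb == 0) return(0)
  hab <- entropy(paste(a, b))
  2 * (ha + hb - hab) / (ha + hb)
}

#' CFS merit of a feature subset
#'
#' `merit = k * mean(feature-class correlation) /
#' sqrt(k + k (k - 1) * mean(feature-feature correlation))`, with both
#' correlations measured as symmetrical uncertainty on equal-frequency
#' entropy-discretized features.
#'
#' @param x numeric feature matrix / data frame.
#' @param y binary labels.
#' @param features character vector (or indices) of the subset.
#' @return the merit (0 for an empty subset).
#' @export
cfs_merit <- function(x, y, features) {
  x <- as.matrix(x); y <- as_binary_labels(y)
  if (length(features) == 0L) return(0)
  n_bins <- max(2L, min(10L, floor(sqrt(nrow(x)))))
  xd <- apply(x[, features, drop = FALSE], 2, discretize_ef, n_bins = n_bins)
  k <- ncol(xd)
  rcf <- mean(apply(xd, 2, symmetrical_uncertainty, b = y))
  rff <- 0
  if (k > 1L) {
    pairs <- utils::combn(k, 2)
    rff <- mean(apply(pairs, 2, function(q) symmetrical_uncertainty(xd[, q[1]], xd[, q[2]])))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection with best-first search
#'
#' Searches feature subsets by best-first expansion (adding one feature at
#' a time from the empty set), scoring each subset by [cfs_merit()], and
#' stops after five consecutive expansions that fail to improve on the
#' best merit found so far.
#'
#' @param x numeric feature matrix / data frame.
#' @param y binary labels (both classes must be present).
#' @param max_stale consecutive non-improving expansions tolerated
#'   (default 5).
#' @return character vector: the selected feature subset, with the merit
#'   attached as attribute `"merit"`.
#' @export
cfs_select <- function(x, y, max_stale = 5L) {
  x <- as.matrix(x); y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("degenerate table: a single class")
  if (ncol(x) < 2L) stop("need at least 2 features")
  nm <- colnames(x); if (is.null(nm)) { nm <- paste0("f", seq_len(ncol(x))); colnames(x) <- nm }
  n_bins <- max(2L, min(10L, floor(sqrt(nrow(x)))))
  xd <- apply(x, 2, discretize_ef, n_bins = n_bins)
  su_cf <- apply(xd, 2, symmetrical_uncertainty, b = y)
  p <- ncol(x)
  su_ff <- matrix(0, p, p)
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
    su_ff[a, b] <- su_ff[b, a] <- symmetrical_uncertainty(xd[, a], xd[, b])
  }
  merit_of <- function(sel) {  # sel: integer indices
    k <- length(sel)
    if (k == 0L) return(0)
    rcf <- mean(su_cf[sel])
    rff <- if (k > 1L) mean(su_ff[sel, sel][upper.tri(diag(k))]) else 0
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }
  key <- function(sel) paste(sort(sel), collapse = ",")
  open <- list(list(sel = integer(0), merit = 0))
  visited <- new.env(parent = emptyenv())
  best_sel <- integer(0); best_merit <- 0; stale <- 0L
  while (length(open) > 0L && stale < max_stale) {
    ms <- vapply(open, `[[`, numeric(1), "merit")
    pick <- which.max(ms)
    node <- open[[pick]]; open[[pick]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$sel)) {
      child <- sort(c(node$sel, f))
      kk <- key(child)
      if (!is.null(visited[[kk]])) next
      assign(kk, TRUE, envir = visited)
      m <- merit_of(child)
      open[[length(open) + 1L]] <- list(sel = child, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_sel <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  out <- nm[best_sel]
  attr(out, "merit") <- best_merit
  out
}
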