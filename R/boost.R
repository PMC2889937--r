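get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
  invisible(NULL)
}

# best weighted-error decision stump over all features and midpoints.
# x: numeric matrix, y: labels in {-1, +1}, w: non-negative weights.
# Ties broken by (lower feature index, lower split value, left class 1).
fit_stump <- function(x, y, w, sort_idx = NULL) {
  n <- nrow(x); p <- ncol(x)
  W <- sum(w)
  best <- list(error = Inf)
  for (f in seq_len(p)) {
    ord <- if (is.null(sort_idx)) order(x[, f]) else sort_idx[[f]]
    sv <- x[ord, f]
    wp <- cumsum(w[ord] * (y[ord] == 1))
    wn <- cumsum(w[ord] * (y[ord] == -1))
    P <- wp[n]; N <- wn[n]
    valid <- which(sv[-n] < sv[-1])  # split between distinct values
    if (!length(valid)) next
    # left class +1: mistakes = negatives on the left + positives on the right
    e_pos <- wn[valid] + (P - wp[valid])
    e_neg <- wp[valid] + (N - wn[valid])
    for (side in 1:2) {
      e <- if (side == 1) e_pos else e_neg
      t <- which.min(e)
      if (e[t] < best$error - 1e-12) {
        best <- list(feature = f, split = (sv[valid[t]] + sv[valid[t] + 1L]) / 2,
                     left = if (side == 1) 1L else -1L, error = e[t])
      }
    }
  }
  if (!is.finite(best$error)) return(NULL)  # all features constant
  best$error <- best$error / W
  best
}

stump_predict <- function(stump, x) {
  ifelse(x[, stump$feature] <= stump$split, stump$left, -stump$left)
}

#' Train a MultiBoost committee of decision stumps
#'
#' MultiBoosting wraps AdaBoost subcommittees in a wagging-style outer
#' loop: within a subcommittee the usual AdaBoost.M1 weight updates apply;
#' at subcommittee boundaries (and when a base learner reaches error 0 or
#' at least 0.5) the instance weights are re-drawn from the continuous
#' Poisson approximation (standardized exponential deviates).  The base
#' learner is the best weighted-error decision stump over all features and
#' value midpoints.  With a single subcommittee the procedure is exactly
#' AdaBoost.
#'
#' @param x numeric feature matrix / data frame.
#' @param y binary labels (0/1, logical or two-level factor).
#' @param n_iterations total committee size (default 200).
#' @param n_subcommittees number of subcommittees; default
#'   `ceiling(sqrt(n_iterations))`.
#' @param seed RNG seed controlling the wagging draws; training is
#'   bit-reproducible given `(x, y, n_iterations, seed)`.
#' @param feature_set feature names recorded in the model (defaults to the
#'   columns of `x`).
#' @return object of class `boosted_model`: stumps with weights `alpha`,
#'   subcommittee bounds, feature set, unset thresholds, the seed, and the
#'   energy-table version.
#' @export
train_multiboost <- function(x, y, n_iterations = 200L,
                             n_subcommittees = ceiling(sqrt(n_iterations)),
                             seed = 1L, feature_set = colnames(x)) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  if (length(unique(yb)) < 2L) stop("both classes must be present for training")
  y2 <- ifelse(yb == 1L, 1L, -1L)
  n <- nrow(x)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  breakpoints <- if (n_subcommittees > 1L) {
    unique(ceiling(seq_len(n_subcommittees - 1L) * n_iterations / n_subcommittees))
  } else integer(0)
  sort_idx <- lapply(seq_len(ncol(x)), function(f) order(x[, f]))
  wagging <- function() { u <- runif(n); w <- -log(u); w * n / sum(w) }
  w <- rep(1, n)
  stumps <- list()
  for (t in seq_len(n_iterations)) {
    if ((t - 1L) %in% breakpoints) w <- wagging()
    st <- fit_stump(x, y2, w, sort_idx)
    if (is.null(st)) break
    if (st$error >= 0.5) { w <- wagging(); next }  # stump discarded
    if (st$error == 0) {
      st$alpha <- log(1e10)
      stumps[[length(stumps) + 1L]] <- st
      w <- wagging()
      next
    }
    st$alpha <- log((1 - st$error) / st$error)
    stumps[[length(stumps) + 1L]] <- st
    pred <- stump_predict(st, x)
    wrong <- pred != y2
    w[wrong] <- w[wrong] / (2 * st$error)
    w[!wrong] <- w[!wrong] / (2 * (1 - st$error))
    w <- pmax(w, 1e-8)
  }
  nm <- colnames(x); if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  stump_df <- if (length(stumps)) data.frame(
    feature = nm[vapply(stumps, `[[`, integer(1), "feature")],
    split = vapply(stumps, `[[`, numeric(1), "split"),
    left_class = ifelse(vapply(stumps, `[[`, integer(1), "left") == 1L, 1L, 0L),
    alpha = vapply(stumps, `[[`, numeric(1), "alpha"),
    stringsAsFactors = FALSE)
  else data.frame(feature = character(0), split = numeric(0),
                  left_class = integer(0), alpha = numeric(0))
  structure(list(stumps = stump_df, n_iterations = as.integer(n_iterations),
                 subcommittee_bounds = as.integer(breakpoints),
                 feature_set = if (is.null(feature_set)) nm else feature_set,
                 thresholds = NULL, seed = as.integer(seed),
                 params_version = tryCatch(energy_parameters()$version,
                                           error = function(e) NA_character_)),
            class = "boosted_model")
}

#' @export
print.boosted_model <- function(x, ...) {
  cat("boosted stump committee: ", nrow(x$stumps), " stumps (cap ",
      x$n_iterations, "), ", length(x$feature_set), " features\n", sep = "")
  if (!is.null(x$thresholds)) {
    cat("  thresholds: sens ", formatC(x$thresholds$sens, digits = 4, format = "f"),
        ", spec ", formatC(x$thresholds$spec, digits = 4, format = "f"), "\n", sep = "")
  }
  invisible(x)
}

#' Score instances with a boosted model
#'
#' The normalized committee vote for the positive class:
#' `(margin / sum(alpha) + 1) / 2` where `margin` is the alpha-weighted
#' sum of the stumps' signed predictions.  An empty committee scores 0.5
#' (no evidence).
#'
#' @param model a `boosted_model`.
#' @param x data frame / matrix containing the model's feature set, or a
#'   single named feature vector.
#' @return numeric scores in `[0, 1]`.
#' @export
score_features <- function(model, x) {
  if (is.null(dim(x))) x <- as.data.frame(as.list(x))
  x <- as.data.frame(x)
  missing_f <- setdiff(unique(model$stumps$feature), colnames(x))
  if (length(missing_f)) stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  n <- nrow(x)
  if (nrow(model$stumps) == 0L) return(rep(0.5, n))
  margin <- numeric(n)
  for (k in seq_len(nrow(model$stumps))) {
    s <- model$stumps[k, ]
    pred <- ifelse(x[[s$feature]] <= s$split,
                   if (s$left_class == 1L) 1 else -1,
                   if (s$left_class == 1L) -1 else 1)
    margin <- margin + s$alpha * pred
  }
  (margin / sum(model$stumps$alpha) + 1) / 2
}

#' @export
predict.boosted_model <- function(object, newdata, ...) score_features(object, newdata)

#' ROC curve and AUC
#'
#' Points are swept over all score thresholds; the AUC is the trapezoidal
#' integral, which for a step-wise ROC equals the rank (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels.
#' @return object of class `roc_curve`: data frame of `(fpr, tpr)` points
#'   plus an `auc` attribute (also returned by `auc()`).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes required for a ROC curve")
  ord <- order(-scores)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1L); fp <- cumsum(ys == 0L)
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)  # collapse tied thresholds
  tpr <- c(0, tp[keep] / sum(y == 1L))
  fpr <- c(0, fp[keep] / sum(y == 0L))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr), auc = auc, class = c("roc_curve", "data.frame"))
}

#' @rdname roc_curve
#' @param x a `roc_curve`.
#' @export
auc <- function(x) attr(x, "auc")

#' Rank-statistic AUC
#'
#' The probability that a random positive outscores a random negative,
#' ties counted one half (Mann-Whitney formulation).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  r <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation of the boosted classifier
#'
#' Instances are shuffled within each class (seeded) and dealt into folds
#' cyclically; each instance is scored by the committee trained on the
#' remaining folds, and the ROC/AUC is computed over the pooled
#' out-of-fold scores.
#'
#' @inheritParams train_multiboost
#' @param folds number of folds (default 10).
#' @return list with `scores` (out-of-fold, in input order), `labels`,
#'   `fold` assignments, `roc` and `auc`.
#' @export
cross_validate <- function(x, y, folds = 10L, seed = 1L, n_iterations = 200L,
                           n_subcommittees = ceiling(sqrt(n_iterations))) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  n <- nrow(x)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(yb)) {
    id <- which(yb == cls)
    fold[id[sample.int(length(id))]] <- rep_len(seq_len(folds), length(id))
  }
  scores <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(yb[tr])) < 2L) stop("fold ", k, " leaves a single-class training set")
    m <- train_multiboost(x[tr, , drop = FALSE], yb[tr], n_iterations = n_iterations,
                          n_subcommittees = n_subcommittees, seed = seed + k)
    scores[!tr] <- score_features(m, x[!tr, , drop = FALSE])
  }
  roc <- if (length(unique(yb)) == 2L) roc_curve(scores, yb) else NULL
  list(scores = scores, labels = yb, fold = fold, roc = roc,
       auc = if (!is.null(roc)) auc(roc) else NA_real_)
}

#' Calibrate sensitive/specific score thresholds from out-of-fold scores
#'
#' The sensitive threshold is the smallest score `s` with empirical
#' false-positive rate (fraction of negatives scoring at or above `s`)
#' strictly below `sens_fpr`; the specific threshold uses `<= spec_fpr`.
#' Candidate thresholds are the observed score values plus a value just
#' above the maximum.
#'
#' @param scores out-of-fold scores.
#' @param labels binary labels aligned with `scores`.
#' @param sens_fpr,spec_fpr target false-positive rates (defaults 0.05
#'   and 0.01).
#' @return list with elements `sens` and `spec` (`sens <= spec`).
#' @export
calibrate_thresholds <- function(scores, labels, sens_fpr = 0.05, spec_fpr = 0.01) {
  y <- as_binary_labels(labels)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes required")
  if (length(unique(scores)) == 1L) {
    stop("degenerate score distribution: all scores equal (", scores[1], ")")
  }
  neg <- scores[y == 0L]
  cand <- sort(unique(c(scores, max(scores) + 1e-9)))
  fpr <- vapply(cand, function(s) mean(neg >= s), numeric(1))
  sens <- cand[fpr < sens_fpr][1]
  spec <- cand[fpr <= spec_fpr][1]
  if (is.na(sens) || is.na(spec)) stop("could not calibrate thresholds")
  list(sens = sens, spec = max(spec, sens))
}
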