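#' Zone-calling thresholds
#'
#' The thresholds are dimensionless ratios relative to the perfect
#' reverse-complement energy of the microRNA: a smoothed profile value
#' passes the zone cut-off when it is at most `x_ratio` times that energy
#' (both negative), and a representative duplex must reach `y_ratio`.
#' Defaults are the deliberately permissive `x = 0.24`, `y = 0.25`.
#'
#' @param x_ratio,y_ratio ratios in (0, 1) with `x_ratio <= y_ratio`.
#' @return object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(x_ratio = 0.24, y_ratio = 0.25) {
  if (!(x_ratio > 0 && x_ratio <= y_ratio && y_ratio < 1)) {
    stop("need 0 < x_ratio <= y_ratio < 1")
  }
  structure(list(x_ratio = x_ratio, y_ratio = y_ratio), class = "zone_thresholds")
}

#' Per-position attraction profile of a UTR for one microRNA
#'
#' For every UTR position the minimum anchored duplex energy is computed
#' (after seed-preference pruning: anchors harboring a perfect 7-pair
#' 5'-end helix keep only seed structures), giving the raw attraction
#' profile; positions with no admissible anchored structure contribute
#' 0 kcal/mol.  The profile is then smoothed with a centered sliding
#' window of length three (truncated at the sequence ends).
#'
#' @param mirna,utr RNA sequences (characters or Biostrings objects).
#' @param params [energy_parameters()].
#' @param mirna_id,utr_id identifiers carried into downstream records.
#' @param prune apply the seed-preference pruning (default `TRUE`).
#' @return object of class `attraction_profile`: list with `raw_energy`,
#'   `smoothed_energy`, `has_structure`, `seed`, `first_mi`, `pairs`
#'   (per-anchor pair matrices in UTR coordinates), `mirna`, `utr` and ids.
#' @export
build_profile <- function(mirna, utr, params = energy_parameters(),
                          mirna_id = "mirna", utr_id = "utr", prune = TRUE) {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  mi <- rna_codes(mirna); u <- rna_codes(utr)
  res <- cpp_profile(mi, u, unclass(params), prune, span_3prime(length(mi), params))
  raw <- res$energy
  has <- !is.na(raw)
  raw[!has] <- 0.0
  structure(list(
    utr_id = utr_id, mirna_id = mirna_id,
    raw_energy = raw, smoothed_energy = smooth3(raw),
    has_structure = has, seed = res$seed, first_mi = res$first_mi,
    pairs = res$pairs, mirna = mirna, utr = utr),
    class = "attraction_profile")
}

# centered mean over {i-1, i, i+1} intersected with [1, n]
smooth3 <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  left <- c(NA, x[-n]); right <- c(x[-1], NA)
  num <- ifelse(is.na(left), 0, left) + x + ifelse(is.na(right), 0, right)
  den <- 1 + (!is.na(left)) + (!is.na(right))
  num / den
}

#' @export
print.attraction_profile <- function(x, ...) {
  cat("attraction profile ", x$mirna_id, " vs ", x$utr_id, ": ",
      length(x$raw_energy), " positions, ", sum(x$has_structure),
      " with an anchored duplex\n", sep = "")
  invisible(x)
}

#' Call candidate zones from an attraction profile
#'
#' Candidate zones are the maximal runs of consecutive UTR positions whose
#' smoothed energy is at most `x_ratio * e_perfect`.  Within a run, the
#' eligible representatives are anchored optima whose raw energy reaches
#' `y_ratio * e_perfect` and whose 5'-most pairing uses microRNA position
#' 1 or 2; the minimum-energy eligible structure becomes the zone's
#' representative (ties towards the smaller anchor), and runs without an
#' eligible representative are dropped.  The zone interval is the run
#' extended to cover the representative's target footprint.
#'
#' @param profile an [build_profile()] result.
#' @param e_perfect perfect reverse-complement energy of the microRNA
#'   (must be negative); defaults to computing it from the profile.
#' @param th [zone_thresholds()].
#' @param params [energy_parameters()] used for the default `e_perfect`.
#' @return list of `candidate_zone` objects.
#' @export
call_zones <- function(profile, e_perfect = NULL, th = zone_thresholds(),
                       params = energy_parameters()) {
  stopifnot(inherits(profile, "attraction_profile"))
  if (is.null(e_perfect)) e_perfect <- perfect_complement_energy(profile$mirna, params)
  if (e_perfect >= 0) stop("e_perfect must be negative")
  sm <- profile$smoothed_energy
  below <- sm <= th$x_ratio * e_perfect
  if (!any(below)) return(list())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zones <- list()
  for (q in which(r$values)) {
    run <- starts[q]:ends[q]
    elig <- run[profile$has_structure[run] &
                profile$raw_energy[run] <= th$y_ratio * e_perfect &
                profile$first_mi[run] %in% c(1L, 2L)]
    if (length(elig) == 0L) next
    rep_anchor <- elig[which.min(profile$raw_energy[elig])]
    pr <- profile$pairs[[rep_anchor]]
    rep_st <- duplex_structure(pr, profile$mirna, profile$utr,
                               energy = profile$raw_energy[rep_anchor],
                               validate = FALSE)
    zones[[length(zones) + 1L]] <- structure(list(
      utr_id = profile$utr_id, mirna_id = profile$mirna_id,
      start = min(starts[q], min(pr[, 2])), end = max(ends[q], max(pr[, 2])),
      representative = rep_st, representative_anchor = rep_anchor,
      seed = profile$seed[rep_anchor], score = NA_real_),
      class = "candidate_zone")
  }
  zones
}

#' @export
print.candidate_zone <- function(x, ...) {
  cat("candidate zone ", x$mirna_id, " @ ", x$utr_id, ":", x$start, "-", x$end,
      " (anchor ", x$representative_anchor, ", E ",
      formatC(x$representative$energy, digits = 2, format = "f"),
      if (!is.na(x$score)) paste0(", score ", formatC(x$score, digits = 3, format = "f")) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Merge overlapping candidate zones
#'
#' Overlapping intervals (1-based inclusive) on the same (UTR, microRNA)
#' pair are unioned; the representative and score of a merged zone are
#' those of its highest-scoring constituent.  All zones must already carry
#' a classifier score.
#'
#' @param zones list of scored `candidate_zone` objects sharing
#'   `(utr_id, mirna_id)`.
#' @return non-overlapping list sorted by start.
#' @export
merge_zones <- function(zones) {
  if (length(zones) == 0L) return(zones)
  if (any(vapply(zones, function(z) is.na(z$score), logical(1)))) {
    stop("all zones must be scored before merging")
  }
  key <- unique(vapply(zones, function(z) paste(z$utr_id, z$mirna_id), character(1)))
  if (length(key) != 1L) stop("zones must share (utr_id, mirna_id)")
  ord <- order(vapply(zones, `[[`, numeric(1), "start"),
               vapply(zones, `[[`, numeric(1), "end"))
  zones <- zones[ord]
  out <- list()
  cur <- zones[[1]]
  for (z in zones[-1]) {
    if (z$start <= cur$end) {  # overlap (1-based inclusive)
      better <- z$score > cur$score ||
        (z$score == cur$score && z$representative_anchor < cur$representative_anchor)
      if (better) {
        keep_start <- min(cur$start, z$start); keep_end <- max(cur$end, z$end)
        cur <- z; cur$start <- keep_start; cur$end <- keep_end
      } else {
        cur$end <- max(cur$end, z$end)
        cur$start <- min(cur$start, z$start)
      }
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- z
    }
  }
  out[[length(out) + 1L]] <- cur
  out
}
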