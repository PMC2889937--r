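#' Construct a duplex structure
#'
#' A duplex structure is an ordered list of intermolecular base pairs
#' between a microRNA (positions counted 1-based from its 5' end) and a
#' target window (1-based positions, 5'->3').  Along the list `mi_pos` is
#' strictly increasing and `t_pos` strictly decreasing (antiparallel
#' strands, no crossing pairs), every pair is Watson-Crick or G:U, and
#' every helix (maximal run of directly stacked pairs) has length at least
#' two.
#'
#' @param pairs two-column integer matrix (`mi_pos`, `t_pos`).
#' @param mirna,target RNA sequences the pairs refer to.
#' @param energy optional precomputed energy (kcal/mol).
#' @param validate check the structural invariants (default `TRUE`).
#' @return object of class `duplex_structure` with elements `pairs`,
#'   `pair_types` (strings like `"GC"`, microRNA base first) and `energy`.
#' @export
duplex_structure <- function(pairs, mirna, target, energy = NA_real_, validate = TRUE) {
  mirna <- as_rna(mirna); target <- as_rna(target)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("mi_pos", "t_pos")))
  mi_b <- strsplit(mirna, "")[[1]]
  t_b <- strsplit(target, "")[[1]]
  if (nrow(pairs) == 0L) stop("a duplex structure needs at least one pair")
  if (any(pairs[, 1] < 1L) || any(pairs[, 1] > length(mi_b)) ||
      any(pairs[, 2] < 1L) || any(pairs[, 2] > length(t_b))) {
    stop("pair index out of sequence range")
  }
  types <- paste0(mi_b[pairs[, 1]], t_b[pairs[, 2]])
  if (validate) {
    if (nrow(pairs) > 1L) {
      if (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) >= 0L)) {
        stop("invalid structure: pairs must have increasing mi_pos and decreasing t_pos")
      }
    }
    ok <- types %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    if (!all(ok)) stop("invalid structure: non-pairable bases ", paste(unique(types[!ok]), collapse = ","))
    if (min(helix_lengths(pairs)) < 2L) stop("invalid structure: lonely pair (helix of length 1)")
  }
  structure(list(pairs = pairs, pair_types = types, energy = energy),
            class = "duplex_structure")
}

# lengths of maximal stacked runs (helices) along the pair list
helix_lengths <- function(pairs) {
  if (nrow(pairs) == 1L) return(1L)
  stacked <- diff(pairs[, 1]) == 1L & diff(pairs[, 2]) == -1L
  runs <- integer(0); cur <- 1L
  for (k in seq_along(stacked)) {
    if (stacked[k]) cur <- cur + 1L else { runs <- c(runs, cur); cur <- 1L }
  }
  c(runs, cur)
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat("duplex structure: ", nrow(x$pairs), " pairs, energy ",
      formatC(x$energy, digits = 3, format = "f"), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Score a duplex structure with the nearest-neighbor model
#'
#' Returns `init + sum(stack terms) + sum(bulge/interior penalties) +
#' terminal penalties`, the explicit scoring function behind all anchored
#' optimization.  Terminal penalties are charged at the duplex's first and
#' last pair when they are AU or GU.
#'
#' @param pairs two-column matrix (`mi_pos`, `t_pos`) or a `duplex_structure`.
#' @param mirna,window RNA sequences (characters or Biostrings objects).
#' @param params [energy_parameters()].
#' @return energy in kcal/mol.
#' @export
#' @examples
#' score_structure(cbind(1:2, 2:1), "GG", "CC")
score_structure <- function(pairs, mirna, window, params = energy_parameters()) {
  if (inherits(pairs, "duplex_structure")) pairs <- pairs$pairs
  st <- duplex_structure(pairs, mirna, window, validate = TRUE)
  types <- st$pair_types
  pr <- st$pairs
  e <- params$init
  n <- nrow(pr)
  for (k in seq_len(n - 1L)) {
    gi <- pr[k + 1L, 1] - pr[k, 1] - 1L
    gj <- pr[k, 2] - pr[k + 1L, 2] - 1L
    if (gi > params$max_loop_side || gj > params$max_loop_side) {
      stop("invalid structure: loop side exceeds max_loop_side")
    }
    if (gi == 0L && gj == 0L) {
      e <- e + params$stack[types[k], types[k + 1L]]
    } else if (gi == 0L || gj == 0L) {
      e <- e + params$bulge[gi + gj]
    } else {
      e <- e + params$interior[gi + gj - 1L]
    }
  }
  for (k in unique(c(1L, n))) {
    if (types[k] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal
  }
  e
}

#' Energy of the perfect reverse-complement duplex
#'
#' The minimum free energy attainable by a microRNA is defined as the
#' score of the fully Watson-Crick duplex of the microRNA against its
#' perfect reverse complement.  All zone thresholds are expressed relative
#' to this value.
#'
#' @inheritParams score_structure
#' @return energy in kcal/mol (strictly negative for any microRNA of
#'   length >= 8 under the bundled table).
#' @export
perfect_complement_energy <- function(mirna, params = energy_parameters()) {
  s <- as_rna(mirna)
  m <- nchar(s)
  target <- reverse_complement(s)
  score_structure(cbind(seq_len(m), rev(seq_len(m))), s, target, params)
}

#' G:U admissibility filter for duplex structures
#'
#' A structure is discarded (returns `FALSE`) when any of its first eight
#' pairs (in `mi_pos` order) is a G:U wobble, or when it carries five or
#' more G:U pairs in total.
#'
#' @param structure a `duplex_structure`.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_structure <- function(structure) {
  stopifnot(inherits(structure, "duplex_structure"))
  gu <- structure$pair_types %in% c("GU", "UG")
  if (any(gu[seq_len(min(8L, length(gu)))])) return(FALSE)
  if (sum(gu) >= 5L) return(FALSE)
  TRUE
}

# does the structure carry a perfect 5'-end pairing of >= 7 consecutive
# nucleotides starting at microRNA position 1 (the seed region)?
has_seed_region <- function(structure) {
  pr <- structure$pairs
  if (nrow(pr) < 7L) return(FALSE)
  all(pr[1:7, 1] == 1:7) && all(diff(pr[1:7, 2]) == -1L)
}

span_3prime <- function(mirna_length, params) mirna_length + 15L

#' Minimum-energy duplex anchored at a given mRNA position
#'
#' Searches all admissible duplex structures whose 5'-most microRNA pairing
#' sits at UTR position `anchor` (pairing confined to the window
#' `[anchor - span, anchor]` with `span = microRNA length + 15`), applies
#' the G:U discard rules of [filter_structure()], and returns the
#' energetically most favorable structure.  Ties are broken towards fewer
#' pairs.
#'
#' @param mirna,utr RNA sequences.
#' @param anchor 1-based UTR position.
#' @param params [energy_parameters()].
#' @param seed_forced restrict the search to structures beginning with the
#'   perfect 7-pair 5'-end helix (used by the seed-preference pruning).
#' @return object of class `anchored_optimum`: list with `anchor`,
#'   `structure` (a `duplex_structure` or `NULL` when no admissible
#'   structure anchors there) and `seed_flag`.
#' @export
anchored_minimum <- function(mirna, utr, anchor, params = energy_parameters(),
                             seed_forced = FALSE) {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  n <- nchar(utr)
  if (anchor < 1L || anchor > n) stop("anchor out of range [1, ", n, "]")
  mi <- rna_codes(mirna)
  lo <- max(1L, anchor - span_3prime(length(mi), params))
  win <- rna_codes(substr(utr, lo, anchor))
  res <- cpp_dp_anchor(mi, win, unclass(params), seed_forced)
  if (!res$found) {
    return(structure(list(anchor = anchor, structure = NULL, seed_flag = FALSE),
                     class = "anchored_optimum"))
  }
  pr <- res$pairs
  pr[, 2] <- pr[, 2] + lo - 1L
  st <- duplex_structure(pr, mirna, utr, energy = res$energy)
  structure(list(anchor = anchor, structure = st, seed_flag = has_seed_region(st)),
            class = "anchored_optimum")
}

#' Seed-preference pruning of same-anchor duplexes
#'
#' When structures sharing one anchor include at least one with a perfect
#' 5'-end pairing of at least seven consecutive nucleotides starting at
#' microRNA position 1 (a seed region), all seedless structures at that
#' anchor are discarded; otherwise the group is returned unchanged.
#'
#' @param candidates_at_anchor list of `duplex_structure` objects sharing
#'   an anchor.
#' @param mirna the microRNA (unused by the computation, kept for interface
#'   symmetry with the other per-anchor operations).
#' @return the retained list.
#' @export
prune_anchor_group <- function(candidates_at_anchor, mirna = NULL) {
  if (length(candidates_at_anchor) == 0L) return(candidates_at_anchor)
  seeded <- vapply(candidates_at_anchor, has_seed_region, logical(1))
  if (any(seeded)) candidates_at_anchor[seeded] else candidates_at_anchor
}
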