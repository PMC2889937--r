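#' Canonical feature catalogue
#'
#' Names of the full duplex/site feature catalogue computed by
#' [extract_features()].  Nucleotide-valued anchor features are encoded
#' numerically (`none = 0, A = 1, C = 2, G = 3, U = 4`); S/W anchor
#' indicators are 1 when the base is A or U.  The two RISC-accessibility
#' features are not part of the catalogue; they exist only behind the
#' optional hook of [accessibility_hook()].
#'
#' @return character vector of 43 feature names.
#' @export
feature_catalogue <- function() c(
  "seed8_pairings", "gc_target", "pairings_3prime_8", "consecutive_3prime_2gap",
  "cpg_target", "gc_ratio_mirna_target", "compactness", "t9_anchor",
  "longest_stretch", "mi_bulges_len3", "t1_sw_anchor", "total_pairings",
  "t_bulges_len7plus", "t1_anchor", "mi_bulges_len2", "cpg_upstream",
  "t_bulges_len1", "t_bulge_total_len", "target_len", "mi_bulge_total_len",
  "utr_position_bin", "symmetric_bulges", "gc_upstream50", "t_bulge_count",
  "t_second_largest_bulge", "t_bulge_mean_len", "t9_sw_anchor",
  "binding_asymmetry", "t_bulges_len2", "gu_total", "t_bulges_len4",
  "gc_diff_first_last8", "cpg_downstream", "mi_bulges_len1",
  "mi_second_largest_bulge", "mi_bulge_count", "mi_bulges_len5",
  "t_bulges_len3", "gc_diff_site_flank", "t_bulges_len5", "mi_bulges_len4",
  "gc_downstream50", "t_bulges_len6")

#' Default classifier feature set
#'
#' The seven-feature subset used by the default model: compactness, G+C
#' content ratio between microRNA and target site, longest consecutive
#' pairing stretch, binding asymmetry, G+C content of the target site,
#' pairings to the microRNA 8-mer seed, and the target-site position bin
#' within the 3'UTR.
#'
#' @return character vector of 7 feature names.
#' @export
model_feature_set <- function() c(
  "compactness", "gc_ratio_mirna_target", "longest_stretch",
  "binding_asymmetry", "gc_target", "seed8_pairings", "utr_position_bin")

#' Extension point for RISC-accessibility features
#'
#' Accessibility of the target site to the silencing complex requires an
#' intramolecular folding backend, which this package deliberately does
#' not bundle.  Registering a function `f(zone, utr, mirna)` returning a
#' named numeric vector (e.g. `accessibility_3_15`, `accessibility_30_30`)
#' makes those values available to [extract_features()] when explicitly
#' requested; by default the features are absent.
#'
#' @param f hook function, or `NULL` to unregister.
#' @return the previously registered hook, invisibly.
#' @export
accessibility_hook <- function(f = NULL) {
  old <- .mirsite_env$accessibility_hook
  if (!missing(f)) .mirsite_env$accessibility_hook <- f
  invisible(old)
}

gc_content <- function(s) {
  if (nchar(s) == 0L) return(0)
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("G", "C"))
}
gc_count <- function(s) if (nchar(s) == 0L) 0L else sum(strsplit(s, "")[[1]] %in% c("G", "C"))
cpg_count <- function(s) {
  if (nchar(s) < 2L) return(0L)
  length(gregexpr("CG", s, fixed = TRUE)[[1]][gregexpr("CG", s, fixed = TRUE)[[1]] > 0])
}

#' Base-pairing extent features
#'
#' @param structure a `duplex_structure`.
#' @param mirna the microRNA sequence.
#' @return named numeric vector with `seed8_pairings`,
#'   `pairings_3prime_8`, `consecutive_3prime_2gap`, `longest_stretch`,
#'   `target_len`, `total_pairings`, `gu_total`, `binding_asymmetry`.
#' @export
pairing_features <- function(structure, mirna) {
  m <- nchar(as_rna(mirna))
  pr <- structure$pairs
  mi <- pr[, 1]
  # run from the 3'-most paired position towards 5', tolerating at most two
  # unpaired microRNA positions in total
  cons <- 0L; gaps <- 0L
  p <- max(mi)
  paired <- logical(m); paired[mi] <- TRUE
  while (p >= 1L) {
    if (paired[p]) cons <- cons + 1L
    else { gaps <- gaps + 1L; if (gaps > 2L) break }
    p <- p - 1L
  }
  n3 <- sum(mi > m - 8L)
  n5 <- sum(mi <= 8L)
  asym <- if (n5 == 0L) (n3 + 1) / 1 else n3 / n5
  c(seed8_pairings = sum(mi <= 8L),
    pairings_3prime_8 = n3,
    consecutive_3prime_2gap = cons,
    longest_stretch = max(helix_lengths(pr)),
    target_len = diff(range(pr[, 2])) + 1L,
    total_pairings = nrow(pr),
    gu_total = sum(structure$pair_types %in% c("GU", "UG")),
    binding_asymmetry = asym)
}

#' Bulge features of a duplex
#'
#' A bulge on a strand is a maximal run of unpaired nucleotides strictly
#' between two paired positions of that strand; a symmetric bulge is an
#' inter-pair gap with equal (non-zero) unpaired counts on both strands.
#' MicroRNA bulge sizes 1-5 and target bulge sizes 1-6 plus "7 or greater"
#' are histogrammed separately, the target side additionally carrying the
#' mean and second-largest lengths.
#'
#' @param structure a `duplex_structure`.
#' @return named numeric vector of the bulge-related catalogue entries.
#' @export
bulge_features <- function(structure) {
  pr <- structure$pairs
  n <- nrow(pr)
  gi <- gj <- integer(0)
  if (n > 1L) {
    gi <- pr[-1, 1] - pr[-n, 1] - 1L
    gj <- pr[-n, 2] - pr[-1, 2] - 1L
  }
  mib <- gi[gi > 0L]; tb <- gj[gj > 0L]
  second <- function(v) if (length(v) < 2L) 0 else sort(v, decreasing = TRUE)[2]
  out <- c(
    mi_bulge_count = length(mib), mi_bulge_total_len = sum(mib),
    mi_second_largest_bulge = second(mib),
    t_bulge_count = length(tb), t_bulge_total_len = sum(tb),
    t_second_largest_bulge = second(tb),
    t_bulge_mean_len = if (length(tb)) mean(tb) else 0,
    symmetric_bulges = sum(gi > 0L & gi == gj))
  for (k in 1:5) out[paste0("mi_bulges_len", k)] <- sum(mib == k)
  for (k in 1:6) out[paste0("t_bulges_len", k)] <- sum(tb == k)
  out["t_bulges_len7plus"] <- sum(tb >= 7L)
  out
}

#' Position-specific features
#'
#' The 3'UTR is split into 100 bins and the bin containing the
#' representative's anchor reported; the target nucleotides opposite
#' microRNA positions 1 and 9 are read along the representative's pairing
#' register (position 9 interpolated from the nearest 5'-side pair when
#' unpaired) and encoded as `none = 0, A = 1, C = 2, G = 3, U = 4`, with
#' companion indicators marking an A or U base.
#'
#' @param zone a `candidate_zone`.
#' @param utr the UTR sequence.
#' @param mirna the microRNA sequence (unused, kept for interface symmetry).
#' @return named numeric vector with `utr_position_bin`, `t1_anchor`,
#'   `t9_anchor`, `t1_sw_anchor`, `t9_sw_anchor`.
#' @export
positional_features <- function(zone, utr, mirna = NULL) {
  utr <- as_rna(utr)
  n <- nchar(utr)
  anchor <- zone$representative_anchor
  if (anchor < 1L || anchor > n) stop("representative anchor outside the UTR")
  bin <- min(100L, max(1L, as.integer(ceiling(100 * anchor / n))))
  pr <- zone$representative$pairs
  fp <- range(pr[, 2])
  opposite <- function(q) {
    hit <- which(pr[, 1] == q)
    if (length(hit)) return(pr[hit[1], 2])
    below <- which(pr[, 1] < q)
    if (!length(below)) return(NA_integer_)
    k <- below[length(below)]
    pr[k, 2] - (q - pr[k, 1])
  }
  code <- function(t) {
    if (is.na(t) || t < fp[1] || t > fp[2]) return(c(base = 0, sw = 0))
    b <- substr(utr, t, t)
    c(base = match(b, c("A", "C", "G", "U")), sw = as.numeric(b %in% c("A", "U")))
  }
  c1 <- code(opposite(1L)); c9 <- code(opposite(9L))
  c(utr_position_bin = bin,
    t1_anchor = c1[["base"]], t9_anchor = c9[["base"]],
    t1_sw_anchor = c1[["sw"]], t9_sw_anchor = c9[["sw"]])
}

#' Compositional features of the target site and its flanks
#'
#' G+C content of the site and its 50-nt flanks (truncated at the UTR
#' ends), the microRNA/site G+C ratio, the difference in G+C between the
#' site and its 20-nt upstream flank, between the first and last eight
#' site nucleotides, and CpG dinucleotide counts in the site and its
#' 20-nt flanks.  When the site contains no G or C at all, the ratio
#' denominator is replaced by half a count to stay finite.
#'
#' @param zone a `candidate_zone`.
#' @param utr,mirna RNA sequences.
#' @return named numeric vector of the compositional catalogue entries.
#' @export
compositional_features <- function(zone, utr, mirna) {
  utr <- as_rna(utr); mirna <- as_rna(mirna)
  n <- nchar(utr)
  fp <- range(zone$representative$pairs[, 2])
  if (fp[1] < 1L || fp[2] > n) stop("target footprint outside the UTR")
  site <- substr(utr, fp[1], fp[2])
  flank <- function(len, side) {
    if (side == "up") substr(utr, max(1L, fp[1] - len), fp[1] - 1L)
    else substr(utr, fp[2] + 1L, min(n, fp[2] + len))
  }
  gc_site <- gc_content(site)
  denom <- max(gc_count(site), 0.5) / nchar(site)
  k8 <- min(8L, nchar(site))
  c(gc_target = gc_site,
    gc_upstream50 = gc_content(flank(50L, "up")),
    gc_downstream50 = gc_content(flank(50L, "down")),
    gc_ratio_mirna_target = gc_content(mirna) / denom,
    gc_diff_site_flank = gc_site - gc_content(flank(20L, "up")),
    gc_diff_first_last8 = gc_content(substr(site, 1L, k8)) -
      gc_content(substr(site, nchar(site) - k8 + 1L, nchar(site))),
    cpg_target = cpg_count(site),
    cpg_upstream = cpg_count(flank(20L, "up")),
    cpg_downstream = cpg_count(flank(20L, "down")))
}

#' Compactness of a duplex
#'
#' The mean of `n_pair / microRNA length` and `n_pair / target site
#' length`; when the target site is shorter than the microRNA the mean is
#' additionally multiplied by `target length / microRNA length`, which
#' preserves the range and is continuous at equal lengths.  Compactness
#' lies in `[0, 1]` and equals 1 exactly when every nucleotide of both
#' strands is paired.
#'
#' @param structure a `duplex_structure`, or `NULL` for the degenerate
#'   pairless case (compactness 0).
#' @param mirna the microRNA sequence.
#' @return a value in `[0, 1]`.
#' @export
#' @examples
#' # 22-nt microRNA fully paired to an equal-length site
#' m <- paste(rep("GCAU", 6), collapse = "")
#' m <- substr(m, 1, 22)
#' s <- duplex_structure(cbind(1:22, 22:1), m, reverse_complement(m))
#' compactness(s, m)  # 1
compactness <- function(structure, mirna) {
  mi_len <- nchar(as_rna(mirna))
  if (is.null(structure) || nrow(structure$pairs) == 0L) return(0)
  n_pair <- nrow(structure$pairs)
  ts_len <- diff(range(structure$pairs[, 2])) + 1L
  v <- 0.5 * (n_pair / mi_len + n_pair / ts_len)
  if (ts_len < mi_len) v <- v * ts_len / mi_len
  v
}

#' Compute a feature vector for a candidate zone
#'
#' Aggregates the pairing, bulge, positional, compositional and
#' compactness computations on the zone's representative duplex and
#' returns the requested subset.  Accessibility features are only
#' available after registering [accessibility_hook()].
#'
#' @param zone a `candidate_zone`.
#' @param utr,mirna RNA sequences.
#' @param set character vector of feature names (default: the full
#'   catalogue).
#' @return named numeric vector in the order of `set`.
#' @export
extract_features <- function(zone, utr, mirna, set = feature_catalogue()) {
  known <- feature_catalogue()
  hook <- .mirsite_env$accessibility_hook
  acc <- c("accessibility_3_15", "accessibility_30_30")
  bad <- setdiff(set, c(known, if (!is.null(hook)) acc))
  if (length(bad)) stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  st <- zone$representative
  v <- c(pairing_features(st, mirna),
         bulge_features(st),
         positional_features(zone, utr, mirna),
         compositional_features(zone, utr, mirna),
         compactness = compactness(st, mirna))
  if (!is.null(hook) && any(set %in% acc)) v <- c(v, hook(zone, utr, mirna))
  v[set]
}

#' Write a feature table as TSV
#'
#' @param table data frame of feature vectors (one row per instance).
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
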