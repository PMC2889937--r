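#' Perfect 7-mer seed match
#'
#' `TRUE` when the target interval sequence contains the exact
#' Watson-Crick reverse complement (no G:U) of microRNA positions 1-7 or
#' 2-8.
#'
#' @param site_seq the zone's target interval sequence (RNA).
#' @param mirna the microRNA sequence.
#' @return logical.
#' @export
seed_match <- function(site_seq, mirna) {
  site_seq <- as_rna(site_seq); mirna <- as_rna(mirna)
  if (nchar(mirna) < 8L) stop("microRNA shorter than 8 nt")
  s17 <- reverse_complement(substr(mirna, 1L, 7L))
  s28 <- reverse_complement(substr(mirna, 2L, 8L))
  grepl(s17, site_seq, fixed = TRUE) || grepl(s28, site_seq, fixed = TRUE)
}

#' Conserved seed match through a multi-species UTR alignment
#'
#' `TRUE` when the record's interval contains a Watson-Crick 6-mer seed
#' match (microRNA positions 2-7) whose six alignment columns are
#' gap-free and identical across all species, and whose reference
#' sequence additionally matches microRNA base 1 (position 3' of the
#' 6-mer) or base 8 (position 5' of it).
#'
#' @param alignment an `aligned_utr_set` whose reference degaps to the
#'   record's UTR.
#' @param record one prediction row (list/data.frame row with `start`,
#'   `end`).
#' @param mirna the microRNA sequence.
#' @return logical.
#' @export
conserved_seed_match <- function(alignment, record, mirna) {
  mirna <- as_rna(mirna)
  ref <- reference_utr(alignment)
  n <- nchar(ref)
  if (record$end > n || record$start < 1L) {
    warning("record interval does not map into the reference row")
    return(FALSE)
  }
  seed6 <- reverse_complement(substr(mirna, 2L, 7L))
  m1 <- wc_complement_base(substr(mirna, 1L, 1L))
  m8 <- wc_complement_base(substr(mirna, 8L, 8L))
  rows <- alignment$rows
  hits <- gregexpr(seed6, substr(ref, record$start, record$end), fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(FALSE)
  for (h in hits) {
    s <- record$start + h - 1L           # 6-mer at ref positions s .. s+5
    cols <- alignment$ref_map[s:(s + 5L)]
    col_seq <- vapply(rows, function(r) paste(strsplit(r, "")[[1]][cols], collapse = ""),
                      character(1))
    if (any(col_seq != col_seq[[alignment$reference]]) || any(grepl("-", col_seq))) next
    ok1 <- s + 6L <= n && substr(ref, s + 6L, s + 6L) == m1   # pairs microRNA base 1
    ok8 <- s - 1L >= 1L && substr(ref, s - 1L, s - 1L) == m8  # pairs microRNA base 8
    if (ok1 || ok8) return(TRUE)
  }
  FALSE
}

#' Predict microRNA target sites on a set of UTRs
#'
#' The end-to-end pipeline: for each (microRNA, UTR) pair an attraction
#' profile is built, candidate zones are called, each zone's
#' representative is featurized and scored by the boosted model,
#' overlapping zones are merged (keeping the highest-scoring
#' representative), and records are emitted sorted by descending score
#' with seed / conserved-seed class flags and the sens/spec stringency
#' derived from the model's calibrated thresholds.
#'
#' @param mirnas,utrs named character vectors (e.g. from [read_fasta()]).
#' @param model a calibrated `boosted_model`.
#' @param params [energy_parameters()].
#' @param th [zone_thresholds()].
#' @param alignments optional named list (by UTR id) of
#'   `aligned_utr_set` objects enabling the conserved-seed flag.
#' @return data frame with columns `utr_id`, `mirna_id`, `start`, `end`,
#'   `score`, `seed_flag`, `conserved_flag`, `stringency`.
#' @export
predict_targets <- function(mirnas, utrs, model, params = energy_parameters(),
                            th = zone_thresholds(), alignments = NULL) {
  stopifnot(inherits(model, "boosted_model"))
  if (is.null(model$thresholds)) stop("model has no calibrated thresholds")
  empty <- data.frame(utr_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      seed_flag = logical(0), conserved_flag = logical(0),
                      stringency = character(0), stringsAsFactors = FALSE)
  if (length(mirnas) == 0L || length(utrs) == 0L) {
    warning("empty input: no predictions made")
    return(empty)
  }
  rows <- list()
  for (mid in names(mirnas)) {
    e_perf <- perfect_complement_energy(mirnas[[mid]], params)
    for (uid in names(utrs)) {
      prof <- build_profile(mirnas[[mid]], utrs[[uid]], params,
                            mirna_id = mid, utr_id = uid)
      zones <- call_zones(prof, e_perfect = e_perf, th = th, params = params)
      if (length(zones) == 0L) next
      for (k in seq_along(zones)) {
        fv <- extract_features(zones[[k]], utrs[[uid]], mirnas[[mid]],
                               set = model$feature_set)
        zones[[k]]$score <- score_features(model, fv)
      }
      zones <- merge_zones(zones)
      aln <- if (!is.null(alignments)) alignments[[uid]] else NULL
      for (z in zones) {
        site <- substr(utrs[[uid]], z$start, z$end)
        sflag <- seed_match(site, mirnas[[mid]])
        cflag <- FALSE
        if (sflag && !is.null(aln)) {
          cflag <- conserved_seed_match(aln, list(start = z$start, end = z$end),
                                        mirnas[[mid]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          utr_id = uid, mirna_id = mid, start = z$start, end = z$end,
          score = z$score, seed_flag = sflag, conserved_flag = cflag,
          stringency = if (z$score >= model$thresholds$spec) "spec"
                       else if (z$score >= model$thresholds$sens) "sens"
                       else "below",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$utr_id, out$mirna_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset predictions by class and stringency
#'
#' @param records prediction data frame from [predict_targets()].
#' @param class `"no-seed"` (all records), `"seed"` or `"cons-seed"`.
#' @param stringency `"all"`, `"sens"` (sens or spec) or `"spec"`.
#' @return filtered data frame.
#' @export
filter_predictions <- function(records, class = c("no-seed", "seed", "cons-seed"),
                               stringency = c("all", "sens", "spec")) {
  class <- match.arg(class); stringency <- match.arg(stringency)
  keep <- rep(TRUE, nrow(records))
  if (class == "seed") keep <- keep & records$seed_flag
  if (class == "cons-seed") keep <- keep & records$conserved_flag
  if (stringency == "sens") keep <- keep & records$stringency %in% c("sens", "spec")
  if (stringency == "spec") keep <- keep & records$stringency == "spec"
  records[keep, , drop = FALSE]
}

#' Build a labeled training table from validated binding sites
#'
#' For every validated site and its microRNA family, the candidate zones
#' of family members overlapping the site (at least one shared position)
#' yield one positive instance - the energetically most favorable
#' overlapping candidate; the energetically most stable non-overlapping
#' candidate of the same interaction yields one negative instance.
#' Sites with no candidate at all are skipped with a message.
#'
#' @param zones flat list of `candidate_zone` objects (all microRNAs of
#'   every site's family must have been scanned).
#' @param validated data frame with `transcript_id`, `start`, `end`,
#'   `family`.
#' @param families named list: family -> character vector of microRNA ids.
#' @param utrs,mirnas named sequence vectors for feature extraction.
#' @param feature_set features to extract (default: full catalogue).
#' @return list with `x` (feature data frame), `y` (1 = overlapping a
#'   validated site), and `info` (ids and energies per instance).
#' @export
build_training_set <- function(zones, validated, families, utrs, mirnas,
                               feature_set = feature_catalogue()) {
  zmeta <- data.frame(
    idx = seq_along(zones),
    utr_id = vapply(zones, `[[`, character(1), "utr_id"),
    mirna_id = vapply(zones, `[[`, character(1), "mirna_id"),
    start = vapply(zones, `[[`, numeric(1), "start"),
    end = vapply(zones, `[[`, numeric(1), "end"),
    energy = vapply(zones, function(z) z$representative$energy, numeric(1)),
    stringsAsFactors = FALSE)
  pick <- list()
  for (r in seq_len(nrow(validated))) {
    v <- validated[r, ]
    fam <- families[[v$family]]
    cand <- zmeta[zmeta$utr_id == v$transcript_id & zmeta$mirna_id %in% fam, , drop = FALSE]
    if (nrow(cand) == 0L) {
      message("validated site ", v$transcript_id, ":", v$start, "-", v$end,
              " (", v$family, ") has no candidate; skipped")
      next
    }
    ov <- cand$start <= v$end & cand$end >= v$start
    if (any(ov)) {
      top <- cand[ov, ][which.min(cand$energy[ov]), ]
      pick[[length(pick) + 1L]] <- cbind(top, label = 1L)
    }
    if (any(!ov)) {
      top <- cand[!ov, ][which.min(cand$energy[!ov]), ]
      pick[[length(pick) + 1L]] <- cbind(top, label = 0L)
    }
  }
  if (length(pick) == 0L) stop("no instances could be built")
  info <- do.call(rbind, pick)
  feats <- lapply(info$idx, function(i) {
    z <- zones[[i]]
    extract_features(z, utrs[[z$utr_id]], mirnas[[z$mirna_id]], set = feature_set)
  })
  x <- as.data.frame(do.call(rbind, feats))
  rownames(x) <- NULL; rownames(info) <- NULL
  list(x = x, y = info$label, info = info[, setdiff(names(info), "label")])
}

#' Fraction of predicted targets with reduced protein output
#'
#' The positive predictive value on proteomic fold-change data: among
#' predicted (gene, microRNA) interactions with a measured log2
#' fold change, the fraction whose fold change falls below the cutoff.
#' Interactions lacking a measurement are excluded from both counts.
#'
#' @param predictions prediction data frame (`utr_id` is the gene id).
#' @param fold_changes data frame with `gene`, `mirna`, `log2fc`.
#' @param cutoff fold-change threshold (default -0.1).
#' @return accuracy in `[0, 1]`; `NaN` with a warning when no predicted
#'   interaction has a measurement.
#' @export
psilac_accuracy <- function(predictions, fold_changes, cutoff = -0.1) {
  ints <- unique(predictions[, c("utr_id", "mirna_id")])
  key <- paste(ints$utr_id, ints$mirna_id, sep = "\r")
  fc_key <- paste(fold_changes$gene, fold_changes$mirna, sep = "\r")
  hit <- match(key, fc_key)
  measured <- !is.na(hit)
  if (!any(measured)) {
    warning("no predicted interaction has a fold-change measurement")
    return(NaN)
  }
  mean(fold_changes$log2fc[hit[measured]] < cutoff)
}
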