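#' Specification of a synthetic test corpus
#'
#' Captures everything the seeded generators need: corpus dimensions, the
#' background base composition, the implant plan (which microRNA is
#' planted where, and at what site quality), the conservation plan for
#' aligned species copies, and the class-separation parameters for
#' labeled feature tables.
#'
#' @param seed integer RNG seed; all generators are bit-reproducible
#'   given it.
#' @param n_utrs,n_mirnas corpus sizes.
#' @param utr_length length-2 integer vector `(min, max)`; lengths are
#'   drawn uniformly.
#' @param gc_background background G+C fraction in (0, 1).
#' @param mirna_length mature microRNA length (default 22).
#' @param implants data frame with columns `utr` (index), `mirna`
#'   (index), `anchor` (1-based UTR position of the site's 3' end) and
#'   `quality` in `perfect`, `seed_only`, `compensatory_3prime`,
#'   `shuffled`.
#' @param n_species,mutation_rate conservation plan for
#'   [generate_alignments()].
#' @param shift,noise_sd class separation for [generate_labeled_table()]:
#'   `shift` is added to the positive-class mean of the default model
#'   features (a named vector shifts arbitrary features), `noise_sd` is
#'   the within-class standard deviation.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_utrs = 10L, utr_length = c(200L, 1000L),
                         gc_background = 0.45, n_mirnas = 5L, mirna_length = 22L,
                         implants = NULL, n_species = 5L, mutation_rate = 0.05,
                         shift = 0.4, noise_sd = 1) {
  stopifnot(length(utr_length) == 2L, utr_length[1] <= utr_length[2],
            gc_background > 0, gc_background < 1,
            mutation_rate >= 0, mutation_rate <= 1, noise_sd > 0)
  if (!is.null(implants)) {
    stopifnot(all(c("utr", "mirna", "anchor", "quality") %in% names(implants)))
    stopifnot(all(implants$quality %in%
                  c("perfect", "seed_only", "compensatory_3prime", "shuffled")))
  }
  structure(list(seed = as.integer(seed), n_utrs = as.integer(n_utrs),
                 utr_length = as.integer(utr_length), gc_background = gc_background,
                 n_mirnas = as.integer(n_mirnas), mirna_length = as.integer(mirna_length),
                 implants = implants, n_species = as.integer(n_species),
                 mutation_rate = mutation_rate, shift = shift, noise_sd = noise_sd),
            class = "fixture_spec")
}

random_rna <- function(n, gc) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)), collapse = "")
}

mutate_base <- function(b) sample(setdiff(c("A", "C", "G", "U"), b), 1L)

# Altschul-Erickson dinucleotide-preserving shuffle
dinucleotide_shuffle <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n < 3L) return(s)
  # edge lists of the dinucleotide multigraph, keyed by source base
  edges <- split(b[-1], b[-n])
  last <- b[n]
  repeat {
    shuffled <- lapply(edges, sample)
    # random walk from the original start consuming edges; succeeds when
    # all edges are used (Eulerian path exists by construction, the walk
    # may still get stuck - then retry)
    ptr <- lapply(shuffled, function(e) 1L)
    out <- character(n); out[1] <- b[1]
    cur <- b[1]; ok <- TRUE
    for (k in 2:n) {
      e <- shuffled[[cur]]
      i <- ptr[[cur]]
      if (is.null(e) || i > length(e)) { ok <- FALSE; break }
      ptr[[cur]] <- i + 1L
      cur <- e[i]
      out[k] <- cur
    }
    if (ok) return(paste(out, collapse = ""))
  }
}

#' Generate a synthetic corpus of microRNAs, UTRs and truth intervals
#'
#' Random i.i.d. UTRs at the configured G+C background carry implanted
#' complementarity sites of controlled quality: `perfect` plants the full
#' reverse complement of the microRNA, `seed_only` only the reverse
#' complement of microRNA positions 1-8, `compensatory_3prime` a site
#' with a deliberately mismatched seed but an intact complementary
#' microRNA 3' block of at least 10 nt, and `shuffled` a
#' dinucleotide-shuffled reverse complement (a composition-matched
#' decoy).  Implant anchors give the 3'-most footprint position; the
#' truth table records every implanted interval.
#'
#' @param spec a [fixture_spec()].
#' @return list with `mirnas`, `utrs` (named character vectors) and
#'   `truth` (data frame `utr_id`, `mirna_id`, `start`, `end`,
#'   `quality`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  mirnas <- setNames(
    vapply(seq_len(spec$n_mirnas), function(i) random_rna(spec$mirna_length, 0.5),
           character(1)),
    paste0("mir-", seq_len(spec$n_mirnas)))
  lens <- spec$utr_length[1] - 1L +
    sample.int(spec$utr_length[2] - spec$utr_length[1] + 1L, spec$n_utrs, replace = TRUE)
  utrs <- setNames(
    vapply(lens, random_rna, character(1), gc = spec$gc_background),
    paste0("utr-", seq_len(spec$n_utrs)))
  truth <- data.frame(utr_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0), quality = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$implants)) {
    used <- vector("list", spec$n_utrs)
    for (r in seq_len(nrow(spec$implants))) {
      im <- spec$implants[r, ]
      mi <- mirnas[[im$mirna]]
      L <- nchar(mi)
      site <- switch(im$quality,
        perfect = reverse_complement(mi),
        seed_only = paste0(random_rna(L - 8L, spec$gc_background),
                           reverse_complement(substr(mi, 1L, 8L))),
        compensatory_3prime = {
          s <- strsplit(reverse_complement(mi), "")[[1]]
          # break pairing at microRNA positions 3-5 (site is reverse order)
          for (q in 3:5) s[L - q + 1L] <- mutate_base(s[L - q + 1L])
          paste(s, collapse = "")
        },
        shuffled = dinucleotide_shuffle(reverse_complement(mi)))
      w <- nchar(site)
      start <- im$anchor - w + 1L
      u <- utrs[[im$utr]]
      if (start < 1L || im$anchor > nchar(u)) {
        stop("implant ", r, " does not fit its UTR (anchor ", im$anchor, ")")
      }
      iv <- c(start, im$anchor)
      for (prev in used[[im$utr]]) {
        if (iv[1] <= prev[2] && iv[2] >= prev[1]) {
          stop("implant plan overcrowded: overlapping implants in UTR ", im$utr)
        }
      }
      used[[im$utr]] <- c(used[[im$utr]], list(iv))
      substr(u, start, im$anchor) <- site
      utrs[[im$utr]] <- u
      truth <- rbind(truth, data.frame(
        utr_id = names(utrs)[im$utr], mirna_id = names(mirnas)[im$mirna],
        start = start, end = im$anchor, quality = im$quality,
        stringsAsFactors = FALSE))
    }
  }
  list(mirnas = mirnas, utrs = utrs, truth = truth)
}

#' Write a truth table as BED
#'
#' @param truth truth data frame from [generate_corpus()].
#' @param path output path (0-based half-open intervals).
#' @export
write_truth_bed <- function(truth, path) {
  gr <- GenomicRanges::GRanges(seqnames = truth$utr_id,
                               ranges = IRanges::IRanges(truth$start, truth$end),
                               strand = "+", name = truth$mirna_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Generate aligned species copies of the corpus UTRs
#'
#' Each UTR becomes an alignment of `n_species` rows: the reference row
#' is the UTR itself and every other species carries independent point
#' substitutions at the configured per-base mutation rate (no indels, so
#' rows stay trivially aligned).
#'
#' @param utrs named character vector of UTR sequences.
#' @param spec a [fixture_spec()] (uses `n_species`, `mutation_rate`,
#'   `seed`).
#' @param reference name given to the reference species row.
#' @return named list of `aligned_utr_set` objects keyed by UTR id.
#' @export
generate_alignments <- function(utrs, spec, reference = "species1") {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed + 104729L)
  out <- list()
  for (uid in names(utrs)) {
    u <- utrs[[uid]]
    rows <- setNames(character(spec$n_species),
                     c(reference, paste0("species", 1L + seq_len(spec$n_species - 1L))))
    rows[[reference]] <- u
    for (sp in names(rows)[-1]) {
      b <- strsplit(u, "")[[1]]
      hit <- which(runif(length(b)) < spec$mutation_rate)
      for (q in hit) b[q] <- mutate_base(b[q])
      rows[[sp]] <- paste(b, collapse = "")
    }
    out[[uid]] <- aligned_utr_set(rows, reference)
  }
  out
}

#' Generate a labeled two-class feature table
#'
#' Rows are drawn i.i.d. Gaussian over the canonical feature catalogue:
#' negatives from `N(0, noise_sd)` on every feature, positives with the
#' configured mean shift added to the shifted features (by default the
#' seven model features).  Used to exercise feature selection and the
#' classifier under a controlled class separation.
#'
#' @param spec a [fixture_spec()].
#' @param n_pos,n_neg class sizes.
#' @return list with `x` (data frame over [feature_catalogue()]) and `y`
#'   (labels, 1 = positive).
#' @export
generate_labeled_table <- function(spec, n_pos = 200L, n_neg = 200L) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (n_pos + n_neg == 0L) stop("empty table requested")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed + 7919L)
  feats <- feature_catalogue()
  shifts <- setNames(numeric(length(feats)), feats)
  if (is.null(names(spec$shift))) {
    shifts[model_feature_set()] <- spec$shift
  } else {
    shifts[names(spec$shift)] <- spec$shift
  }
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- sapply(feats, function(f) rnorm(n, mean = y * shifts[[f]], sd = spec$noise_sd))
  list(x = as.data.frame(x), y = y)
}

#' Generate a synthetic proteomic fold-change table for predictions
#'
#' Assigns each predicted (gene, microRNA) interaction a log2 fold
#' change: with probability `fraction_down` a value below -0.1
#' (down-regulated protein), otherwise a value above it.
#'
#' @param predictions prediction data frame.
#' @param fraction_down probability of down-regulation in `[0, 1]`.
#' @param seed RNG seed.
#' @return data frame with `gene`, `mirna`, `log2fc`.
#' @export
generate_psilac_table <- function(predictions, fraction_down, seed = 1L) {
  stopifnot(fraction_down >= 0, fraction_down <= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  ints <- unique(predictions[, c("utr_id", "mirna_id")])
  n <- nrow(ints)
  down <- runif(n) < fraction_down
  fc <- ifelse(down, -0.1 - runif(n, 0.05, 2), -0.1 + runif(n, 0.05, 1))
  data.frame(gene = ints$utr_id, mirna = ints$mirna_id, log2fc = fc,
             stringsAsFactors = FALSE)
}
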