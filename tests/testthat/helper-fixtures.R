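# shared in-code fixtures for the test suite

pair_names6 <- c("AU", "UA", "GC", "CG", "GU", "UG")

zero_params <- function() {
  make_energy_parameters(
    stack = matrix(0, 6, 6, dimnames = list(pair_names6, pair_names6)),
    bulge = rep(0, 15), interior = rep(0, 29), init = 0, terminal = 0,
    max_loop_side = 15L, version = "zero-table")
}

# directly construct a random admissible structure (helices of length >= 2
# separated by bounded loops) without going through any search code
random_admissible_structure <- function(m_len = 22L, w_len = 30L) {
  repeat {
    mirna <- random_rna_str(m_len)
    i <- sample.int(max(1L, m_len - 3L), 1L)
    j <- sample(seq(min(6L, w_len), w_len), 1L)
    pairs <- NULL
    while (TRUE) {
      helix <- sample(2:4, 1L)
      for (q in seq_len(helix)) {
        if (i > m_len || j < 1L) break
        pairs <- rbind(pairs, c(i, j))
        i <- i + 1L; j <- j - 1L
      }
      if (runif(1) < 0.45 || i > m_len - 1L || j < 3L) break
      gi <- sample(0:3, 1L); gj <- sample(0:3, 1L)
      i <- i + gi; j <- j - gj
      if (i > m_len - 1L || j < 2L) break
    }
    if (is.null(pairs) || nrow(pairs) < 2L) next
    # trim a trailing lonely helix
    hl <- mirsite:::helix_lengths(pairs)
    if (min(hl) < 2L) {
      pairs <- pairs[seq_len(nrow(pairs) - 1L), , drop = FALSE]
      if (nrow(pairs) < 2L || min(mirsite:::helix_lengths(pairs)) < 2L) next
    }
    # fill the window with complementary bases so every pair is WC
    mi_b <- strsplit(mirna, "")[[1]]
    w_b <- strsplit(random_rna_str(w_len), "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    wob <- c(G = "U", U = "G")
    for (k in seq_len(nrow(pairs))) {
      b <- mi_b[pairs[k, 1]]
      # sprinkle admissible wobbles beyond the 8th pair
      w_b[pairs[k, 2]] <- if (k > 8L && b %in% names(wob) && runif(1) < 0.15)
        wob[[b]] else comp[[b]]
    }
    target <- paste(w_b, collapse = "")
    st <- tryCatch(duplex_structure(pairs, mirna, target), error = function(e) NULL)
    if (!is.null(st)) return(list(structure = st, mirna = mirna, target = target))
  }
}

# minimal scored zone for interval-level operations
fake_zone <- function(start, end, score = NA_real_, anchor = end,
                      utr_id = "u1", mirna_id = "m1", energy = -20) {
  mirna <- strrep("G", 8L)
  target <- strrep("C", 8L)
  st <- duplex_structure(cbind(1:2, 2:1), mirna, target, energy = energy)
  structure(list(utr_id = utr_id, mirna_id = mirna_id, start = start, end = end,
                 representative = st, representative_anchor = anchor,
                 seed = FALSE, score = score),
            class = "candidate_zone")
}

# a deliberately permissive calibrated model: single stump, thresholds 0
permissive_model <- function(feature = "compactness") {
  structure(list(
    stumps = data.frame(feature = feature, split = 0.5, left_class = 0L,
                        alpha = 1, stringsAsFactors = FALSE),
    n_iterations = 1L, subcommittee_bounds = integer(0),
    feature_set = model_feature_set(),
    thresholds = list(sens = 0, spec = 0),
    seed = 1L, params_version = "test"), class = "boosted_model")
}
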