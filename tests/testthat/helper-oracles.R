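# Independent brute-force oracles. These deliberately avoid the package's
# DP/search code paths: structures are enumerated recursively and scored by
# explicit term-by-term summation.

oracle_pair_ok <- function(a, b) paste0(a, b) %in% c("AU","UA","GC","CG","GU","UG")
oracle_is_gu <- function(a, b) paste0(a, b) %in% c("GU","UG")

# enumerate all admissible anchored structures (pairs lists) of mirna vs the
# window utr[max(1, anchor-span)..anchor], anchored at `anchor`; returns list
# of pair matrices (UTR coordinates)
oracle_enumerate <- function(mirna, utr, anchor, params) {
  mi <- strsplit(mirna, "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  M <- length(mi)
  L <- params$max_loop_side
  lo <- max(1L, anchor - (M + 15L))
  out <- list()
  emit <- function(pairs) {
    pr <- do.call(rbind, pairs)
    # helix lengths >= 2
    if (nrow(pr) < 2L) return()
    stacked <- diff(pr[, 1]) == 1L & diff(pr[, 2]) == -1L
    runs <- integer(0); cur <- 1L
    for (k in seq_along(stacked)) {
      if (stacked[k]) cur <- cur + 1L else { runs <- c(runs, cur); cur <- 1L }
    }
    if (min(c(runs, cur)) < 2L) return()
    # G:U rules
    gu <- mapply(oracle_is_gu, mi[pr[, 1]], ub[pr[, 2]])
    if (any(gu[seq_len(min(8L, length(gu)))])) return()
    if (sum(gu) >= 5L) return()
    out[[length(out) + 1L]] <<- pr
  }
  recurse <- function(pairs, last_i, last_j) {
    emit(pairs)
    for (i in (last_i + 1L):M) {
      if (i > M) break
      gi <- i - last_i - 1L
      if (gi > L) break
      for (j in (last_j - 1L):lo) {
        if (j < lo) break
        gj <- last_j - j - 1L
        if (gj > L) break
        if (!oracle_pair_ok(mi[i], ub[j])) next
        recurse(c(pairs, list(c(i, j))), i, j)
      }
    }
  }
  for (i0 in seq_len(M)) {
    if (!oracle_pair_ok(mi[i0], ub[anchor])) next
    recurse(list(c(i0, anchor)), i0, anchor)
  }
  out
}

# term-by-term rescoring, independent of score_structure's implementation
oracle_score <- function(pr, mirna, utr, params) {
  mi <- strsplit(mirna, "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  types <- paste0(mi[pr[, 1]], ub[pr[, 2]])
  e <- params$init
  n <- nrow(pr)
  if (n > 1L) for (k in 1:(n - 1L)) {
    gi <- pr[k + 1L, 1] - pr[k, 1] - 1L
    gj <- pr[k, 2] - pr[k + 1L, 2] - 1L
    if (gi == 0L && gj == 0L) e <- e + params$stack[types[k], types[k + 1L]]
    else if (gi == 0L || gj == 0L) e <- e + params$bulge[gi + gj]
    else e <- e + params$interior[gi + gj - 1L]
  }
  if (types[1] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal
  if (types[n] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal
  e
}

# minimum-energy admissible anchored structure by exhaustive enumeration;
# ties broken like the DP: fewer pairs
oracle_anchored_min <- function(mirna, utr, anchor, params) {
  structs <- oracle_enumerate(mirna, utr, anchor, params)
  if (length(structs) == 0L) return(NULL)
  es <- vapply(structs, oracle_score, numeric(1), mirna = mirna, utr = utr,
               params = params)
  np <- vapply(structs, nrow, integer(1))
  best <- order(es, np)[1]
  list(energy = es[best], pairs = structs[[best]],
       n_at_min = sum(abs(es - es[best]) < 1e-9))
}

random_rna_str <- function(n) paste(sample(c("A","C","G","U"), n, replace = TRUE),
                                    collapse = "")

# naive feature recount helpers -------------------------------------------

# recount pairing features directly from the paired-position sets
oracle_pairing <- function(pr, types, m_len) {
  mi <- pr[, 1]
  paired <- logical(m_len); paired[mi] <- TRUE
  cons <- 0L; gaps <- 0L
  for (p in seq(max(mi), 1L)) {
    if (paired[p]) cons <- cons + 1L
    else { gaps <- gaps + 1L; if (gaps > 2L) break }
  }
  longest <- 1L; cur <- 1L
  if (nrow(pr) > 1L) for (k in 1:(nrow(pr) - 1L)) {
    if (pr[k + 1L, 1] == pr[k, 1] + 1L && pr[k + 1L, 2] == pr[k, 2] - 1L) {
      cur <- cur + 1L; longest <- max(longest, cur)
    } else cur <- 1L
  }
  n5 <- sum(mi <= 8L); n3 <- sum(mi > m_len - 8L)
  c(seed8_pairings = sum(mi <= 8L), pairings_3prime_8 = n3,
    consecutive_3prime_2gap = cons, longest_stretch = longest,
    target_len = max(pr[, 2]) - min(pr[, 2]) + 1L,
    total_pairings = nrow(pr), gu_total = sum(types %in% c("GU", "UG")),
    binding_asymmetry = if (n5 == 0L) n3 + 1 else n3 / n5)
}

# gap-scanning bulge recount from explicit per-strand unpaired runs
oracle_bulges <- function(pr) {
  n <- nrow(pr)
  gi <- if (n > 1L) pr[-1, 1] - pr[-n, 1] - 1L else integer(0)
  gj <- if (n > 1L) pr[-n, 2] - pr[-1, 2] - 1L else integer(0)
  mib <- gi[gi > 0]; tb <- gj[gj > 0]
  sec <- function(v) if (length(v) < 2) 0 else sort(v, decreasing = TRUE)[2]
  out <- c(mi_bulge_count = length(mib), mi_bulge_total_len = sum(mib),
           mi_second_largest_bulge = sec(mib), t_bulge_count = length(tb),
           t_bulge_total_len = sum(tb), t_second_largest_bulge = sec(tb),
           t_bulge_mean_len = if (length(tb)) mean(tb) else 0,
           symmetric_bulges = sum(gi > 0 & gi == gj))
  for (k in 1:5) out[paste0("mi_bulges_len", k)] <- sum(mib == k)
  for (k in 1:6) out[paste0("t_bulges_len", k)] <- sum(tb == k)
  out["t_bulges_len7plus"] <- sum(tb >= 7)
  out
}

# generate a random admissible structure by sampling from the enumeration
# of a random small instance
random_structure_instance <- function(m_len = 8L, w_len = 14L) {
  repeat {
    mirna <- random_rna_str(m_len)
    utr <- random_rna_str(w_len)
    params <- energy_parameters()
    structs <- oracle_enumerate(mirna, utr, w_len, params)
    if (length(structs) > 0L) {
      pr <- structs[[sample.int(length(structs), 1L)]]
      return(list(mirna = mirna, utr = utr, pairs = pr))
    }
  }
}

# plain AdaBoost.M1 with decision stumps, written independently of
# train_multiboost (simple O(n^2) stump search)
oracle_adaboost <- function(x, y01, T) {
  x <- as.matrix(x)
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(x)
  w <- rep(1, n)
  stumps <- list()
  for (t in seq_len(T)) {
    best <- NULL
    for (f in seq_len(ncol(x))) {
      sv <- sort(unique(x[, f]))
      if (length(sv) < 2) next
      mids <- (sv[-1] + sv[-length(sv)]) / 2
      for (s in mids) {
        for (left in c(1, -1)) {
          pred <- ifelse(x[, f] <= s, left, -left)
          err <- sum(w[pred != y])
          if (is.null(best) || err < best$err - 1e-12) {
            best <- list(f = f, s = s, left = left, err = err)
          }
        }
      }
    }
    if (is.null(best)) break
    eps <- best$err / sum(w)
    if (eps >= 0.5) break
    if (eps == 0) { best$alpha <- log(1e10); stumps[[t]] <- best; break }
    best$alpha <- log((1 - eps) / eps)
    stumps[[t]] <- best
    pred <- ifelse(x[, best$f] <= best$s, best$left, -best$left)
    wrong <- pred != y
    w[wrong] <- w[wrong] / (2 * eps)
    w[!wrong] <- w[!wrong] / (2 * (1 - eps))
    w <- pmax(w, 1e-8)
  }
  stumps
}
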