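test_that("pairing features match closed forms on canonical duplexes", {
  set.seed(601)
  m <- random_rna_str(22)
  perfect <- duplex_structure(cbind(1:22, 22:1), m, reverse_complement(m))
  pf <- pairing_features(perfect, m)
  expect_equal(pf[["seed8_pairings"]], 8)
  expect_equal(pf[["pairings_3prime_8"]], 8)
  expect_equal(pf[["longest_stretch"]], 22)
  expect_equal(pf[["binding_asymmetry"]], 1)
  expect_equal(pf[["total_pairings"]], 22)
  expect_equal(pf[["target_len"]], 22)
  expect_equal(pf[["consecutive_3prime_2gap"]], 22)
  # pairing only microRNA positions 2-8
  m2 <- "AGGGGGGGAAAAAAAAAAAAAA"
  st <- duplex_structure(cbind(2:8, 7:1), m2, "CCCCCCC")
  pf2 <- pairing_features(st, m2)
  expect_equal(pf2[["seed8_pairings"]], 7)
  expect_equal(pf2[["pairings_3prime_8"]], 0)
  # 5' side empty: pseudocount ratio (n3 + 1) / 1
  st3 <- duplex_structure(cbind(15:19, 8:4), m, reverse_complement(m))
  expect_equal(pairing_features(st3, m)[["binding_asymmetry"]], 6)
})

test_that("pairing and bulge features equal a naive recount on random structures", {
  set.seed(602)
  for (k in 1:150) {
    inst <- random_admissible_structure(sample(15:22, 1), sample(20:32, 1))
    st <- inst$structure
    got_p <- pairing_features(st, inst$mirna)
    want_p <- oracle_pairing(st$pairs, st$pair_types, nchar(inst$mirna))
    expect_equal(got_p[names(want_p)], want_p, ignore_attr = TRUE)
    got_b <- bulge_features(st)
    want_b <- oracle_bulges(st$pairs)
    expect_equal(got_b[names(want_b)], want_b, ignore_attr = TRUE)
  }
})

test_that("bulge features on hand-built structures", {
  m <- "GGGGGGGG"
  perfect <- duplex_structure(cbind(1:8, 8:1), m, strrep("C", 8))
  bf <- bulge_features(perfect)
  expect_true(all(bf == 0))
  # one 3-nt bulge on the microRNA only
  m2 <- strrep("G", 10)
  st <- duplex_structure(rbind(cbind(1:3, 7:5), cbind(7:9, 4:2)), m2, strrep("C", 7))
  bf2 <- bulge_features(st)
  expect_equal(bf2[["mi_bulge_count"]], 1)
  expect_equal(bf2[["mi_bulges_len3"]], 1)
  expect_equal(bf2[["mi_bulge_total_len"]], 3)
  expect_equal(bf2[["t_bulge_count"]], 0)
  expect_equal(bf2[["symmetric_bulges"]], 0)
})

test_that("positional features follow the 100-bin and anchor-register rules", {
  set.seed(603)
  m <- random_rna_str(22)
  utr100 <- paste0(reverse_complement(m), random_rna_str(78))
  z <- list(representative_anchor = 1L,
            representative = duplex_structure(cbind(1:22, 22:1), m, utr100))
  class(z) <- "candidate_zone"
  expect_equal(positional_features(z, utr100, m)[["utr_position_bin"]], 1)
  z$representative_anchor <- 100L
  expect_equal(positional_features(z, utr100, m)[["utr_position_bin"]], 100)
  # closed form: anchor 473 in a 1210-nt UTR falls in bin 40
  z$representative_anchor <- 473L
  utr1210 <- strrep("A", 1210)
  zz <- list(representative_anchor = 473L,
             representative = duplex_structure(cbind(1:2, 473:472), strrep("U", 8),
                                               utr1210))
  class(zz) <- "candidate_zone"
  expect_equal(positional_features(zz, utr1210, m)[["utr_position_bin"]], 40)
})

test_that("t1/t9 anchor nucleotides are read along the pairing register", {
  m <- "GGGGGGGGGGGG"  # 12 nt
  utr <- paste0("AAAA", strrep("C", 12), "AAAA")  # site at 5..16
  z <- list(representative_anchor = 16L,
            representative = duplex_structure(cbind(1:12, 16:5), m, utr))
  class(z) <- "candidate_zone"
  pf <- positional_features(z, utr, m)
  expect_equal(pf[["t1_anchor"]], 2)   # C
  expect_equal(pf[["t9_anchor"]], 2)   # C
  expect_equal(pf[["t1_sw_anchor"]], 0)
  expect_equal(pf[["t9_sw_anchor"]], 0)
  # position 9 unpaired: register interpolated from the nearest 5'-side pair
  utr2 <- paste0("AAAA", "CCCC", "AAA", "G", "AA", "CCCCCC", "AAAA")  # 24 nt
  m2 <- strrep("G", 16)
  pr <- rbind(cbind(1:6, 20:15), cbind(11:14, 8:5))
  z2 <- list(representative_anchor = 20L,
             representative = duplex_structure(pr, m2, utr2))
  class(z2) <- "candidate_zone"
  pf2 <- positional_features(z2, utr2, m2)
  # register from pair (6, 15): t(9) = 15 - 3 = 12 -> base "G"
  expect_equal(pf2[["t9_anchor"]], 3)
  expect_equal(pf2[["t9_sw_anchor"]], 0)
})

test_that("compositional features equal direct character counting", {
  set.seed(604)
  for (k in 1:30) {
    m <- random_rna_str(12)
    utr <- random_rna_str(160)
    a <- sample(60:100, 1)
    z <- list(representative_anchor = a,
              representative = duplex_structure(cbind(1:2, a:(a - 1)), strrep("U", 12),
                                                strrep("A", 160), validate = FALSE))
    class(z) <- "candidate_zone"
    cf <- compositional_features(z, utr, m)
    site <- substr(utr, a - 1, a)
    up50 <- substr(utr, a - 51, a - 2)
    dn50 <- substr(utr, a + 1, a + 50)
    up20 <- substr(utr, a - 21, a - 2)
    cnt <- function(s, what) sum(strsplit(s, "")[[1]] %in% what) / nchar(s)
    expect_equal(cf[["gc_target"]], cnt(site, c("G", "C")))
    expect_equal(cf[["gc_upstream50"]], cnt(up50, c("G", "C")))
    expect_equal(cf[["gc_downstream50"]], cnt(dn50, c("G", "C")))
    expect_equal(cf[["gc_diff_site_flank"]], cnt(site, c("G", "C")) - cnt(up20, c("G", "C")))
    ndi <- function(s) length(grep("CG", substring(s, 1:(nchar(s) - 1), 2:nchar(s)), fixed = TRUE))
    expect_equal(cf[["cpg_upstream"]], ndi(up20))
    expect_equal(cf[["cpg_downstream"]], ndi(substr(utr, a + 1, a + 20)))
  }
})

test_that("compositional edge cases: pure GC and pure AU sites", {
  utr <- paste0(strrep("A", 20), "GCGCGCGC", strrep("A", 20))
  z <- list(representative_anchor = 28L,
            representative = duplex_structure(cbind(1:8, 28:21), strrep("U", 8),
                                              strrep("A", 48), validate = FALSE))
  class(z) <- "candidate_zone"
  cf <- compositional_features(z, utr, "GCGCGCGC")
  expect_equal(cf[["gc_target"]], 1)
  # CpG = C followed by G in 5'->3'; GCGCGCGC carries three of them
  expect_equal(cf[["cpg_target"]], 3)
  expect_equal(compositional_features(z, paste0(strrep("A", 20), "CGCGCGCG",
                                                strrep("A", 20)),
                                      "GCGCGCGC")[["cpg_target"]], 4)
  utr2 <- paste0(strrep("G", 20), "AUAUAUAU", strrep("G", 20))
  cf2 <- compositional_features(z, utr2, "GCGCGCGC")
  expect_equal(cf2[["gc_target"]], 0)
  expect_equal(cf2[["cpg_target"]], 0)
  expect_true(is.finite(cf2[["gc_ratio_mirna_target"]]))
})

test_that("compactness follows its defining arithmetic", {
  m22 <- random_rna_str(22)
  perfect <- duplex_structure(cbind(1:22, 22:1), m22, reverse_complement(m22))
  expect_equal(compactness(perfect, m22), 1)
  expect_equal(compactness(NULL, m22), 0)
  # 22-nt microRNA, 30-nt footprint, 15 pairs
  pr <- rbind(cbind(1:8, 30:23), cbind(16:22, 7:1))
  st <- structure(list(pairs = pr), class = "duplex_structure")
  expect_equal(compactness(st, m22), 0.5 * (15 / 22 + 15 / 30))
  # monotone non-decreasing in the number of pairs at fixed lengths
  prev <- -Inf
  for (np in 2:22) {
    p <- cbind(seq_len(np), seq(30, by = -1, length.out = np))
    p[np, 2] <- 1  # force a 30-nt footprint
    v <- compactness(structure(list(pairs = p), class = "duplex_structure"), m22)
    expect_gte(v, prev); prev <- v
  }
  # penalty branch: site shorter than the microRNA, continuous at equality
  mk <- function(ts_len, np) {
    structure(list(pairs = cbind(seq_len(np), seq(ts_len, ts_len - np + 1))),
              class = "duplex_structure")
  }
  expect_equal(compactness(mk(22, 22), m22), 1)
  v21 <- compactness(mk(21, 21), m22)
  expect_lt(v21, 1)
  expect_gt(v21, 0.8)
  for (ts in c(5, 10, 15, 21)) {
    v <- compactness(mk(ts, ts), m22)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("compactness stays in [0, 1] over random structures", {
  set.seed(605)
  for (k in 1:300) {
    inst <- random_admissible_structure(sample(12:22, 1), sample(14:34, 1))
    v <- compactness(inst$structure, inst$mirna)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("extract_features returns the requested catalogue deterministically", {
  set.seed(606)
  m <- random_rna_str(22)
  utr <- paste0(random_rna_str(60), reverse_complement(m), random_rna_str(60))
  prof <- build_profile(m, utr)
  z <- call_zones(prof)[[1]]
  full <- extract_features(z, utr, m)
  expect_length(full, 43)
  expect_identical(names(full), feature_catalogue())
  expect_false(anyNA(full))
  expect_equal(full[["compactness"]], 1)
  expect_equal(full[["seed8_pairings"]], 8)
  seven <- extract_features(z, utr, m, set = model_feature_set())
  expect_identical(names(seven), model_feature_set())
  expect_identical(extract_features(z, utr, m), full)
  expect_error(extract_features(z, utr, m, set = "no_such_feature"), "unknown feature")
  expect_error(extract_features(z, utr, m, set = "accessibility_3_15"), "unknown feature")
})

test_that("gc features are invariant under U/T input encoding", {
  set.seed(607)
  m <- random_rna_str(22)
  utr <- paste0(random_rna_str(50), reverse_complement(m), random_rna_str(50))
  utr_t <- chartr("U", "T", tolower(utr))
  prof <- build_profile(m, utr)
  z <- call_zones(prof)[[1]]
  f1 <- extract_features(z, utr, m)
  f2 <- extract_features(z, utr_t, m)
  expect_identical(f1, f2)
})

test_that("the accessibility hook exposes optional features", {
  on.exit(accessibility_hook(NULL))
  accessibility_hook(function(zone, utr, mirna) c(accessibility_3_15 = -1.5,
                                                  accessibility_30_30 = -2.5))
  set.seed(608)
  m <- random_rna_str(22)
  utr <- paste0(random_rna_str(30), reverse_complement(m), random_rna_str(30))
  z <- call_zones(build_profile(m, utr))[[1]]
  v <- extract_features(z, utr, m, set = c("compactness", "accessibility_3_15"))
  expect_equal(v[["accessibility_3_15"]], -1.5)
})
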