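test_that("decoy generation reverses sequences and drops collisions", {
  expect_equal(generate_decoys("ACDEFK"), "KFEDCA")
  expect_length(generate_decoys("ACA"), 0L)          # palindrome
  seqs <- c("ACDEFK", "KFEDCA", "GHIKLM")            # mutual reversals collide
  d <- generate_decoys(seqs)
  expect_false(any(d %in% seqs))
  expect_lte(length(d), length(seqs))
})

test_that("the search database enumerates forms, charges and decoys sorted by m/z", {
  db <- build_search_db(c("ACDEFGHIK", "ACDMFGHIK"))
  expect_true(all(diff(db$mz) >= 0))
  expect_true(any(db$is_decoy))
  expect_equal(sum(!db$is_decoy), 3L + 6L)   # 1 + 2 forms, 3 charges each
})

test_that("a narrow non-chimeric search sees only isolated-mass candidates", {
  w <- tiny_world(n_bg = 10L, n_spike = 3L)
  pep <- w$mix[1, ]
  pl <- self_spectrum(peptidoform(pep$sequence, charge = 2L))
  db <- build_search_db(w$mix$sequence)
  feats <- data.frame(mz = precursor_mz(w$mix$neutral_mass[2], 2), z = 2L,
                      intensity = 1e4)
  cfg_off <- search_config(chimeric = FALSE)
  psms <- search_scan(pl, precursor_mz(pep$neutral_mass, 2), 2L, 1.2,
                      db, feats, cfg_off)
  expect_true(all(psms$isolation_status == "isolated"))
  best <- psms[!psms$is_decoy, ][which.max(psms$hyperscore[!psms$is_decoy]), ]
  expect_equal(best$sequence, pep$sequence)
})

test_that("chimeric search identifies two co-isolated precursors from one scan", {
  w <- tiny_world(n_bg = 10L, n_spike = 3L)
  p1 <- peptidoform(w$mix$sequence[1], charge = 2L)
  p2 <- peptidoform(w$mix$sequence[2], charge = 2L)
  mz1 <- precursor_mz(monoisotopic_mass(p1), 2)
  mz2 <- precursor_mz(monoisotopic_mass(p2), 2)
  # merge two self-spectra into one chimeric spectrum
  f1 <- fragment_mzs(p1, 1L); f2 <- fragment_mzs(p2, 1L)
  pl <- peaklist(c(f1$mz, f2$mz), rep(100, nrow(f1) + nrow(f2)),
                 precursor_mz = mz1, precursor_charge = 2L)
  db <- build_search_db(w$mix$sequence)
  feats <- data.frame(mz = c(mz1, mz2), z = 2L, intensity = c(1e4, 1e4))
  psms <- search_scan(pl, mz1, 2L, 2 * abs(mz1 - mz2) + 1, db, feats,
                      search_config(chimeric = TRUE))
  got <- psms$sequence[!psms$is_decoy]
  expect_true(p1$sequence %in% got)
  expect_true(p2$sequence %in% got)
  expect_true("co_isolated" %in% psms$isolation_status)
})

test_that("a noise-only spectrum produces no confident candidates", {
  set.seed(31)
  db <- build_search_db(generate_peptidome(30, seed = 9)$sequence)
  pl <- peaklist(runif(30, 100, 1500), rep(3, 30),
                 precursor_mz = 500.25, precursor_charge = 2L)
  psms <- search_scan(pl, 500.25, 2L, 1.2, db, NULL, search_config())
  expect_true(is.null(psms) || all(psms$n_b + psms$n_y <= 2))
})

test_that("the FDR estimator matches its worked examples and a brute-force oracle", {
  # 99 targets above one decoy: nothing reaches 1%
  psms <- data.frame(hyperscore = c(seq(100, 2, length.out = 99), 1),
                     is_decoy = c(rep(FALSE, 99), TRUE),
                     sequence = paste0("P", 1:100))
  expect_equal(nrow(fdr_filter(psms, 0.01)), 0L)
  # 100 decoy-free targets: all pass at exactly (0+1)/100
  psms2 <- data.frame(hyperscore = seq(100, 1, length.out = 100),
                      is_decoy = FALSE, sequence = paste0("P", 1:100))
  expect_equal(nrow(fdr_filter(psms2, 0.01)), 100L)
  expect_equal(unique(fdr_filter(psms2, 0.01)$q_value), 0.01)
  # empty input
  expect_equal(nrow(fdr_filter(data.frame(hyperscore = numeric(),
                                          is_decoy = logical()), 0.01)), 0L)
  # brute-force oracle on random score configurations
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    sim <- data.frame(hyperscore = round(runif(n, 0, 50), 2),
                      is_decoy = runif(n) < 0.3,
                      sequence = paste0("S", seq_len(n)))
    level <- sample(c(0.01, 0.05, 0.2), 1)
    got <- fdr_filter(sim, level)
    # oracle: for every target PSM, q = min over thresholds at-or-below its
    # score of (D(t)+1)/T(t); accept if q <= level
    o <- order(-sim$hyperscore, !sim$is_decoy)
    s <- sim[o, ]
    fdr <- (cumsum(s$is_decoy) + 1) / pmax(cumsum(!s$is_decoy), 1)
    q <- vapply(seq_len(n), function(i) min(fdr[i:n]), numeric(1))
    want <- s$sequence[!s$is_decoy & q <= level]
    expect_setequal(got$sequence, want)
  }
})

test_that("peptide-level FDR collapses to the best PSM per stripped sequence", {
  psms <- data.frame(
    hyperscore = c(seq(50, 31, length.out = 20), seq(50, 31, length.out = 20) - 5, 1),
    is_decoy = c(rep(FALSE, 40), TRUE),
    sequence = c(paste0("P", 1:20), paste0("P", 1:20), "DDD"))
  out <- peptide_fdr(psms, 0.5)
  expect_equal(nrow(out), 20L)                         # collapsed per sequence
  expect_equal(sort(out$hyperscore), sort(seq(50, 31, length.out = 20)))
})

test_that("TIDs require an RTS hit plus an accepted PSM on the event's own scans", {
  log <- list(events = data.frame(
    event_id = 1:3, sequence = c("AAA", "BBB", "CCC"), hit = c(TRUE, TRUE, FALSE),
    sms2_scan_id = c(10L, 20L, 30L), hms2_scan_id = c(11L, NA, NA)))
  accepted <- data.frame(scan_id = c(10L, 11L, 30L, 99L),
                         sequence = c("AAA", "AAA", "CCC", "BBB"))
  tids <- classify_tids(log, accepted, c("AAA", "BBB", "CCC"))
  expect_equal(nrow(tids), 1L)
  expect_equal(tids$sequence, "AAA")
  expect_equal(tids$support, "sMS2+hMS2")
  # discovery-branch PSM of BBB (scan 99) and the non-hit CCC event yield none
  expect_false("BBB" %in% tids$sequence)
  expect_false("CCC" %in% tids$sequence)
})

test_that("mass-difference analysis reports integer-Da residuals for known pairs", {
  # Gly -> Ala substitution: delta = 14.01565, nearest multiple 14
  mA <- monoisotopic_mass("GCDEFHIK"); mB <- monoisotopic_mass("ACDEFHIK")
  acc <- data.frame(scan_id = c(1L, 1L), z = c(2L, 2L),
                    neutral_mass = c(mA, mB), sequence = c("GCDEFHIK", "ACDEFHIK"))
  md <- mass_diff_analysis(acc)
  expect_equal(md$residuals$nearest_da, 14)
  expect_equal(md$residuals$residual, 0.01565, tolerance = 1e-5)
  expect_equal(md$same_charge_fraction, 1)
  # identical masses -> residual 0; charge-mismatched pairs are excluded
  acc2 <- data.frame(scan_id = c(2L, 2L, 2L), z = c(2L, 2L, 3L),
                     neutral_mass = c(mA, mA, mB),
                     sequence = c("X", "Y", "Z"))
  md2 <- mass_diff_analysis(acc2)
  expect_equal(md2$residuals$residual, 0)
  expect_equal(md2$same_charge_fraction, 1 / 3)
  expect_equal(nrow(mass_diff_analysis(acc[0, , drop = FALSE])$residuals), 0L)
})

test_that("noise-only scan logs yield zero accepted PSMs at 1% FDR", {
  set.seed(19)
  db <- build_search_db(generate_peptidome(50, seed = 23)$sequence)
  rows <- list()
  for (i in 1:50) {
    pl <- peaklist(runif(40, 100, 1500), 1 + rpois(40, 2),
                   precursor_mz = runif(1, 300, 900), precursor_charge = 2L)
    psms <- search_scan(pl, pl$precursor_mz, 2L, 3.2, db, NULL, search_config())
    if (!is.null(psms)) rows[[length(rows) + 1L]] <- psms
  }
  all_psms <- do.call(rbind, rows)
  if (is.null(all_psms))
    all_psms <- data.frame(hyperscore = numeric(), is_decoy = logical())
  expect_equal(nrow(fdr_filter(all_psms, 0.01)), 0L)
})
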