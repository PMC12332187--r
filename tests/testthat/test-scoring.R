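test_that("binning square-roots intensities and keeps the max per bin", {
  pl <- peaklist(c(100.0, 100.3), c(49, 16))
  bs <- bin_spectrum(pl)
  idx <- as.integer(round(100.0 / 1.0005079)) + 1L
  expect_equal(bs$values[idx], 7)           # sqrt(49) beats sqrt(16)
  expect_equal(sum(bs$values > 0), 1L)      # both peaks share the bin
  expect_error(bin_spectrum(peaklist(numeric(), numeric())), "empty")
})

test_that("preprocessing subtracts the regional background as specified", {
  # flat nonzero spectrum -> exactly zero after mean subtraction away from edges
  n <- as.integer(round(2500 / 1.0005079)) + 1L
  pl <- peaklist(seq(0.5, 2400, by = 1.0005079), rep(4, 2399))
  bs <- xcorr_preprocess(bin_spectrum(pl))
  mid <- 200:2000
  expect_lt(max(abs(bs$values[mid])), 1e-9)
  # single isolated bin of normalized height 50: 50 - 50/151
  pl2 <- peaklist(1000.5, 25)
  bs2 <- xcorr_preprocess(bin_spectrum(pl2))
  expect_equal(max(bs2$values), 50 - 50 / 151, tolerance = 1e-9)
  # all-zero spectrum stays all-zero
  pl3 <- peaklist(1000.5, 0)
  expect_equal(max(abs(xcorr_preprocess(bin_spectrum(pl3))$values)), 0)
})

test_that("fast cross-correlation equals the direct offset-correlation oracle", {
  # oracle: R(0) - mean over tau of R(tau), computed by explicit shifting
  # of the regionally normalized spectrum
  direct_xcorr <- function(p, bs_norm) {
    tp <- theoretical_peaks(p, bs_norm$bin_width, bs_norm$max_mz, 1L)
    y <- bs_norm$values
    n <- length(y)
    r_tau <- vapply(-75:75, function(tau) {
      j <- tp$idx + tau
      ok <- j >= 1L & j <= n
      sum(tp$val[ok] * y[j[ok]])
    }, numeric(1))
    (r_tau[76] - mean(r_tau)) / 1e4
  }
  aa <- names(residue_masses())
  set.seed(42)
  worst <- 0
  for (i in 1:60) {
    seq <- paste(sample(aa, sample(8:12, 1), replace = TRUE), collapse = "")
    p <- peptidoform(seq, charge = sample(1:3, 1))
    pl <- peaklist(runif(40, 100, 1800), rexp(40, 1 / 50))
    bs_norm <- region_normalize(bin_spectrum(pl))
    bs_pre <- xcorr_preprocess(bin_spectrum(pl))
    worst <- max(worst, abs(xcorr(p, bs_pre) - direct_xcorr(p, bs_norm)))
  }
  expect_lt(worst, 1e-9)
})

test_that("self-match dominates shuffled decoys on a noise-free spectrum", {
  set.seed(7)
  p <- peptidoform("SVHELAGKQW", charge = 2L)
  pl <- self_spectrum(p)
  bs <- xcorr_preprocess(bin_spectrum(pl))
  self_x <- xcorr(p, bs)
  self_h <- {
    mf <- match_fragments(pl, fragment_mzs(p, 1L))
    hyperscore(mf$n_b, mf$n_y, mf$sum_I_b, mf$sum_I_y)
  }
  self_a <- spectral_angle(pl, p)
  expect_equal(self_a, 1.0, tolerance = 1e-12)
  chars <- strsplit(p$sequence, "")[[1L]]
  for (i in 1:100) {
    d <- peptidoform(paste(sample(chars), collapse = ""), charge = 2L)
    if (d$sequence == p$sequence) next
    expect_lt(xcorr(d, bs), self_x)
    mf <- match_fragments(pl, fragment_mzs(d, 1L))
    expect_lte(hyperscore(mf$n_b, mf$n_y, mf$sum_I_b, mf$sum_I_y), self_h)
    expect_lte(spectral_angle(pl, d), self_a)
  }
})

test_that("xcorr and spectral angle are invariant under global intensity scaling", {
  set.seed(8)
  p <- peptidoform("ACDEFGHIK", charge = 2L)
  mz <- c(fragment_mzs(p, 1L)$mz[1:6], runif(20, 100, 1500))
  int <- rexp(26, 1 / 100)
  ref_pl <- peaklist(mz, int)
  x0 <- xcorr(p, xcorr_preprocess(bin_spectrum(ref_pl)))
  a0 <- spectral_angle(ref_pl, p)
  for (c_scale in c(0.01, 250)) {
    pl <- peaklist(mz, int * c_scale)
    bs <- xcorr_preprocess(bin_spectrum(pl))
    expect_equal(xcorr(p, bs), x0, tolerance = 1e-12)
    expect_equal(spectral_angle(pl, p), a0, tolerance = 1e-12)
  }
})

test_that("dCn follows the best-to-runner-up convention", {
  expect_equal(delta_cn(c(2, 1)), 0.5)
  expect_equal(delta_cn(c(1, 2)), 0.5)   # order-free
  expect_equal(delta_cn(2), 1.0)
  expect_equal(delta_cn(c(-1, -2)), 0.0)
  expect_error(delta_cn(numeric()), "candidate")
})

test_that("ppm error is signed and exact", {
  expect_equal(delta_ppm(500, 500), 0)
  expect_equal(delta_ppm(500.0025, 500), 5, tolerance = 1e-9)
  expect_equal(delta_ppm(499.9975, 500), -5, tolerance = 1e-9)
  expect_error(delta_ppm(500, 0), "domain")
})

test_that("fragment matching uses a closed tolerance interval with nearest-peak ties", {
  p <- peptidoform("ACDEFGHIK", charge = 1L)
  fr <- fragment_mzs(p, 1L)
  # peak exactly tol_ppm away is matched
  shift <- fr$mz[1] * 20e-6
  pl <- peaklist(fr$mz[1] + shift, 10)
  mf <- match_fragments(pl, fr[1, , drop = FALSE], tol_ppm = 20)
  expect_true(mf$matches$matched[1])
  # just beyond is not
  pl2 <- peaklist(fr$mz[1] + shift * 1.01, 10)
  mf2 <- match_fragments(pl2, fr[1, , drop = FALSE], tol_ppm = 20)
  expect_false(mf2$matches$matched[1])
  # exact distance tie prefers the lower-m/z peak
  d <- fr$mz[1] * 5e-6
  pl3 <- peaklist(c(fr$mz[1] - d, fr$mz[1] + d), c(1, 2))
  mf3 <- match_fragments(pl3, fr[1, , drop = FALSE], tol_ppm = 20)
  expect_equal(mf3$matches$peak_intensity[1], 1)
  # noise-free self-spectrum: everything matches; empty list: nothing
  pl4 <- self_spectrum(p)
  expect_equal(match_fragments(pl4, fr)$n_b + match_fragments(pl4, fr)$n_y,
               nrow(fr))
  expect_equal(match_fragments(peaklist(numeric(), numeric()), fr)$n_b, 0L)
})

test_that("hyperscore follows the capped factorial formula", {
  expect_equal(hyperscore(2, 2, 100, 100), log(40000), tolerance = 1e-9)
  expect_equal(hyperscore(0, 0, 0, 0), 0)
  expect_equal(hyperscore(1, 0, 10, 0), log(10), tolerance = 1e-9)
  expect_equal(hyperscore(70, 0, 1, 1), lfactorial(64), tolerance = 1e-9)
  expect_error(hyperscore(-1, 0, 0, 0), "domain")
})

test_that("spectral angle hits its boundary cases", {
  p <- peptidoform("ACDEFGHIK", charge = 1L)
  expect_equal(spectral_angle(self_spectrum(p), p), 1.0, tolerance = 1e-12)
  expect_equal(spectral_angle(peaklist(numeric(), numeric()), p), 0)
  far <- peaklist(c(1900, 1950), c(5, 5))
  expect_equal(spectral_angle(far, p), 0)
})

test_that("the real-time-search filter is monotone in its thresholds", {
  base <- rts_filter_config()
  s_pass <- list(xcorr = 0.5, dcn = 0.1, delta_ppm = 2, charge = 2L)
  expect_true(rtsf_pass(s_pass, base))
  expect_false(rtsf_pass(list(xcorr = 0.3, dcn = 0.5, delta_ppm = 1, charge = 2L), base))
  expect_false(rtsf_pass(list(xcorr = 0.8, dcn = 0.2, delta_ppm = 6, charge = 2L), base))
  set.seed(9)
  for (i in 1:200) {
    s <- list(xcorr = runif(1, 0, 2), dcn = runif(1), delta_ppm = runif(1, -8, 8),
              charge = sample(1:4, 1))
    lo <- rts_filter_config(xcorr_min = runif(1, 0, 0.5), dcn_min = runif(1, 0, 0.2),
                            ppm_max = runif(1, 3, 8))
    hi <- rts_filter_config(xcorr_min = lo$xcorr_min + runif(1, 0, 1),
                            dcn_min = lo$dcn_min + runif(1, 0, 0.5),
                            ppm_max = lo$ppm_max - runif(1, 0, lo$ppm_max))
    if (rtsf_pass(s, hi)) expect_true(rtsf_pass(s, lo))
  }
})
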