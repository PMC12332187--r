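test_that("peptidome generation is deterministic, unique, and length-shaped", {
  a <- generate_peptidome(100, seed = 5)
  b <- generate_peptidome(100, seed = 5)
  expect_identical(a, b)
  expect_false(anyDuplicated(a$sequence) > 0)
  big <- generate_peptidome(10000, seed = 6)
  tab <- table(big$length)
  expect_equal(as.integer(names(which.max(tab))), 9L)
  expect_true(all(big$length >= 8 & big$length <= 14))
  expect_equal(rowSums(cbind(big$p_z1, big$p_z2, big$p_z3)), rep(1, 10000))
})

test_that("dilution series scales the spike and keeps the background fixed", {
  bg <- generate_peptidome(50, seed = 1)
  sp <- generate_peptidome(10, seed = 2, source = "spike")
  ser <- make_dilution_series(bg, sp, c(1/16, 1/1024, 0))
  m16 <- ser[["1/16"]]; m1024 <- ser[["1/1024"]]; neg <- ser[["0"]]
  expect_equal(sum(neg$source == "spike"), 0L)
  for (m in ser) {
    bgpart <- m[m$source == "background", ]
    expect_equal(bgpart$abundance, bg$abundance)
  }
  r <- m16$abundance[m16$is_target] / m1024$abundance[m1024$is_target]
  expect_equal(r, rep(64, sum(m16$is_target)))
  expect_error(make_dilution_series(bg, sp, -0.1), "domain")
  # collisions dropped with warning
  sp2 <- sp; sp2$sequence[1] <- bg$sequence[1]
  expect_warning(make_dilution_series(bg, sp2, 1/16), "collide")
})

test_that("MS1 observation follows the elution model and the noise floor", {
  w <- tiny_world()
  pep <- w$mix[1, ]
  at_apex <- ms1_observe(w$mix, pep$rt_apex, w$model, seed = 3)
  f <- at_apex[at_apex$sequence == pep$sequence, ]
  expect_gt(nrow(f), 0)
  far <- ms1_observe(w$mix, pep$rt_apex + 10 * pep$rt_sigma, w$model, seed = 3)
  expect_false(pep$sequence %in% far$sequence)
  # deterministic given seed and t
  expect_identical(at_apex, ms1_observe(w$mix, pep$rt_apex, w$model, seed = 3))
  # intensity at apex is the elution maximum
  off <- ms1_observe(w$mix, pep$rt_apex + 2 * pep$rt_sigma, w$model, seed = 3)
  fo <- off[off$sequence == pep$sequence & off$z == f$z[1], ]
  if (nrow(fo)) expect_lt(fo$intensity, f$intensity[f$z == f$z[1]])
})

test_that("elution conservation: integrated MS1 intensity tracks abundance", {
  w <- tiny_world()
  grid <- seq(0, w$gradient_min, by = 0.005)
  mix <- w$mix[1:4, ]
  mix$p_z2 <- 1; mix$p_z1 <- 0; mix$p_z3 <- 0   # single charge for clarity
  mix$rt_apex <- seq(0.4, 0.6, length.out = 4)  # keep elution off the edges
  attr(mix, "gradient_min") <- w$gradient_min
  model <- w$model
  model$ms1_noise_floor <- 1e-6  # negligible tail truncation for this check
  totals <- numeric(4)
  for (t in grid) {
    f <- ms1_observe(mix, t, model, seed = 11)
    idx <- match(f$sequence, mix$sequence)
    totals[idx] <- totals[idx] + f$intensity
  }
  # integral ~ abundance * sigma * sqrt(2*pi) / dt; compare as ratios
  ratio <- totals / mix$abundance
  expect_lt(max(abs(ratio - mean(ratio)) / mean(ratio)), 0.01)
})

test_that("MS2 simulation is deterministic, chimeric, and ion-budgeted", {
  w <- tiny_world()
  sp <- default_scan_params()
  pep <- w$mix[3, ]
  ctr <- precursor_mz(pep$neutral_mass, 2)
  a <- simulate_ms2(ctr, 1.2, w$mix, pep$rt_apex, sp$sMS2, w$model, seed = 4)
  b <- simulate_ms2(ctr, 1.2, w$mix, pep$rt_apex, sp$sMS2, w$model, seed = 4)
  expect_identical(a, b)

  # hMS2 collects more ions than sMS2 for the same low-abundance precursor
  lowmix <- w$mix; lowmix$abundance <- lowmix$abundance / 1024
  attr(lowmix, "gradient_min") <- w$gradient_min
  tot_s <- tot_h <- numeric(60)
  for (i in 1:60) {
    s <- simulate_ms2(ctr, 1.2, lowmix, pep$rt_apex, sp$sMS2, w$model, seed = i)
    h <- simulate_ms2(ctr, 1.2, lowmix, pep$rt_apex, sp$hMS2, w$model, seed = i + 1000)
    tot_s[i] <- sum(s$intensity); tot_h[i] <- sum(h$intensity)
  }
  expect_gt(median(tot_h), median(tot_s))

  # two precursors in a wide window yield a chimeric spectrum
  m2 <- w$mix[1:2, ]
  m2$rt_apex <- 0.5; m2$p_z2 <- 1; m2$p_z1 <- 0; m2$p_z3 <- 0
  m2$neutral_mass[2] <- m2$neutral_mass[1] + 2  # 1 Th apart at 2+
  attr(m2, "gradient_min") <- w$gradient_min
  ctr2 <- precursor_mz(m2$neutral_mass[1], 2) + 0.5
  model0 <- w$model; model0$ms2_chemical_noise_peaks <- 0
  pl <- simulate_ms2(ctr2, 3.2, m2, 0.5, sp$dMS2, model0, seed = 8)
  fr1 <- fragment_mzs(peptidoform(m2$sequence[1], charge = 1L), 1L)
  fr2 <- fragment_mzs(peptidoform(m2$sequence[2], charge = 1L), 1L)
  m_1 <- match_fragments(pl, fr1, 25)
  m_2 <- match_fragments(pl, fr2, 25)
  expect_gt(m_1$n_b + m_1$n_y, 3)
  expect_gt(m_2$n_b + m_2$n_y, 3)
})

test_that("hMS2 xcorr beats sMS2 xcorr on a low-abundance precursor (median over seeds)", {
  w <- tiny_world()
  sp <- default_scan_params()
  pep <- w$mix[5, ]
  lowmix <- w$mix; lowmix$abundance <- pmin(lowmix$abundance, 2e3)
  attr(lowmix, "gradient_min") <- w$gradient_min
  ctr <- precursor_mz(pep$neutral_mass, 2)
  p <- peptidoform(pep$sequence, charge = 2L)
  xs <- xh <- numeric(200)
  for (i in 1:200) {
    s <- simulate_ms2(ctr, 1.2, lowmix, pep$rt_apex, sp$sMS2, w$model, seed = 2 * i)
    h <- simulate_ms2(ctr, 1.2, lowmix, pep$rt_apex, sp$hMS2, w$model, seed = 2 * i + 1)
    xs[i] <- if (length(s$mz)) xcorr(p, xcorr_preprocess(bin_spectrum(s))) else 0
    xh[i] <- if (length(h$mz)) xcorr(p, xcorr_preprocess(bin_spectrum(h))) else 0
  }
  expect_gt(median(xh), median(xs))
})

test_that("interferents are exact isobars, never targets, and optional", {
  w <- tiny_world()
  expect_identical(spike_interferents(w$mix, w$sil, per_target = 0), w$mix)
  mix2 <- spike_interferents(w$mix, w$sil, per_target = 1, seed = 9)
  intf <- mix2[mix2$source == "interferent", ]
  expect_gt(nrow(intf), 0)
  expect_false(any(intf$is_target))
  expect_false(any(intf$sequence %in% w$sil$sequence))
  # each interferent is within tolerance of some unmodified entry
  entries <- w$sil[w$sil$mods == "", ]
  for (i in seq_len(nrow(intf))) {
    best <- min(abs(delta_ppm(precursor_mz(intf$neutral_mass[i], entries$z),
                              entries$mz)))
    expect_lte(best, 10)
  }
})
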