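test_that("method configuration validates and sets per-method caps", {
  expect_equal(method_config("NeoDiscMS")$precursor_cap, 3L)
  expect_equal(method_config("ilDDA")$precursor_cap, 2L)
  expect_equal(method_config("DDA")$precursor_cap, 1L)
  expect_error(method_config("DDA", cycle_ms = 50), "config")
  expect_error(method_config("DDA", precursor_cap = 0), "config")
  expect_error(method_config("DDA", dda_isolation_width = 0), "config")
  expect_error(run_acquisition(data.frame(), cfg = list()), "config")
})

test_that("an empty sample yields an MS1-only scan log", {
  empty <- generate_peptidome(1, seed = 1, gradient_min = 1, rt_margin = 0.1)
  empty$abundance <- 1e-9   # below any floor
  attr(empty, "gradient_min") <- 0.3
  log <- run_acquisition(empty, cfg = method_config("DDA"),
                         model = signal_model(gradient_min = 0.3), seed = 1)
  expect_true(all(log$scans$scan_type == "MS1"))
  expect_equal(nrow(log$events), 0L)
})

test_that("cycle time is conserved and no scan crosses a cycle boundary", {
  w <- tiny_world()
  for (method in c("DDA", "ilDDA", "NeoDiscMS")) {
    cfg <- method_config(method)
    log <- run_acquisition(w$mix, w$sil, cfg, w$model, seed = 21)
    rep <- cycle_budget_report(log)
    expect_true(all(abs(rep$ms1_ms + rep$targeted_ms + rep$discovery_ms +
                          rep$idle_ms - cfg$cycle_ms) < 1e-9))
    expect_true(all(rep$idle_ms >= 0))
    ends <- log$scans$start_ms + log$scans$duration_ms
    expect_true(all(ends <= log$scans$cycle * cfg$cycle_ms + 1e-9))
    expect_true(all(log$scans$start_ms >= (log$scans$cycle - 1) * cfg$cycle_ms))
  }
})

test_that("acquisition is deterministic under a master seed", {
  w <- tiny_world()
  cfg <- method_config("NeoDiscMS")
  a <- run_acquisition(w$mix, w$sil, cfg, w$model, seed = 33)
  b <- run_acquisition(w$mix, w$sil, cfg, w$model, seed = 33)
  expect_identical(a$scans, b$scans)
  expect_identical(a$events, b$events)
  expect_identical(a$peaks, b$peaks)
  c <- run_acquisition(w$mix, w$sil, cfg, w$model, seed = 34)
  expect_false(identical(a$scans, c$scans))
})

test_that("with an empty inclusion list the targeted methods collapse onto DDA", {
  w <- tiny_world()
  dda <- run_acquisition(w$mix, NULL, method_config("DDA"), w$model, seed = 12)
  for (method in c("ilDDA", "NeoDiscMS")) {
    m <- run_acquisition(w$mix, w$sil[0, , drop = FALSE],
                         method_config(method), w$model, seed = 12)
    expect_equal(m$scans[, -1], dda$scans[, -1])
    expect_equal(nrow(m$events), 0L)
  }
})

test_that("every high-sensitivity scan follows a real-time-search hit", {
  w <- tiny_world()
  log <- run_acquisition(w$mix, w$sil, method_config("NeoDiscMS"), w$model,
                         seed = 44)
  ev <- log$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$hit[!is.na(ev$hms2_scan_id)]))
  hms2_ids <- log$scans$scan_id[log$scans$scan_type == "hMS2"]
  expect_setequal(hms2_ids, ev$hms2_scan_id[!is.na(ev$hms2_scan_id)])
})

test_that("the targeted branch ignores the intensity gate; discovery respects it", {
  w <- tiny_world(ratio = 1 / 1024)   # targets well below the gate
  cfg <- method_config("NeoDiscMS", min_precursor_intensity = 1e9)
  log <- run_acquisition(w$mix, w$sil, cfg, w$model, seed = 3)
  expect_equal(sum(log$scans$scan_type == "dMS2"), 0L)  # gate blocks discovery
  expect_gt(sum(log$scans$scan_type == "sMS2"), 0L)     # targeted still fires
})

test_that("dynamic exclusion bans re-fragmentation and spares the targeted branch", {
  # one abundant peptide, tiny gradient: DDA fragments it once, then the
  # exclusion window (closed interval) blocks it until expiry
  pep <- generate_peptidome(1, seed = 2, gradient_min = 1, rt_margin = 0.1)
  pep$rt_apex <- 0.5; pep$rt_sigma <- 0.5; pep$abundance <- 1e7
  attr(pep, "gradient_min") <- 1
  model <- signal_model(gradient_min = 1)
  cfg <- method_config("DDA",
                       dynamic_exclusion = list(duration_s = 9, tol_ppm = 10))
  log <- run_acquisition(pep, NULL, cfg, model, seed = 5)
  d <- log$scans[log$scans$scan_type == "dMS2", ]
  d <- d[order(d$start_ms), ]
  by_z <- split(d, d$precursor_z)
  for (dz in by_z) {
    if (nrow(dz) < 2) next
    gaps <- diff(dz$cycle)   # cycles are 3 s; 9 s exclusion = 3 cycles
    expect_true(all(gaps > 3))
  }
  # NeoDiscMS: the targeted branch keeps sampling the same precursor every
  # cycle despite discovery exclusion
  tg <- data.frame(sequence = pep$sequence, rt_pred = 0.5)
  sil <- schedule_targets(tg, halfwidth_min = 0.5, gradient_min = 1)
  log2 <- run_acquisition(pep, sil, method_config("NeoDiscMS"), model, seed = 5)
  s <- log2$scans[log2$scans$scan_type == "sMS2", ]
  expect_gt(length(unique(s$cycle)), 10)
})

test_that("per-cycle per-precursor caps hold across branches", {
  pep <- generate_peptidome(1, seed = 3, gradient_min = 1, rt_margin = 0.1)
  pep$rt_apex <- 0.5; pep$rt_sigma <- 0.5; pep$abundance <- 1e7
  attr(pep, "gradient_min") <- 1
  model <- signal_model(gradient_min = 1)
  tg <- data.frame(sequence = pep$sequence, rt_pred = 0.5)
  sil <- schedule_targets(tg, halfwidth_min = 0.5, gradient_min = 1)
  caps <- c(DDA = 1L, ilDDA = 2L, NeoDiscMS = 3L)
  for (method in names(caps)) {
    log <- run_acquisition(pep, sil, method_config(method), model, seed = 6)
    ms2 <- log$scans[log$scans$scan_type != "MS1", ]
    key <- paste(round(ms2$precursor_mz, 4), ms2$precursor_z, ms2$cycle)
    expect_lte(max(table(key)), caps[[method]])
  }
})

test_that("scan logs round-trip through the plain-text writer", {
  w <- tiny_world(n_bg = 10L, n_spike = 3L)
  log <- run_acquisition(w$mix, w$sil, method_config("NeoDiscMS"), w$model,
                         seed = 17)
  stem <- file.path(withr::local_tempdir(), "run1")
  write_scan_log(log, stem)
  scans <- utils::read.delim(paste0(stem, "_scans.tsv"))
  expect_equal(nrow(scans), nrow(log$scans))
  hdr <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(hdr$method, "NeoDiscMS")
  expect_equal(hdr$seed, log$seed)
  mgf <- read_mgf(paste0(stem, ".mgf"))
  keep <- !vapply(log$peaks, is.null, logical(1))
  expect_equal(length(mgf), sum(keep))
  one <- which(keep)[1L]
  expect_equal(mgf[[sprintf("scan=%d", one)]]$mz, log$peaks[[one]]$mz,
               tolerance = 1e-6)
})
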