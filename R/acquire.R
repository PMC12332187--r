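# Cycle-budgeted acquisition engine: DDA, ilDDA and the real-time-search
# filtered targeted method (NeoDiscMS scheme). Cycles sit on a fixed 3-s
# grid; each cycle runs MS1, then the targeted branch (scouting scan ->
# real-time-search filter -> high-sensitivity scan), then TopN discovery
# with dynamic exclusion on the remaining budget.

#' Acquisition method configuration
#'
#' @param method one of `"DDA"`, `"ilDDA"`, `"NeoDiscMS"`.
#' @param cycle_ms fixed cycle time in ms (default 3000).
#' @param scan_params per-scan-type parameters, see [default_scan_params()].
#' @param dda_isolation_width discovery MS2 isolation width in Th (1.2
#'   regular, 3.2 wide; default 3.2).
#' @param min_precursor_intensity minimum MS1 intensity for discovery
#'   selection (the targeted branch ignores it).
#' @param dynamic_exclusion list with `duration_s` and `tol_ppm`; discovery
#'   branch only.
#' @param inclusion_match_tol_ppm MS1-feature-to-inclusion-entry match
#'   tolerance.
#' @param precursor_cap maximum MS2 scans per precursor per cycle across
#'   branches; defaults 3 (NeoDiscMS), 2 (ilDDA), 1 (DDA).
#' @param rts an [rts_filter_config()].
#' @param varmods,max_mods variable-modification space of the real-time
#'   search database.
#' @return object of class `method_config`.
#' @export
method_config <- function(method = c("DDA", "ilDDA", "NeoDiscMS"),
                          cycle_ms = 3000,
                          scan_params = default_scan_params(),
                          dda_isolation_width = 3.2,
                          min_precursor_intensity = 200,
                          dynamic_exclusion = list(duration_s = 20, tol_ppm = 10),
                          inclusion_match_tol_ppm = 10,
                          precursor_cap = NULL,
                          rts = rts_filter_config(),
                          varmods = list(residue = "M", delta = 15.994915),
                          max_mods = 3L) {
  method <- match.arg(method)
  if (is.null(precursor_cap))
    precursor_cap <- switch(method, NeoDiscMS = 3L, ilDDA = 2L, DDA = 1L)
  if (cycle_ms <= scan_params$MS1$duration_ms)
    stop("config error: cycle_ms must exceed the MS1 scan duration")
  if (precursor_cap < 1L) stop("config error: precursor cap must be >= 1")
  if (dda_isolation_width <= 0) stop("config error: isolation width must be > 0")
  scan_params$dMS2$isolation_width <- dda_isolation_width
  structure(list(method = method, cycle_ms = cycle_ms,
                 scan_params = scan_params,
                 dda_isolation_width = dda_isolation_width,
                 min_precursor_intensity = min_precursor_intensity,
                 dynamic_exclusion = dynamic_exclusion,
                 inclusion_match_tol_ppm = inclusion_match_tol_ppm,
                 precursor_cap = as.integer(precursor_cap),
                 rts = rts, varmods = varmods, max_mods = as.integer(max_mods)),
            class = "method_config")
}

#' Build the real-time-search peptidoform database
#'
#' All modification variants and charge states of the target sequences,
#' with precursor m/z, for candidate lookup by isolation window.
#'
#' @param sequences target peptide sequences.
#' @param varmods,max_mods,charges see [enumerate_precursors()].
#' @return data.frame with one row per (form, charge).
#' @export
build_rts_db <- function(sequences,
                         varmods = list(residue = "M", delta = 15.994915),
                         max_mods = 3L, charges = 1:3) {
  sequences <- unique(sequences)
  out <- do.call(rbind, lapply(sequences, enumerate_precursors,
                               varmods = varmods, max_mods = max_mods,
                               charges = charges))
  rownames(out) <- NULL
  out
}

#' Evaluate a scouting scan with the real-time search
#'
#' Candidates are all database peptidoforms whose precursor m/z lies within
#' the scan's isolation window at the scan's precursor charge. Every
#' candidate is scored by cross-correlation; dCn is computed over the
#' sorted candidate scores and the precursor ppm error for the best
#' candidate. The event is a hit iff [rtsf_pass()] accepts it.
#'
#' @param pl the scouting-scan [peaklist()].
#' @param precursor_mz,precursor_z the isolated precursor.
#' @param isolation_width scan isolation width (Th).
#' @param rts_db database from [build_rts_db()].
#' @param cfg an [rts_filter_config()].
#' @return one-row data.frame (an RTS event, without scan bookkeeping).
#' @export
rts_evaluate <- function(pl, precursor_mz, precursor_z, isolation_width,
                         rts_db, cfg = rts_filter_config()) {
  as.data.frame(.rts_eval_core(pl, precursor_mz, precursor_z, isolation_width,
                               rts_db, cfg))
}

.rts_eval_core <- function(pl, precursor_mz, precursor_z, isolation_width,
                           rts_db, cfg) {
  half <- isolation_width / 2
  sel <- which(abs(rts_db$mz - precursor_mz) <= half &
                 rts_db$charge == precursor_z &
                 rts_db$charge %in% cfg$charges)
  if (length(sel) == 0L || length(pl$mz) == 0L) {
    return(list(sequence = NA_character_, mods = NA_character_,
                z = NA_integer_, xcorr = NA_real_, dcn = NA_real_,
                delta_ppm = NA_real_, n_candidates = length(sel), hit = FALSE))
  }
  bs <- xcorr_preprocess(bin_spectrum(pl))
  xs <- vapply(sel, function(i) {
    p <- .cand_form(rts_db$sequence[i], rts_db$mods[i], rts_db$charge[i])
    xcorr(p, bs)
  }, numeric(1))
  best <- sel[which.max(xs)]
  dppm <- delta_ppm(precursor_mz, rts_db$mz[best])
  s <- list(xcorr = max(xs), dcn = delta_cn(xs), delta_ppm = dppm,
            charge = rts_db$charge[best])
  list(sequence = rts_db$sequence[best], mods = rts_db$mods[best],
       z = rts_db$charge[best], xcorr = s$xcorr, dcn = s$dcn,
       delta_ppm = dppm, n_candidates = length(sel), hit = rtsf_pass(s, cfg))
}

.prec_key <- function(mz, z) sprintf("%.4f/%d", mz, z)

#' Run a cycle-budgeted acquisition
#'
#' Simulates a full LC-MS/MS run of `mixture` under the configured method.
#' Per 3-s cycle: (1) an MS1 scan observes eluting features; (2) for ilDDA
#' and the targeted method, features matching an active inclusion entry
#' (ppm + charge + RT window) are queued by descending intensity; the
#' targeted method scouts each with an sMS2, evaluates the real-time-search
#' filter, and triggers an hMS2 on a hit, while ilDDA triggers the hMS2
#' directly; neither dynamic exclusion nor the minimum-intensity gate apply
#' to this branch; (3) TopN discovery MS2 scans fill the remaining budget
#' with dynamic exclusion and the intensity gate. A scan is acquired only
#' if it fits the remaining cycle budget; per-cycle per-precursor caps are
#' enforced across branches.
#'
#' @param mixture a `sample_mixture` from [make_dilution_series()] (or any
#'   `peptidome`).
#' @param sil inclusion list from [schedule_targets()]; ignored for DDA.
#' @param cfg a [method_config()].
#' @param model a [signal_model()].
#' @param seed master seed; all per-scan randomness derives from it.
#' @return object of class `scan_log`: `scans` (data.frame), `peaks`
#'   (list of peak lists by scan id), `features` (per-cycle MS1 features),
#'   `events` (RTS events), plus the config echo and seed.
#' @export
run_acquisition <- function(mixture, sil = NULL, cfg = method_config(),
                            model = signal_model(), seed = 1L) {
  if (!inherits(cfg, "method_config")) stop("config error: need a method_config")
  targeted <- cfg$method %in% c("ilDDA", "NeoDiscMS") &&
    !is.null(sil) && nrow(sil) > 0L
  if (cfg$method %in% c("ilDDA", "NeoDiscMS") && is.null(sil))
    sil <- data.frame()
  gradient <- attr(mixture, "gradient_min")
  if (is.null(gradient)) gradient <- model$gradient_min
  n_cycles <- floor(gradient * 60000 / cfg$cycle_ms)
  rts_db <- NULL
  if (targeted && cfg$method == "NeoDiscMS")
    rts_db <- build_rts_db(unique(sil$sequence), cfg$varmods, cfg$max_mods,
                           cfg$rts$charges)
  sp <- cfg$scan_params
  # vector accumulators for scan records (hot path)
  acc <- new.env(parent = emptyenv())
  acc$cycle <- integer(); acc$type <- character(); acc$start <- numeric()
  acc$dur <- numeric(); acc$pmz <- numeric(); acc$pz <- integer()
  acc$width <- numeric(); acc$prov <- character(); acc$npk <- integer()
  n_scans <- 0L
  peaks <- list()
  event_rows <- vector("list", 512L); n_events <- 0L
  features <- vector("list", n_cycles)
  excl_mz <- numeric(); excl_exp <- numeric()

  push_scan <- function(cycle, type, start_ms, dur, pmz, pz, width, prov, pl) {
    n_scans <<- n_scans + 1L
    i <- n_scans
    acc$cycle[i] <- cycle; acc$type[i] <- type; acc$start[i] <- start_ms
    acc$dur[i] <- dur; acc$pmz[i] <- pmz
    acc$pz[i] <- if (is.na(pz)) NA_integer_ else as.integer(pz)
    acc$width[i] <- width; acc$prov[i] <- prov
    acc$npk[i] <- if (is.null(pl)) NA_integer_ else length(pl$mz)
    if (!is.null(pl)) peaks[[i]] <<- pl
    i
  }

  for (cycle in seq_len(n_cycles)) {
    t_min <- ((cycle - 1L) * cfg$cycle_ms / 1000) / 60
    t_s <- t_min * 60
    cycle_start <- (cycle - 1L) * cfg$cycle_ms
    used <- 0
    counts <- new.env(parent = emptyenv())
    bump <- function(key) {
      n <- if (is.null(counts[[key]])) 0L else counts[[key]]
      counts[[key]] <- n + 1L
    }
    count_of <- function(key) if (is.null(counts[[key]])) 0L else counts[[key]]

    # --- level 1: MS1 ---
    feats <- ms1_observe(mixture, t_min, model, hash_seed(seed, "ms1", cycle))
    push_scan(cycle, "MS1", cycle_start, sp$MS1$duration_ms,
              NA_real_, NA_integer_, NA_real_, "survey", NULL)
    used <- used + sp$MS1$duration_ms
    features[[cycle]] <- if (nrow(feats)) cbind(cycle = cycle, feats) else feats
    ord_in_cycle <- 1L

    # --- level 2: targeted branch ---
    if (targeted && nrow(feats)) {
      active <- sil[t_min >= sil$t_start & t_min <= sil$t_stop, , drop = FALSE]
      if (nrow(active)) {
        # pair features with entries (charge match + ppm match); a feature
        # keeps its best-matching entry
        tolr <- cfg$inclusion_match_tol_ppm * 1e-6
        pair_fi <- integer(); pair_entry <- integer()
        for (z in unique(feats$z)) {
          fiz <- which(feats$z == z)
          eiz <- which(active$z == z)
          if (!length(eiz)) next
          dm <- abs(outer(feats$mz[fiz], active$mz[eiz], "-")) /
            outer(rep(1, length(fiz)), active$mz[eiz]) # relative error
          ok <- dm <= tolr
          hit <- which(rowSums(ok) > 0L)
          for (k in hit) {
            cols <- which(ok[k, ])
            best <- cols[which.min(dm[k, cols])]
            pair_fi <- c(pair_fi, fiz[k])
            pair_entry <- c(pair_entry, eiz[best])
          }
        }
        if (length(pair_fi)) {
          o <- order(-feats$intensity[pair_fi], feats$mz[pair_fi])
          pair_fi <- pair_fi[o]; pair_entry <- pair_entry[o]
          for (r in seq_along(pair_fi)) {
            f <- list(mz = feats$mz[pair_fi[r]], z = feats$z[pair_fi[r]])
            ent <- list(compound_id = active$compound_id[pair_entry[r]])
            key <- .prec_key(f$mz, f$z)
            if (count_of(key) >= cfg$precursor_cap) next
            if (cfg$method == "NeoDiscMS") {
              if (used + sp$sMS2$duration_ms > cfg$cycle_ms) next
              ord_in_cycle <- ord_in_cycle + 1L
              pl <- simulate_ms2(f$mz, sp$sMS2$isolation_width, mixture, t_min,
                                 sp$sMS2, model,
                                 hash_seed(seed, "scan", cycle, ord_in_cycle),
                                 precursor_charge = f$z)
              sid <- push_scan(cycle, "sMS2", cycle_start + used,
                               sp$sMS2$duration_ms, f$mz, f$z,
                               sp$sMS2$isolation_width, ent$compound_id, pl)
              used <- used + sp$sMS2$duration_ms
              bump(key)
              ev <- .rts_eval_core(pl, f$mz, f$z, sp$sMS2$isolation_width,
                                   rts_db, cfg$rts)
              ev$sms2_scan_id <- sid
              ev$hms2_scan_id <- NA_integer_
              ev$hms2_skipped <- FALSE
              ev$cycle <- cycle
              if (ev$hit) {
                if (used + sp$hMS2$duration_ms <= cfg$cycle_ms &&
                    count_of(key) < cfg$precursor_cap) {
                  ord_in_cycle <- ord_in_cycle + 1L
                  plh <- simulate_ms2(f$mz, sp$hMS2$isolation_width, mixture,
                                      t_min, sp$hMS2, model,
                                      hash_seed(seed, "scan", cycle, ord_in_cycle),
                                      precursor_charge = f$z)
                  hid <- push_scan(cycle, "hMS2", cycle_start + used,
                                   sp$hMS2$duration_ms, f$mz, f$z,
                                   sp$hMS2$isolation_width, ent$compound_id, plh)
                  used <- used + sp$hMS2$duration_ms
                  bump(key)
                  ev$hms2_scan_id <- hid
                } else {
                  ev$hms2_skipped <- TRUE
                }
              }
              n_events <- n_events + 1L
              event_rows[[n_events]] <- ev
            } else { # ilDDA: high-sensitivity scan directly
              if (used + sp$hMS2$duration_ms > cfg$cycle_ms) next
              ord_in_cycle <- ord_in_cycle + 1L
              plh <- simulate_ms2(f$mz, sp$hMS2$isolation_width, mixture, t_min,
                                  sp$hMS2, model,
                                  hash_seed(seed, "scan", cycle, ord_in_cycle),
                                  precursor_charge = f$z)
              push_scan(cycle, "hMS2", cycle_start + used, sp$hMS2$duration_ms,
                        f$mz, f$z, sp$hMS2$isolation_width, ent$compound_id, plh)
              used <- used + sp$hMS2$duration_ms
              bump(key)
            }
          }
        }
      }
    }

    # --- level 3: discovery (TopN with dynamic exclusion) ---
    if (nrow(feats)) {
      live <- excl_exp >= t_s
      excl_mz <- excl_mz[live]; excl_exp <- excl_exp[live]
      o <- order(-feats$intensity, feats$mz)
      for (fi in o) {
        f <- list(mz = feats$mz[fi], z = feats$z[fi],
                  intensity = feats$intensity[fi])
        if (f$intensity < cfg$min_precursor_intensity) next
        if (length(excl_mz) &&
            any(abs(f$mz - excl_mz) <= excl_mz * cfg$dynamic_exclusion$tol_ppm * 1e-6))
          next
        key <- .prec_key(f$mz, f$z)
        if (count_of(key) >= cfg$precursor_cap) next
        if (used + sp$dMS2$duration_ms > cfg$cycle_ms) break
        ord_in_cycle <- ord_in_cycle + 1L
        pl <- simulate_ms2(f$mz, sp$dMS2$isolation_width, mixture, t_min,
                           sp$dMS2, model,
                           hash_seed(seed, "scan", cycle, ord_in_cycle),
                           precursor_charge = f$z)
        push_scan(cycle, "dMS2", cycle_start + used, sp$dMS2$duration_ms,
                  f$mz, f$z, sp$dMS2$isolation_width, "topN", pl)
        used <- used + sp$dMS2$duration_ms
        bump(key)
        excl_mz <- c(excl_mz, f$mz)
        excl_exp <- c(excl_exp, t_s + cfg$dynamic_exclusion$duration_s)
      }
    }
  }

  scans <- data.frame(
    scan_id = seq_len(n_scans), cycle = acc$cycle, scan_type = acc$type,
    start_ms = acc$start, duration_ms = acc$dur, precursor_mz = acc$pmz,
    precursor_z = acc$pz, isolation_width = acc$width,
    provenance = acc$prov, n_peaks = acc$npk)
  if (n_events) {
    evl <- event_rows[seq_len(n_events)]
    col <- function(nm) unlist(lapply(evl, `[[`, nm), use.names = FALSE)
    events <- data.frame(
      sequence = col("sequence"), mods = col("mods"), z = col("z"),
      xcorr = col("xcorr"), dcn = col("dcn"), delta_ppm = col("delta_ppm"),
      n_candidates = col("n_candidates"), hit = col("hit"),
      sms2_scan_id = col("sms2_scan_id"), hms2_scan_id = col("hms2_scan_id"),
      hms2_skipped = col("hms2_skipped"), cycle = col("cycle"),
      event_id = seq_len(n_events))
  } else {
    events <- data.frame(sequence = character(), mods = character(),
                         z = integer(), xcorr = numeric(), dcn = numeric(),
                         delta_ppm = numeric(), n_candidates = integer(),
                         hit = logical(), sms2_scan_id = integer(),
                         hms2_scan_id = integer(), hms2_skipped = logical(),
                         cycle = integer(), event_id = integer())
  }
  structure(list(method = cfg$method, config = cfg, seed = seed,
                 gradient_min = gradient, scans = scans, peaks = peaks,
                 events = events, features = features),
            class = "scan_log")
}

#' @export
print.scan_log <- function(x, ...) {
  tt <- table(x$scans$scan_type)
  cat(sprintf("<scan_log> %s, %d cycles, %d scans (%s), %d RTS events (%d hits)\n",
              x$method, max(x$scans$cycle), nrow(x$scans),
              paste(names(tt), tt, sep = ":", collapse = " "),
              nrow(x$events), sum(x$events$hit)))
  invisible(x)
}

#' Per-cycle time budget report
#'
#' @param log a `scan_log`.
#' @return data.frame with `cycle`, `ms1_ms`, `targeted_ms`, `discovery_ms`,
#'   `idle_ms`; the four components sum to the cycle time.
#' @export
cycle_budget_report <- function(log) {
  cyc <- sort(unique(log$scans$cycle))
  agg <- function(types) {
    s <- log$scans[log$scans$scan_type %in% types, , drop = FALSE]
    v <- tapply(s$duration_ms, factor(s$cycle, levels = cyc), sum)
    ifelse(is.na(v), 0, v)
  }
  ms1 <- agg("MS1"); targ <- agg(c("sMS2", "hMS2")); disc <- agg("dMS2")
  data.frame(cycle = cyc, ms1_ms = as.numeric(ms1),
             targeted_ms = as.numeric(targ), discovery_ms = as.numeric(disc),
             idle_ms = log$config$cycle_ms - as.numeric(ms1) - as.numeric(targ) -
               as.numeric(disc))
}

#' Write a scan log to plain-text files
#'
#' Emits `<stem>.json` (config echo + seed), `<stem>_scans.tsv`,
#' `<stem>_events.tsv`, `<stem>_features.tsv` and `<stem>.mgf`.
#'
#' @param log a `scan_log`.
#' @param stem output path stem.
#' @return invisibly, the stem.
#' @export
write_scan_log <- function(log, stem) {
  hdr <- list(method = log$method, seed = log$seed,
              gradient_min = log$gradient_min,
              cycle_ms = log$config$cycle_ms,
              dda_isolation_width = log$config$dda_isolation_width)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE)
  utils::write.table(log$scans, paste0(stem, "_scans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(log$events, paste0(stem, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  featdf <- do.call(rbind, log$features[!vapply(log$features, is.null, logical(1))])
  utils::write.table(featdf, paste0(stem, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  keep <- !vapply(log$peaks, is.null, logical(1))
  pls <- log$peaks[keep]
  names(pls) <- sprintf("scan=%d", which(keep))
  write_mgf(pls, paste0(stem, ".mgf"))
  invisible(stem)
}

#' Read a scan log written by [write_scan_log()]
#'
#' Reconstructs a `scan_log` sufficient for offline searching and
#' evaluation (the method config echo is reduced to the JSON header).
#'
#' @param stem path stem used when writing.
#' @return a `scan_log`.
#' @export
read_scan_log <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"))
  scans <- utils::read.delim(paste0(stem, "_scans.tsv"), stringsAsFactors = FALSE)
  events <- utils::read.delim(paste0(stem, "_events.tsv"), stringsAsFactors = FALSE)
  featdf <- utils::read.delim(paste0(stem, "_features.tsv"), stringsAsFactors = FALSE)
  n_cycles <- max(scans$cycle)
  features <- vector("list", n_cycles)
  for (cy in unique(featdf$cycle))
    features[[cy]] <- featdf[featdf$cycle == cy, , drop = FALSE]
  mgf <- read_mgf(paste0(stem, ".mgf"))
  peaks <- vector("list", nrow(scans))
  ids <- as.integer(sub("^scan=", "", names(mgf)))
  for (k in seq_along(mgf)) peaks[[ids[k]]] <- mgf[[k]]
  structure(list(method = hdr$method, config = hdr, seed = hdr$seed,
                 gradient_min = hdr$gradient_min, scans = scans,
                 peaks = peaks, events = events, features = features),
            class = "scan_log")
}
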