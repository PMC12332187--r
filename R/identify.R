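# Simplified offline search engine over scan logs: candidate lookup with
# chimeric co-isolation, scoring, target-decoy FDR, target-identification
# classification, and the co-isolated mass-difference analysis.

#' Offline search configuration
#'
#' @param precursor_tol_ppm precursor match tolerance (isolated and
#'   feature-matched modes).
#' @param fragment_tol_ppm fragment match tolerance.
#' @param varmods,max_mods,charges database enumeration space.
#' @param fdr_level accepted false discovery rate (default 0.01).
#' @param chimeric also search precursors co-isolated with the selected
#'   mass (MS1 features inside the isolation window).
#' @param isolated_tol_ppm tolerance separating isolated from co-isolated
#'   precursors around the isolation center.
#' @return object of class `search_config`.
#' @export
search_config <- function(precursor_tol_ppm = 10, fragment_tol_ppm = 20,
                          varmods = list(residue = "M", delta = 15.994915),
                          max_mods = 3L, charges = 1:3, fdr_level = 0.01,
                          chimeric = TRUE, isolated_tol_ppm = 10) {
  stopifnot(fdr_level > 0, fdr_level < 1)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, varmods = varmods,
                 max_mods = as.integer(max_mods), charges = as.integer(charges),
                 fdr_level = fdr_level, chimeric = chimeric,
                 isolated_tol_ppm = isolated_tol_ppm),
            class = "search_config")
}

#' Generate reversed-sequence decoys
#'
#' Each sequence is reversed in full; decoys that collide with any target
#' sequence (palindromes included) are dropped.
#'
#' @param sequences target peptide sequences.
#' @return character vector of decoy sequences.
#' @export
generate_decoys <- function(sequences) {
  rev_seq <- vapply(strsplit(sequences, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1))
  unique(rev_seq[!(rev_seq %in% sequences)])
}

#' Build the offline search database
#'
#' Enumerates all modification variants and charges of the target sequences
#' plus their reversed decoys, sorted by precursor m/z for window lookup.
#'
#' @param sequences target (sample-universe) peptide sequences.
#' @param cfg a [search_config()].
#' @param decoys include reversed decoys (default TRUE).
#' @return data.frame of class `search_db`.
#' @export
build_search_db <- function(sequences, cfg = search_config(), decoys = TRUE) {
  sequences <- unique(sequences)
  tdb <- do.call(rbind, lapply(sequences, enumerate_precursors,
                               varmods = cfg$varmods, max_mods = cfg$max_mods,
                               charges = cfg$charges))
  tdb$is_decoy <- FALSE
  if (decoys) {
    dseq <- generate_decoys(sequences)
    if (length(dseq)) {
      ddb <- do.call(rbind, lapply(dseq, enumerate_precursors,
                                   varmods = cfg$varmods, max_mods = cfg$max_mods,
                                   charges = cfg$charges))
      ddb$is_decoy <- TRUE
      tdb <- rbind(tdb, ddb)
    }
  }
  tdb <- tdb[order(tdb$mz), , drop = FALSE]
  rownames(tdb) <- NULL
  class(tdb) <- c("search_db", "data.frame")
  attr(tdb, "vectors") <- list(
    mz = tdb$mz, z = tdb$charge, seq = tdb$sequence, mods = tdb$mods,
    decoy = tdb$is_decoy, mass = tdb$neutral_mass)
  tdb
}

.db_window <- function(db, lo, hi) {
  i <- findInterval(c(lo, hi), db$mz)
  if (i[2L] == 0L) return(db[0L, , drop = FALSE])
  from <- i[1L] + 1L
  # findInterval gives the count of mz <= lo; include equality at lo
  while (from > 1L && db$mz[from - 1L] >= lo) from <- from - 1L
  db[seq.int(from, i[2L]), , drop = FALSE]
}

.cand_form <- function(sequence, mods, charge) {
  key <- paste("pf", sequence, mods, charge, sep = "\r")
  .cache_get(key, function()
    peptidoform(sequence, parse_mod_signature(mods), charge))
}

.score_candidate <- function(pl, bs_pre, sequence, mods, charge, cfg) {
  p <- .cand_form(sequence, mods, charge)
  fr <- .cache_get(paste("fr1", sequence, mods, sep = "\r"),
                   function() fragment_mzs(p, 1L))
  st <- .match_stats(pl, fr, cfg$fragment_tol_ppm)
  hs <- hyperscore(st$n_b, st$n_y, st$sum_I_b, st$sum_I_y)
  v <- sqrt(st$obs); nv <- sqrt(sum(v^2))
  sa <- if (nv == 0) 0 else {
    cth <- min(max(sum(v) / (nv * sqrt(length(v))), -1), 1)
    1 - (2 / pi) * acos(cth)
  }
  xc <- xcorr(p, bs_pre)
  c(hyperscore = hs, xcorr = xc, spectral_angle = sa,
    n_b = st$n_b, n_y = st$n_y)
}

#' Search one MS2 scan against the database
#'
#' Candidate peptidoforms are (a) those within the precursor tolerance of
#' the isolated m/z at matching charge and, (b) in chimeric mode, those
#' matching any MS1 feature of the scan's cycle whose m/z lies inside the
#' isolation window. Candidates are scored (hyperscore primary) and the
#' best target and best decoy are retained per co-isolation group.
#'
#' @param pl the scan's [peaklist()].
#' @param precursor_mz,precursor_z,isolation_width scan metadata.
#' @param db a [build_search_db()] database.
#' @param features MS1 features of the scan's cycle (may be empty).
#' @param cfg a [search_config()].
#' @return data.frame of candidate PSMs (possibly empty).
#' @export
search_scan <- function(pl, precursor_mz, precursor_z, isolation_width,
                        db, features, cfg = search_config()) {
  cols <- .search_scan_core(pl, precursor_mz, precursor_z, isolation_width,
                            .db_vectors(db), features, cfg)
  if (is.null(cols)) return(NULL)
  as.data.frame(cols)
}

# Plain-vector view of a search_db (kept on the object as an attribute so
# repeated searches do not re-extract columns), plus a per-row cache of
# precomputed fragment tables and theoretical sparse spectra.
.db_vectors <- function(db) {
  v <- attr(db, "vectors")
  if (is.null(v)) {
    v <- list(mz = db$mz, z = db$charge, seq = db$sequence, mods = db$mods,
              decoy = db$is_decoy, mass = db$neutral_mass)
  }
  if (is.null(v$cache)) {
    v$cache <- new.env(parent = emptyenv())
    v$cache$ent <- vector("list", length(v$mz))
  }
  v
}

# Lazily built per-row scoring entry: fragment m/z ladder, b-series mask,
# and the theoretical sparse cross-correlation spectrum on the default grid.
.db_entry <- function(dbv, i) {
  ent <- dbv$cache$ent[[i]]
  if (is.null(ent)) {
    p <- peptidoform(dbv$seq[i], parse_mod_signature(dbv$mods[i]), dbv$z[i])
    fr <- fragment_mzs(p, 1L)
    tp <- theoretical_peaks(p)
    ent <- list(fmz = fr$mz, isb = fr$series == "b",
                tidx = tp$idx, tval = tp$val)
    dbv$cache$ent[[i]] <- ent
  }
  ent
}

# Lean candidate scorer used in the offline search hot path.
.score_entry <- function(pl_mz, pl_int, ypre, ent, tol_ppm) {
  fmz <- ent$fmz
  np <- length(pl_mz)
  obs <- numeric(length(fmz))
  i <- findInterval(fmz, pl_mz)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, np)
  best <- hi
  use_lo <- abs(fmz - pl_mz[lo]) <= abs(fmz - pl_mz[hi])
  best[use_lo] <- lo[use_lo]
  dist <- abs(fmz - pl_mz[best])
  matched <- dist <= fmz * tol_ppm * 1e-6 * (1 + 1e-9)
  obs[matched] <- pl_int[best[matched]]
  mb <- matched & ent$isb; my <- matched & !ent$isb
  n_b <- sum(mb); n_y <- sum(my)
  hs <- if (n_b + n_y == 0L) 0 else
    lfactorial(min(n_b, 64L)) + lfactorial(min(n_y, 64L)) +
    log(max(sum(obs[mb]), 1)) + log(max(sum(obs[my]), 1))
  v <- sqrt(obs); nv <- sqrt(sum(v^2))
  sa <- if (nv == 0) 0 else
    1 - (2 / pi) * acos(min(max(sum(v) / (nv * sqrt(length(v))), -1), 1))
  xc <- sum(ent$tval * ypre[ent$tidx]) / 1e4
  c(hs, xc, sa, n_b, n_y)
}

# Fast per-scan search core: returns a list of parallel column vectors
# (one element per retained PSM) or NULL.
.search_scan_core <- function(pl, precursor_mz, precursor_z, isolation_width,
                              dbv, features, cfg) {
  if (length(pl$mz) == 0L) return(NULL)
  g_mz <- precursor_mz; g_z <- precursor_z
  g_lab <- "isolated"; g_status <- "isolated"
  if (cfg$chimeric && !is.null(features) && nrow(features)) {
    half <- isolation_width / 2
    keep <- abs(features$mz - precursor_mz) <= half &
      abs(features$mz - precursor_mz) > precursor_mz * cfg$isolated_tol_ppm * 1e-6
    if (any(keep)) {
      co_mz <- features$mz[keep]; co_z <- features$z[keep]
      lab <- sprintf("co_%.4f/%d", co_mz, co_z)
      d <- !duplicated(lab)
      g_mz <- c(g_mz, co_mz[d]); g_z <- c(g_z, co_z[d])
      g_lab <- c(g_lab, lab[d])
      g_status <- c(g_status, rep("co_isolated", sum(d)))
    }
  }
  bs_pre <- NULL
  n_out <- 0L
  o_group <- character(); o_status <- character(); o_seq <- character()
  o_mods <- character(); o_z <- integer(); o_mass <- numeric()
  o_decoy <- logical(); o_hs <- numeric(); o_xc <- numeric(); o_sa <- numeric()
  o_nb <- integer(); o_ny <- integer(); o_obs <- numeric(); o_theo <- numeric()
  for (gi in seq_along(g_mz)) {
    tol <- g_mz[gi] * cfg$precursor_tol_ppm * 1e-6
    rng <- findInterval(c(g_mz[gi] - tol, g_mz[gi] + tol), dbv$mz)
    if (rng[2L] == 0L) next
    from <- rng[1L] + 1L
    while (from > 1L && dbv$mz[from - 1L] >= g_mz[gi] - tol) from <- from - 1L
    if (from > rng[2L]) next
    idx <- seq.int(from, rng[2L])
    idx <- idx[dbv$z[idx] == g_z[gi]]
    nc <- length(idx)
    if (nc == 0L) next
    if (is.null(bs_pre)) bs_pre <- xcorr_preprocess(bin_spectrum(pl))
    hs <- xc <- sa <- numeric(nc); nb <- ny <- integer(nc)
    for (k in seq_len(nc)) {
      sc <- .score_entry(pl$mz, pl$intensity, bs_pre$values,
                         .db_entry(dbv, idx[k]), cfg$fragment_tol_ppm)
      hs[k] <- sc[[1L]]; xc[k] <- sc[[2L]]; sa[k] <- sc[[3L]]
      nb[k] <- sc[[4L]]; ny[k] <- sc[[5L]]
    }
    for (dec in c(FALSE, TRUE)) {
      sel <- which(dbv$decoy[idx] == dec)
      if (!length(sel)) next
      b <- sel[order(-hs[sel], -xc[sel], dbv$seq[idx[sel]])][1L]
      n_out <- n_out + 1L
      o_group[n_out] <- g_lab[gi]; o_status[n_out] <- g_status[gi]
      o_seq[n_out] <- dbv$seq[idx[b]]; o_mods[n_out] <- dbv$mods[idx[b]]
      o_z[n_out] <- dbv$z[idx[b]]; o_mass[n_out] <- dbv$mass[idx[b]]
      o_decoy[n_out] <- dec
      o_hs[n_out] <- hs[b]; o_xc[n_out] <- xc[b]; o_sa[n_out] <- sa[b]
      o_nb[n_out] <- nb[b]; o_ny[n_out] <- ny[b]
      o_obs[n_out] <- g_mz[gi]; o_theo[n_out] <- dbv$mz[idx[b]]
    }
  }
  if (n_out == 0L) return(NULL)
  list(group = o_group, isolation_status = o_status, sequence = o_seq,
       mods = o_mods, z = o_z, neutral_mass = o_mass, is_decoy = o_decoy,
       hyperscore = o_hs, xcorr = o_xc, spectral_angle = o_sa,
       n_b = o_nb, n_y = o_ny, obs_mz = o_obs, theo_mz = o_theo,
       delta_ppm = (o_obs - o_theo) / o_theo * 1e6)
}

#' Search all MS2 scans of a scan log
#'
#' @param log a `scan_log` from [run_acquisition()].
#' @param db a [build_search_db()] database.
#' @param cfg a [search_config()].
#' @param scan_types MS2 scan types to search.
#' @return data.frame of candidate PSMs with `scan_id`, `cycle` and
#'   `scan_type` attached.
#' @export
search_scanlog <- function(log, db, cfg = search_config(),
                           scan_types = c("sMS2", "hMS2", "dMS2")) {
  take <- log$scans$scan_type %in% scan_types
  sid <- log$scans$scan_id[take]
  scyc <- log$scans$cycle[take]
  stype <- log$scans$scan_type[take]
  spmz <- log$scans$precursor_mz[take]
  spz <- log$scans$precursor_z[take]
  swid <- log$scans$isolation_width[take]
  dbv <- .db_vectors(db)
  out <- vector("list", length(sid))
  for (i in seq_along(sid)) {
    pl <- log$peaks[[sid[i]]]
    if (is.null(pl)) next
    cols <- .search_scan_core(pl, spmz[i], spz[i], swid[i], dbv,
                              log$features[[scyc[i]]], cfg)
    if (!is.null(cols)) {
      n <- length(cols$sequence)
      cols$scan_id <- rep(sid[i], n)
      cols$cycle <- rep(scyc[i], n)
      cols$scan_type <- rep(stype[i], n)
      out[[i]] <- cols
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame())
  nms <- names(out[[1L]])
  res <- as.data.frame(lapply(stats::setNames(nms, nms), function(nm)
    unlist(lapply(out, `[[`, nm), use.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Target-decoy FDR filtering with q-values
#'
#' PSMs are sorted by hyperscore (descending; decoys first on ties); the
#' running FDR estimate is `(#decoys + 1) / max(#targets, 1)`; q-values are
#' its monotone minimum from the bottom. Target PSMs with `q <= level` are
#' accepted.
#'
#' @param psms data.frame with `hyperscore` and `is_decoy`.
#' @param level FDR level (default 0.01).
#' @return accepted target PSMs with a `q_value` column.
#' @export
fdr_filter <- function(psms, level = 0.01) {
  if (is.null(psms) || nrow(psms) == 0L) {
    out <- if (is.null(psms)) data.frame() else psms
    out$q_value <- numeric(0)
    return(out)
  }
  o <- order(-psms$hyperscore, !psms$is_decoy)
  sorted <- psms[o, , drop = FALSE]
  cum_d <- cumsum(sorted$is_decoy)
  cum_t <- cumsum(!sorted$is_decoy)
  fdr <- (cum_d + 1) / pmax(cum_t, 1)
  q <- rev(cummin(rev(fdr)))
  sorted$q_value <- q
  acc <- sorted[!sorted$is_decoy & sorted$q_value <= level, , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Peptide-level FDR filtering
#'
#' Collapses PSMs to the best hyperscore per stripped sequence (per decoy
#' status) and applies the same target-decoy procedure.
#'
#' @param psms data.frame with `sequence`, `hyperscore`, `is_decoy`.
#' @param level FDR level.
#' @return accepted peptide rows with `q_value`.
#' @export
peptide_fdr <- function(psms, level = 0.01) {
  if (is.null(psms) || nrow(psms) == 0L) return(fdr_filter(psms, level))
  o <- order(psms$sequence, psms$is_decoy, -psms$hyperscore)
  s <- psms[o, , drop = FALSE]
  best <- s[!duplicated(s[, c("sequence", "is_decoy")]), , drop = FALSE]
  fdr_filter(best, level)
}

#' Classify target identifications (TIDs)
#'
#' For each real-time-search hit event, a TID is emitted when the event's
#' best-candidate peptide is among the accepted PSMs on the event's
#' scouting and/or high-sensitivity scans, recording which scan types
#' support it. Accepted discovery-branch PSMs of targets are not TIDs.
#'
#' @param log a `scan_log`.
#' @param accepted accepted PSMs from [fdr_filter()].
#' @param target_sequences character vector of target peptides.
#' @return data.frame with one row per TID (`event_id`, `sequence`,
#'   `support`).
#' @export
classify_tids <- function(log, accepted, target_sequences) {
  ev <- log$events
  out <- list()
  if (nrow(ev) == 0L || is.null(accepted) || nrow(accepted) == 0L)
    return(data.frame(event_id = integer(), sequence = character(),
                      support = character()))
  hits <- ev[ev$hit, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    e <- hits[i, ]
    if (!(e$sequence %in% target_sequences)) next
    s_ok <- any(accepted$scan_id == e$sms2_scan_id &
                  accepted$sequence == e$sequence)
    h_ok <- !is.na(e$hms2_scan_id) &&
      any(accepted$scan_id == e$hms2_scan_id & accepted$sequence == e$sequence)
    if (s_ok || h_ok) {
      out[[length(out) + 1L]] <- data.frame(
        event_id = e$event_id, sequence = e$sequence,
        support = if (s_ok && h_ok) "sMS2+hMS2" else if (s_ok) "sMS2" else "hMS2")
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(event_id = integer(), sequence = character(),
               support = character())
}

#' Co-isolated mass-difference analysis
#'
#' For every scan with two or more accepted same-charge PSMs, reports the
#' absolute neutral mass difference, its nearest integer multiple of 1 Da,
#' and the residual, plus the fraction of PSM pairs sharing a charge.
#'
#' @param accepted accepted PSMs (chimeric search).
#' @return list with `residuals` (data.frame) and `same_charge_fraction`.
#' @export
mass_diff_analysis <- function(accepted) {
  empty <- data.frame(scan_id = integer(), z = integer(), delta_mass = numeric(),
                      nearest_da = numeric(), residual = numeric())
  if (is.null(accepted) || nrow(accepted) == 0L)
    return(list(residuals = empty, same_charge_fraction = NA_real_))
  rows <- list(); n_pairs <- 0L; n_same <- 0L
  for (sid in unique(accepted$scan_id)) {
    sub <- accepted[accepted$scan_id == sid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) for (j in seq.int(i + 1L, nrow(sub))) {
      n_pairs <- n_pairs + 1L
      if (sub$z[i] != sub$z[j]) next
      n_same <- n_same + 1L
      dm <- abs(sub$neutral_mass[i] - sub$neutral_mass[j])
      nearest <- round(dm)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = sid, z = sub$z[i], delta_mass = dm, nearest_da = nearest,
        residual = abs(dm - nearest))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  list(residuals = res,
       same_charge_fraction = if (n_pairs) n_same / n_pairs else NA_real_)
}
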