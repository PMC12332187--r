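# Personalized targeting assets: candidate filtering, retention-time
# prediction, inclusion-list scheduling with RT windows, burden profiling,
# and the RTS FASTA / inclusion CSV emitters.

.KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Kyte-Doolittle hydropathy sum of a sequence
#'
#' @param sequence peptide sequence(s).
#' @return numeric vector of hydropathy sums.
#' @export
kd_hydropathy <- function(sequence) {
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) sum(.KD_HYDROPATHY[ch]), numeric(1))
}

#' Filter target candidates
#'
#' Retains candidate sequences within a length range, observed in at least
#' `min_presence` replicates, and passing every rank predicate; deduplicates
#' and returns in deterministic (alphabetical) order.
#'
#' Presence is counted from a `replicate` column (distinct replicates per
#' sequence) if present, else from an `n_obs` column, else each row counts
#' as one observation of its sequence.
#'
#' @param candidates data.frame with `sequence` plus optional `class`,
#'   `replicate`/`n_obs`, rank and `rt_min` columns.
#' @param length_range integer c(min, max) sequence length.
#' @param min_presence minimum number of replicates a sequence must appear in.
#' @param rank_filters named list of predicate functions; each name must be
#'   a column of `candidates` (e.g. `list(rank_A68 = function(x) x < 2)`).
#' @return data.frame of retained targets (one row per sequence).
#' @export
select_targets <- function(candidates, length_range = c(8L, 11L),
                           min_presence = 1L, rank_filters = list()) {
  if (!"sequence" %in% names(candidates))
    stop("schema error: candidate table needs a 'sequence' column")
  missing_cols <- setdiff(names(rank_filters), names(candidates))
  if (length(missing_cols))
    stop("schema error: rank column(s) not found: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(candidates) == 0L) return(candidates)
  if ("replicate" %in% names(candidates)) {
    pres <- tapply(candidates$replicate, candidates$sequence,
                   function(r) length(unique(r)))
  } else if ("n_obs" %in% names(candidates)) {
    pres <- tapply(candidates$n_obs, candidates$sequence, max)
  } else {
    pres <- table(candidates$sequence)
  }
  first <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  first$presence <- as.integer(pres[first$sequence])
  len <- nchar(first$sequence)
  keep <- len >= length_range[1L] & len <= length_range[2L] &
    first$presence >= min_presence
  for (col in names(rank_filters)) {
    keep <- keep & vapply(first[[col]], rank_filters[[col]], logical(1))
  }
  out <- first[keep & !is.na(keep), , drop = FALSE]
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict target retention times
#'
#' Pluggable retention-time prediction. Targets carrying an `rt_min` column
#' (external predictions or measured RTs) bypass prediction. Otherwise a
#' built-in surrogate is fitted by least squares on calibration
#' (peptide, rt) pairs: `rt = a * hydropathy_sum + b * length + c`, then
#' applied and clamped to the gradient.
#'
#' @param targets data.frame with `sequence` (and optionally `rt_min`).
#' @param calibration data.frame with `sequence` and `rt` (minutes);
#'   required when any target lacks `rt_min`. At least 10 pairs.
#' @param predictor optional function `character -> minutes` replacing the
#'   surrogate.
#' @param gradient_min gradient length in minutes (clamp bound).
#' @return `targets` with an `rt_pred` column.
#' @export
predict_rt <- function(targets, calibration = NULL, predictor = NULL,
                       gradient_min = 125) {
  rt_pred <- rep(NA_real_, nrow(targets))
  if ("rt_min" %in% names(targets)) rt_pred <- as.numeric(targets$rt_min)
  todo <- is.na(rt_pred)
  if (any(todo)) {
    if (!is.null(predictor)) {
      rt_pred[todo] <- predictor(targets$sequence[todo])
    } else {
      if (is.null(calibration) || nrow(calibration) < 10L)
        stop("calibration error: need >= 10 calibration (peptide, rt) pairs")
      fit <- stats::lm(rt ~ hyd + len,
                       data = data.frame(rt = calibration$rt,
                                         hyd = kd_hydropathy(calibration$sequence),
                                         len = nchar(calibration$sequence)))
      rt_pred[todo] <- stats::predict(
        fit, newdata = data.frame(hyd = kd_hydropathy(targets$sequence[todo]),
                                  len = nchar(targets$sequence[todo])))
    }
  }
  targets$rt_pred <- pmin(pmax(rt_pred, 0), gradient_min)
  targets
}

#' Build a scheduled inclusion list
#'
#' Enumerates all modification variants and charge states of each target
#' and assigns each precursor a retention-time window of `+/- halfwidth_min`
#' around the target's predicted RT, clamped to the gradient. Modified
#' forms inherit the unmodified peptide's `rt_pred`.
#'
#' @param targets data.frame with `sequence` and `rt_pred` (see
#'   [predict_rt()]).
#' @param varmods,max_mods,charges passed to [enumerate_precursors()].
#' @param halfwidth_min RT half-window in minutes (default 15).
#' @param gradient_min gradient length in minutes (default 125).
#' @return data.frame of class `inclusion_list` with `compound_id`,
#'   `sequence`, `mods`, `mz`, `z`, `t_start`, `t_stop`, `rt_pred`;
#'   attribute `gradient_min`.
#' @export
schedule_targets <- function(targets,
                             varmods = list(residue = "M", delta = 15.994915),
                             max_mods = 3L, charges = 1:3,
                             halfwidth_min = 15, gradient_min = 125) {
  if (!"rt_pred" %in% names(targets) || anyNA(targets$rt_pred))
    stop("scheduling error: every target needs rt_pred (run predict_rt first)")
  targets <- targets[order(targets$sequence), , drop = FALSE]
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    pre <- enumerate_precursors(targets$sequence[i], varmods, max_mods, charges)
    rt <- targets$rt_pred[i]
    rows[[i]] <- data.frame(
      compound_id = pre$compound_id,
      sequence = pre$sequence,
      mods = pre$mods,
      mz = pre$mz,
      z = pre$charge,
      t_start = max(0, rt - halfwidth_min),
      t_stop = min(gradient_min, rt + halfwidth_min),
      rt_pred = rt
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gradient_min") <- gradient_min
  class(out) <- c("inclusion_list", "data.frame")
  out
}

#' Inclusion-list burden over the gradient
#'
#' Number of scheduled precursors whose RT window (closed interval)
#' contains each time point.
#'
#' @param sil an [schedule_targets()] inclusion list.
#' @param times numeric vector of times (minutes).
#' @return data.frame with `time` and `n_scheduled`.
#' @export
burden_profile <- function(sil, times) {
  n <- vapply(times, function(t) sum(t >= sil$t_start & t <= sil$t_stop),
              numeric(1))
  data.frame(time = times, n_scheduled = as.numeric(n))
}

#' Write the real-time-search FASTA
#'
#' One entry per unique target peptide sequence; see
#' [write_peptide_fasta()] for the header format.
#'
#' @param targets data.frame with `sequence` (and optionally `class`).
#' @param path output FASTA.
#' @return invisibly, the number of records written.
#' @export
write_rts_fasta <- function(targets, path) {
  write_peptide_fasta(targets, path)
}

#' Write a vendor-style inclusion CSV
#'
#' Minimal reconstruction of a method-editor inclusion table:
#' `Compound,m/z,z,t start (min),t stop (min)` with m/z to 5 decimals.
#'
#' @param sil inclusion list from [schedule_targets()].
#' @param path output CSV.
#' @return invisibly, the number of rows written.
#' @export
write_inclusion_csv <- function(sil, path) {
  if (nrow(sil) == 0L) {
    warning("empty inclusion list: writing header only")
  }
  df <- data.frame(
    Compound = sil$compound_id,
    `m/z` = sprintf("%.5f", sil$mz),
    z = sil$z,
    `t start (min)` = sil$t_start,
    `t stop (min)` = sil$t_stop,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(nrow(df))
}

#' Read an inclusion CSV written by [write_inclusion_csv()]
#'
#' @param path CSV file.
#' @return data.frame with `compound_id`, `mz`, `z`, `t_start`, `t_stop`.
#' @export
read_inclusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(compound_id = df$Compound, mz = as.numeric(df$`m/z`),
             z = as.integer(df$z),
             t_start = as.numeric(df$`t start (min)`),
             t_stop = as.numeric(df$`t stop (min)`))
}
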