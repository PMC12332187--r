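# Benchmark metrics and reports: overlap coefficients, the target-gain vs
# depth-loss trade-off, the real-time-search funnel, reproducibility
# cross-tabulation, MS1-based quantification, and the end-to-end dilution
# benchmark.

#' Overlap coefficient between two identification sets
#'
#' Szymkiewicz-Simpson coefficient `|A n B| / min(|A|, |B|)`; Jaccard
#' available behind the `method` flag for comparison.
#'
#' @param A,B character vectors (treated as sets).
#' @param method `"overlap"` or `"jaccard"`.
#' @return value in `[0, 1]`.
#' @export
overlap_coefficient <- function(A, B, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L)
    stop("undefined metric: empty identification set")
  inter <- length(intersect(A, B))
  if (method == "overlap") inter / min(length(A), length(B))
  else inter / length(union(A, B))
}

#' Target-sensitivity vs depth-loss trade-off ratio
#'
#' Percent target gain relative to DDA divided by percent global-depth loss
#' relative to DDA. When the comparison method loses no depth the ratio is
#' undefined and an `Inf` sentinel is returned with a warning.
#'
#' @param depth_method,depth_dda unique-peptide depths.
#' @param targets_method,targets_dda unique target identification counts.
#' @return ratio (percent gain per percent loss).
#' @export
tradeoff_ratio <- function(depth_method, depth_dda, targets_method, targets_dda) {
  stopifnot(depth_dda > 0, targets_dda > 0)
  gain <- (targets_method - targets_dda) / targets_dda * 100
  if (gain == 0) return(0)
  loss <- (depth_dda - depth_method) / depth_dda * 100
  if (loss <= 0) {
    warning("no depth loss: trade-off ratio undefined, returning Inf sentinel")
    return(Inf)
  }
  gain / loss
}

#' Real-time-search funnel
#'
#' Counts and rates of the event -> hit -> TID funnel.
#'
#' @param log a `scan_log`.
#' @param tids data.frame from [classify_tids()].
#' @return list with `n_events`, `n_hits`, `n_tids`, `hit_rate`,
#'   `tid_rate`, and `flag` noting zero denominators.
#' @export
rts_funnel <- function(log, tids) {
  n_events <- nrow(log$events)
  n_hits <- sum(log$events$hit)
  n_tids <- if (is.null(tids)) 0L else length(unique(tids$event_id))
  if (n_tids > n_hits) stop("integrity error: more TIDs than RTS hits")
  flag <- NULL
  hit_rate <- if (n_events > 0) n_hits / n_events else { flag <- "no events"; 0 }
  tid_rate <- if (n_hits > 0) n_tids / n_hits else {
    flag <- c(flag, "no hits"); 0 }
  list(n_events = n_events, n_hits = n_hits, n_tids = n_tids,
       hit_rate = hit_rate, tid_rate = tid_rate, flag = flag)
}

#' Reproducibility cross-tabulation between two methods
#'
#' Entry (i, j) counts targets found in exactly i replicates of method A
#' and j replicates of method B (i, j in 0..n_reps).
#'
#' @param sets_a,sets_b lists of per-replicate identified-target sets.
#' @param universe character vector of all targets considered.
#' @param n_reps replicates per method.
#' @return integer matrix with margins as attributes.
#' @export
reproducibility_matrix <- function(sets_a, sets_b, universe, n_reps = 3L) {
  if (length(sets_a) != n_reps || length(sets_b) != n_reps)
    stop("config error: replicate count mismatch")
  cnt <- function(sets, x) sum(vapply(sets, function(s) x %in% s, logical(1)))
  m <- matrix(0L, n_reps + 1L, n_reps + 1L,
              dimnames = list(A = 0:n_reps, B = 0:n_reps))
  for (x in unique(universe)) {
    i <- cnt(sets_a, x); j <- cnt(sets_b, x)
    m[i + 1L, j + 1L] <- m[i + 1L, j + 1L] + 1L
  }
  attr(m, "row_margin") <- rowSums(m)
  attr(m, "col_margin") <- colSums(m)
  m
}

#' MS1-based quantification of accepted PSMs
#'
#' Precursor intensity is the maximum over the precursor's PSM-associated
#' MS1 feature intensities within the run; peptide intensity is the sum of
#' its precursors' intensities. PSMs with no matching MS1 feature are
#' assigned 0 and flagged.
#'
#' @param accepted accepted PSMs (need `sequence`, `mods`, `z`, `cycle`,
#'   `theo_mz`).
#' @param log the `scan_log` the PSMs came from.
#' @param tol_ppm feature match tolerance.
#' @return list with `precursors` and `peptides` data.frames.
#' @export
quantify <- function(accepted, log, tol_ppm = 10) {
  if (is.null(accepted) || nrow(accepted) == 0L)
    return(list(precursors = data.frame(sequence = character(), mods = character(),
                                        z = integer(), intensity = numeric(),
                                        unmatched = logical()),
                peptides = data.frame(sequence = character(), intensity = numeric())))
  inten <- numeric(nrow(accepted))
  flagged <- logical(nrow(accepted))
  for (i in seq_len(nrow(accepted))) {
    feats <- log$features[[accepted$cycle[i]]]
    v <- 0
    if (!is.null(feats) && nrow(feats)) {
      ok <- feats$z == accepted$z[i] &
        abs(delta_ppm(feats$mz, accepted$theo_mz[i])) <= tol_ppm
      if (any(ok)) v <- max(feats$intensity[ok])
    }
    inten[i] <- v
    flagged[i] <- v == 0
  }
  key <- paste(accepted$sequence, accepted$mods, accepted$z, sep = "\r")
  prec_int <- tapply(inten, key, max)
  prec_flag <- tapply(flagged, key, all)
  parts <- strsplit(names(prec_int), "\r", fixed = TRUE)
  precursors <- data.frame(
    sequence = vapply(parts, `[`, "", 1L),
    mods = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "",
                  character(1)),
    z = as.integer(vapply(parts, `[`, "", 3L)),
    intensity = as.numeric(prec_int),
    unmatched = as.logical(prec_flag))
  pep_int <- tapply(precursors$intensity, precursors$sequence, sum)
  peptides <- data.frame(sequence = names(pep_int),
                         intensity = as.numeric(pep_int))
  rownames(precursors) <- rownames(peptides) <- NULL
  list(precursors = precursors, peptides = peptides)
}

#' Between-replicate quantification correlation
#'
#' Coefficient of determination of log10 precursor intensities over
#' precursors quantified (intensity > 0) in both replicates, split by
#' target status.
#'
#' @param quant_a,quant_b outputs of [quantify()].
#' @param target_sequences character vector of target peptides.
#' @return data.frame with one row per group (`target`, `non_target`) and
#'   columns `r_squared`, `n_shared`, `flag`.
#' @export
replicate_correlation <- function(quant_a, quant_b, target_sequences) {
  pa <- quant_a$precursors; pb <- quant_b$precursors
  key <- function(p) paste(p$sequence, p$mods, p$z, sep = "\r")
  pa <- pa[pa$intensity > 0, , drop = FALSE]
  pb <- pb[pb$intensity > 0, , drop = FALSE]
  shared <- intersect(key(pa), key(pb))
  rows <- lapply(c(TRUE, FALSE), function(is_t) {
    ks <- shared[(vapply(strsplit(shared, "\r", fixed = TRUE), `[`, "", 1L) %in%
                    target_sequences) == is_t]
    if (length(ks) < 3L)
      return(data.frame(group = if (is_t) "target" else "non_target",
                        r_squared = NA_real_, n_shared = length(ks),
                        flag = "too few shared precursors"))
    xa <- log10(pa$intensity[match(ks, key(pa))])
    xb <- log10(pb$intensity[match(ks, key(pb))])
    data.frame(group = if (is_t) "target" else "non_target",
               r_squared = stats::cor(xa, xb)^2, n_shared = length(ks),
               flag = NA_character_)
  })
  do.call(rbind, rows)
}

#' Summarize one acquisition + identification run
#'
#' Depth and target counts follow peptide-level filtering when
#' `accepted_peptides` is supplied (the convention for unique-sequence
#' counts); PSM-level metrics (PSM counts, the funnel) come from
#' `accepted`.
#'
#' @param log a `scan_log`.
#' @param accepted accepted PSMs (PSM-level FDR).
#' @param tids TID table.
#' @param target_sequences target peptides.
#' @param accepted_peptides optional peptide-level accepted table from
#'   [peptide_fdr()]; defaults to the sequences of `accepted`.
#' @return one-row data.frame of run-level metrics.
#' @export
run_summary <- function(log, accepted, tids, target_sequences,
                        accepted_peptides = NULL) {
  pep_seq <- if (is.null(accepted_peptides)) unique(accepted$sequence) else
    unique(accepted_peptides$sequence)
  depth <- length(pep_seq)
  tseq <- pep_seq[pep_seq %in% target_sequences]
  funnel <- rts_funnel(log, tids)
  if (length(tseq) > depth) stop("integrity error: targets exceed depth")
  data.frame(method = log$method, seed = log$seed,
             depth = depth, n_targets = length(tseq),
             n_target_psms = sum(accepted$sequence %in% target_sequences),
             n_events = funnel$n_events, n_hits = funnel$n_hits,
             n_tids = funnel$n_tids, hit_rate = funnel$hit_rate,
             tid_rate = funnel$tid_rate)
}

#' Default configuration for the dilution benchmark
#'
#' Problem sizes are desk-scale: the gradient is shortened and the RT
#' scheduling window and RT prediction error are scaled proportionally
#' (15/125 and 13/125 of the gradient), preserving the window's ~75%
#' target coverage; acquisition thresholds and the dilution ratios are the
#' study conditions.
#'
#' @param n_background,n_spike peptidome sizes.
#' @param gradient_min gradient length (minutes).
#' @param ratios dilution ratios (0 = negative control).
#' @param methods acquisition methods to run.
#' @param n_replicates replicates (seeds) per condition; a vector is
#'   recycled over `ratios` (e.g. more seeds at the strongest dilution).
#' @param seed master seed.
#' @param interferents_per_target isobaric interferents per inclusion entry.
#' @param compare_chimeric additionally search DDA logs without chimeric
#'   handling.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_background = 1600L, n_spike = 60L,
                             gradient_min = 4, ratios = c(1/1024, 0),
                             methods = c("DDA", "ilDDA", "NeoDiscMS"),
                             n_replicates = 3L, seed = 1L,
                             rt_sigma = 0.1,
                             interferents_per_target = 1L,
                             compare_chimeric = TRUE) {
  structure(list(n_background = n_background, n_spike = n_spike,
                 gradient_min = gradient_min, ratios = ratios,
                 methods = methods, n_replicates = n_replicates, seed = seed,
                 halfwidth_min = 15 * gradient_min / 125,
                 rt_noise_sd = 13 * gradient_min / 125,
                 rt_sigma = rt_sigma,
                 interferents_per_target = interferents_per_target,
                 compare_chimeric = compare_chimeric),
            class = "benchmark_config")
}

#' End-to-end dilution-series benchmark
#'
#' Generates background and spike peptidomes, builds the scheduled
#' inclusion list from the spike targets (measured RT plus prediction
#' error via the rt_min bypass), mixes the dilution series, adds isobaric
#' interferents, acquires every (method, ratio, replicate) combination,
#' searches each log with chimeric co-isolation handling, applies 1%
#' target-decoy FDR, and summarizes sensitivity, depth and the
#' real-time-search funnel.
#'
#' @param cfg a [benchmark_config()].
#' @param model optional [signal_model()] (gradient and profile seed are
#'   overridden from `cfg`).
#' @return list of class `comparison_report` with `summary` (per-run
#'   data.frame), `sets` (per-run accepted sequence sets), `target_sets`
#'   (per-run identified target sets), `targets` (target sequences),
#'   `chimeric` (paired chimeric on/off depths, if requested),
#'   `mass_diff` (co-isolation residual analysis) and `config`.
#' @export
benchmark_dilution <- function(cfg = benchmark_config(), model = NULL) {
  g <- cfg$gradient_min
  if (is.null(model)) model <- signal_model(gradient_min = g)
  model$gradient_min <- g
  model$profile_seed <- hash_seed(cfg$seed, "profiles")
  margin <- 5 * g / 125
  bg <- generate_peptidome(cfg$n_background, hash_seed(cfg$seed, "background"),
                           gradient_min = g, rt_margin = margin,
                           rt_sigma = cfg$rt_sigma)
  sp <- generate_peptidome(cfg$n_spike, hash_seed(cfg$seed, "spike"),
                           gradient_min = g, source = "spike",
                           target_fraction = 1, rt_margin = margin,
                           rt_sigma = cfg$rt_sigma)
  targets <- data.frame(sequence = sp$sequence, class = "target")
  targets$rt_min <- with_seed(hash_seed(cfg$seed, "rt"),
                              sp$rt_apex + stats::rnorm(nrow(sp), 0, cfg$rt_noise_sd))
  targets <- predict_rt(targets, gradient_min = g)
  sil <- schedule_targets(targets, halfwidth_min = cfg$halfwidth_min,
                          gradient_min = g)
  series <- make_dilution_series(bg, sp, cfg$ratios)
  series <- lapply(series, spike_interferents, sil = sil,
                   per_target = cfg$interferents_per_target,
                   seed = hash_seed(cfg$seed, "interferents"))
  universe <- unique(unlist(lapply(series, `[[`, "sequence")))
  universe <- unique(c(universe, sp$sequence))
  scfg <- search_config(chimeric = TRUE)
  db <- build_search_db(universe, scfg)

  summary_rows <- list(); sets <- list(); target_sets <- list()
  chim_rows <- list(); md_all <- NULL
  reps <- rep_len(cfg$n_replicates, length(cfg$ratios))
  for (ri in seq_along(cfg$ratios)) {
    ratio <- cfg$ratios[ri]
    mix <- series[[ri]]
    for (method in cfg$methods) {
      mcfg <- method_config(method)
      for (rep in seq_len(reps[ri])) {
        acq_seed <- hash_seed(cfg$seed, "acq", method, ri, rep)
        log <- run_acquisition(mix, if (method == "DDA") NULL else sil,
                               mcfg, model, acq_seed)
        psms <- search_scanlog(log, db, scfg)
        acc <- fdr_filter(psms, scfg$fdr_level)
        acc_pep <- peptide_fdr(psms, scfg$fdr_level)
        tids <- classify_tids(log, acc, sp$sequence)
        s <- run_summary(log, acc, tids, sp$sequence, acc_pep)
        s$ratio <- ratio; s$replicate <- rep
        key <- sprintf("%s|%g|%d", method, ratio, rep)
        summary_rows[[key]] <- s
        sets[[key]] <- unique(acc_pep$sequence)
        target_sets[[key]] <- unique(
          acc_pep$sequence[acc_pep$sequence %in% sp$sequence])
        if (cfg$compare_chimeric && method == "DDA") {
          scfg_off <- scfg; scfg_off$chimeric <- FALSE
          psms_off <- search_scanlog(log, db, scfg_off)
          chim_rows[[key]] <- data.frame(
            ratio = ratio, replicate = rep,
            depth_chimeric = length(unique(acc_pep$sequence)),
            depth_non_chimeric = length(unique(
              peptide_fdr(psms_off, scfg$fdr_level)$sequence)))
          md <- mass_diff_analysis(acc)
          md_all <- rbind(md_all, md$residuals)
        }
      }
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 sets = sets, target_sets = target_sets,
                 targets = sp$sequence,
                 chimeric = if (length(chim_rows)) do.call(rbind, chim_rows) else NULL,
                 mass_diff = md_all, config = cfg),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  agg <- stats::aggregate(cbind(depth, n_targets) ~ method + ratio,
                          data = x$summary, FUN = mean)
  print(agg)
  invisible(x)
}
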