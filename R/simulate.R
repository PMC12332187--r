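# Synthetic ground truth: peptidome generation, dilution-series mixing,
# MS1 observation and noisy MS2 rendering under scan-parameter-dependent
# signal quality.

.AA_LETTERS <- names(residue_masses())

.default_length_probs <- function() {
  # peaked at 9-mers over 8-14, mean ~9.5 as typical for HLA-I elutions
  c(`8` = 0.25, `9` = 0.40, `10` = 0.15, `11` = 0.08, `12` = 0.06,
    `13` = 0.04, `14` = 0.02)
}

.charge_probs_for_length <- function(len) {
  if (len <= 9L) c(0.2, 0.7, 0.1) else c(0.1, 0.65, 0.25)
}

#' Signal model for the in-silico instrument
#'
#' Calibration constants tying ground-truth abundances to observed signal:
#' ionization flux converts MS1-level intensity into ions per millisecond
#' available to an MS2 accumulation; the fragment-profile concentration
#' controls how peaked each peptide's fragment intensity pattern is
#' (Dirichlet-like, drawn once per peptide and reused so repeated scans are
#' correlated); chemical noise peaks are uniform in m/z; measurement noise
#' is Gaussian in ppm.
#'
#' @param gradient_min gradient length (minutes).
#' @param ms1_noise_floor MS1 features below this intensity are not observed.
#' @param ionization_flux ions/ms per MS1 intensity unit.
#' @param ms2_chemical_noise_peaks expected number of noise peaks per MS2.
#' @param fragment_profile_concentration Dirichlet concentration per fragment.
#' @param ms1_ppm_sd MS1 m/z measurement noise (ppm, sd).
#' @param ms2_ppm_sd fragment m/z measurement noise (ppm, sd).
#' @param mz_range observable m/z range (Th).
#' @param profile_seed seed component for per-peptide fragment profiles.
#' @return object of class `signal_model`.
#' @export
signal_model <- function(gradient_min = 125, ms1_noise_floor = 10,
                         ionization_flux = 0.05,
                         ms2_chemical_noise_peaks = 30,
                         fragment_profile_concentration = 0.8,
                         ms1_ppm_sd = 1.5, ms2_ppm_sd = 4,
                         mz_range = c(100, 2000), profile_seed = 0L) {
  stopifnot(gradient_min > 0, ms1_noise_floor > 0, ionization_flux > 0,
            ms2_chemical_noise_peaks >= 0,
            fragment_profile_concentration > 0)
  structure(list(gradient_min = gradient_min,
                 ms1_noise_floor = ms1_noise_floor,
                 ionization_flux = ionization_flux,
                 ms2_chemical_noise_peaks = ms2_chemical_noise_peaks,
                 fragment_profile_concentration = fragment_profile_concentration,
                 ms1_ppm_sd = ms1_ppm_sd, ms2_ppm_sd = ms2_ppm_sd,
                 mz_range = mz_range, profile_seed = as.integer(profile_seed)),
            class = "signal_model")
}

#' Default per-scan-type acquisition parameters
#'
#' Durations, ion-accumulation controls and isolation widths for the four
#' scan types. The high-sensitivity scan (hMS2) is five times longer than
#' the scouting scan (sMS2) and has a higher AGC target and maximum
#' injection time; discovery scans (dMS2) use the configured wide window.
#'
#' @return named list of per-scan-type parameter lists.
#' @export
default_scan_params <- function() {
  list(
    MS1 = list(duration_ms = 110),
    sMS2 = list(duration_ms = 30, max_inject_ms = 20, agc_target = 5e4,
                isolation_width = 1.2),
    hMS2 = list(duration_ms = 150, max_inject_ms = 120, agc_target = 5e5,
                isolation_width = 1.2, stepped_ce = TRUE),
    dMS2 = list(duration_ms = 40, max_inject_ms = 30, agc_target = 1e5,
                isolation_width = 3.2)
  )
}

#' Generate a synthetic immunopeptidome
#'
#' `n` unique random peptides with lengths peaked at 9 over 8-14,
#' log-normal abundances, Gaussian elution profiles with apexes uniform
#' over the usable gradient, and length-dependent charge-state priors.
#' Fully reproducible given `seed`.
#'
#' @param n number of peptides.
#' @param seed integer seed.
#' @param length_probs named probability vector over lengths.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters.
#' @param gradient_min gradient length (minutes).
#' @param rt_margin apexes are drawn from `[rt_margin, gradient - rt_margin]`.
#' @param rt_sigma elution peak sd (minutes).
#' @param target_fraction fraction of peptides flagged as targets.
#' @param source provenance label.
#' @return data.frame of class `peptidome` with one row per peptide.
#' @export
generate_peptidome <- function(n, seed = 1L,
                               length_probs = .default_length_probs(),
                               abundance_meanlog = log(1e5),
                               abundance_sdlog = 1.5,
                               gradient_min = 125, rt_margin = 5,
                               rt_sigma = 0.25, target_fraction = 0,
                               source = "background") {
  stopifnot(n >= 1)
  if (2 * rt_margin >= gradient_min)
    stop("rt_margin too large for the gradient")
  with_seed(seed, {
    lens <- sample(as.integer(names(length_probs)), n, replace = TRUE,
                   prob = length_probs)
    seqs <- vapply(lens, function(l)
      paste(sample(.AA_LETTERS, l, replace = TRUE), collapse = ""), character(1))
    tries <- 0L
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- vapply(lens[dup], function(l)
        paste(sample(.AA_LETTERS, l, replace = TRUE), collapse = ""), character(1))
      tries <- tries + 1L
      if (tries > 100L) stop("generation error: could not draw unique sequences")
    }
    cp <- t(vapply(lens, .charge_probs_for_length, numeric(3)))
    is_target <- rep(FALSE, n)
    if (target_fraction > 0)
      is_target[sample.int(n, round(n * target_fraction))] <- TRUE
    df <- data.frame(
      sequence = seqs,
      length = lens,
      abundance = stats::rlnorm(n, abundance_meanlog, abundance_sdlog),
      rt_apex = stats::runif(n, rt_margin, gradient_min - rt_margin),
      rt_sigma = rt_sigma,
      p_z1 = cp[, 1L], p_z2 = cp[, 2L], p_z3 = cp[, 3L],
      source = source,
      is_target = is_target
    )
    df$neutral_mass <- vapply(df$sequence, monoisotopic_mass, numeric(1),
                              USE.NAMES = FALSE)
    attr(df, "gradient_min") <- gradient_min
    class(df) <- c("peptidome", "data.frame")
    df
  })
}

#' Mix a dilution series
#'
#' The spike peptidome is diluted into an unchanged background: spike
#' abundances are multiplied by each ratio while the background is shared
#' identically across all mixtures; ratio 0 is the spike-free negative
#' control. Spike sequences colliding with the background are dropped with
#' a warning.
#'
#' @param background,spike peptidomes from [generate_peptidome()].
#' @param ratios spike:background dilution factors.
#' @return named list of `sample_mixture` data.frames (attribute `ratio`).
#' @export
make_dilution_series <- function(background, spike,
                                 ratios = c(1/16, 1/64, 1/256, 1/1024, 0)) {
  if (any(ratios < 0)) stop("domain error: negative dilution ratio")
  clash <- spike$sequence %in% background$sequence
  if (any(clash)) {
    warning(sum(clash), " spike sequence(s) collide with background; dropped")
    spike <- spike[!clash, , drop = FALSE]
  }
  spike$is_target <- TRUE
  out <- lapply(ratios, function(r) {
    if (r == 0) {
      mix <- background
    } else {
      sp <- spike
      sp$abundance <- sp$abundance * r
      mix <- rbind(as.data.frame(background), as.data.frame(sp))
    }
    attr(mix, "gradient_min") <- attr(background, "gradient_min")
    attr(mix, "ratio") <- r
    class(mix) <- c("sample_mixture", "peptidome", "data.frame")
    mix
  })
  names(out) <- ifelse(ratios == 0, "0", paste0("1/", round(1 / ratios)))
  out
}

#' Observe MS1 features at a time point
#'
#' Each peptide's elution intensity `abundance * exp(-(t-apex)^2/(2*sigma^2))`
#' is partitioned across charges 1-3 by its charge priors; features below
#' the noise floor are not observed. m/z carries Gaussian ppm measurement
#' noise. Deterministic given `seed` and `t`.
#'
#' @param mixture a `sample_mixture` (or `peptidome`).
#' @param t time (minutes).
#' @param model a [signal_model()].
#' @param seed integer seed.
#' @return data.frame with `sequence`, `z`, `mz`, `intensity`,
#'   `neutral_mass`, `is_target`, `source`.
#' @export
ms1_observe <- function(mixture, t, model = signal_model(), seed = 1L) {
  g <- exp(-((t - mixture$rt_apex)^2) / (2 * mixture$rt_sigma^2))
  base <- mixture$abundance * g
  pz <- cbind(mixture$p_z1, mixture$p_z2, mixture$p_z3)
  rows <- vector("list", 3L)
  for (z in 1:3) {
    inten <- base * pz[, z]
    keep <- inten >= model$ms1_noise_floor
    if (!any(keep)) next
    rows[[z]] <- data.frame(
      sequence = mixture$sequence[keep],
      z = z,
      mz_true = precursor_mz(mixture$neutral_mass[keep], z),
      intensity = inten[keep],
      neutral_mass = mixture$neutral_mass[keep],
      is_target = mixture$is_target[keep],
      source = mixture$source[keep]
    )
  }
  feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(feats))
    return(data.frame(sequence = character(), z = integer(), mz = numeric(),
                      intensity = numeric(), neutral_mass = numeric(),
                      is_target = logical(), source = character()))
  feats <- feats[order(feats$sequence, feats$z), , drop = FALSE]
  feats$mz <- with_seed(seed, feats$mz_true *
                          (1 + stats::rnorm(nrow(feats)) * model$ms1_ppm_sd * 1e-6))
  feats$mz_true <- NULL
  rownames(feats) <- NULL
  feats[, c("sequence", "z", "mz", "intensity", "neutral_mass",
            "is_target", "source")]
}

# Per-peptide fragment intensity profile over the 2(L-1) singly charged
# b/y fragments, drawn once per (profile_seed, sequence) from a Dirichlet
# with the configured concentration and reused across scans.
.fragment_profile <- function(sequence, model) {
  key <- paste("prof", model$profile_seed, sequence,
               model$fragment_profile_concentration, sep = "\r")
  .cache_get(key, function() {
    L <- nchar(sequence)
    k <- 2L * (L - 1L)
    with_seed(hash_seed("fragment-profile", model$profile_seed, sequence), {
      w <- stats::rgamma(k, shape = model$fragment_profile_concentration)
      if (sum(w) == 0) w <- rep(1, k)
      w / sum(w)
    })
  })
}

#' Simulate an MS2 spectrum for an isolation window
#'
#' All precursors whose m/z falls inside the window contribute fragments
#' (chimeric co-isolation). The total number of ions collected is
#' `min(agc_target, flux_in_window * max_inject_ms)`; each contributing
#' peptide's share is proportional to its flux, spread over its fixed
#' fragment profile with Poisson shot noise. Uniform chemical noise peaks
#' are appended.
#'
#' @param window_center isolation window center (Th).
#' @param isolation_width window width (Th).
#' @param mixture a `sample_mixture`.
#' @param t time (minutes).
#' @param sp scan parameter list (see [default_scan_params()]), needs
#'   `max_inject_ms` and `agc_target`.
#' @param model a [signal_model()].
#' @param seed integer seed.
#' @param precursor_charge charge annotation for the returned peak list.
#' @return a [peaklist()].
#' @export
simulate_ms2 <- function(window_center, isolation_width, mixture, t, sp,
                         model = signal_model(), seed = 1L,
                         precursor_charge = NA_integer_) {
  if (isolation_width <= 0) stop("isolation width must be > 0")
  half <- isolation_width / 2
  g <- exp(-((t - mixture$rt_apex)^2) / (2 * mixture$rt_sigma^2))
  base <- mixture$abundance * g
  pz <- cbind(mixture$p_z1, mixture$p_z2, mixture$p_z3)
  # flux per peptide summed over its charges inside the window
  flux <- numeric(nrow(mixture))
  proton <- 1.007276
  for (z in 1:3) {
    mzz <- (mixture$neutral_mass + z * proton) / z
    inside <- abs(mzz - window_center) <= half
    flux <- flux + base * pz[, z] * model$ionization_flux * inside
  }
  contrib <- which(flux > 1e-9)
  with_seed(seed, {
    mzs <- numeric(); ints <- numeric()
    if (length(contrib)) {
      total_flux <- sum(flux[contrib])
      n_ions <- min(sp$agc_target, total_flux * sp$max_inject_ms)
      for (j in contrib) {
        seqj <- mixture$sequence[j]
        prof <- .fragment_profile(seqj, model)
        ions_j <- n_ions * flux[j] / total_flux
        counts <- stats::rpois(length(prof), ions_j * prof)
        nz <- counts > 0
        if (!any(nz)) next
        fr <- .cache_get(paste("fr1", seqj, sep = "\r"),
                         function() fragment_mzs(peptidoform(seqj, charge = 1L), 1L))
        fmz <- fr$mz[nz] * (1 + stats::rnorm(sum(nz)) * model$ms2_ppm_sd * 1e-6)
        mzs <- c(mzs, fmz)
        ints <- c(ints, counts[nz])
      }
    }
    n_noise <- stats::rpois(1L, model$ms2_chemical_noise_peaks)
    if (n_noise > 0) {
      mzs <- c(mzs, stats::runif(n_noise, model$mz_range[1L], model$mz_range[2L]))
      ints <- c(ints, 1 + stats::rpois(n_noise, 2))
    }
    peaklist(mzs, ints, precursor_mz = window_center,
             precursor_charge = precursor_charge)
  })
}

# Build an exact isobar of a residue multiset that is not a plain anagram
# where possible: apply a mass-exact composition rewrite (N <-> GG,
# Q <-> AG; both identities hold to ~1e-6 Da) and shuffle. A plain shuffle
# is the fallback when no rewrite applies. Anagrams share too many partial
# residue sums with the original; the rewrite diversifies the fragment
# ladder while keeping the precursor mass exact, as real-world isobaric
# non-targets do.
.isobar_of <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  rewrites <- list()
  if (any(chars == "N"))
    rewrites <- c(rewrites, list(function(ch) c(ch[-match("N", ch)], "G", "G")))
  if (sum(chars == "G") >= 2L)
    rewrites <- c(rewrites, list(function(ch) c(ch[-which(ch == "G")[1:2]], "N")))
  if (any(chars == "Q"))
    rewrites <- c(rewrites, list(function(ch) c(ch[-match("Q", ch)], "A", "G")))
  if (any(chars == "A") && any(chars == "G"))
    rewrites <- c(rewrites, list(function(ch)
      c(ch[-c(match("A", ch), match("G", ch))], "Q")))
  if (length(rewrites))
    chars <- rewrites[[sample.int(length(rewrites), 1L)]](chars)
  paste(sample(chars), collapse = "")
}

#' Spike isobaric interferents around inclusion-list entries
#'
#' For each scheduled target sequence, adds `per_target` non-target
#' peptides exactly isobaric with the target (mass-exact composition
#' rewrites plus residue rearrangement, so the precursor m/z matches the
#' entry at every charge state within any tolerance), eluting uniformly
#' within the entry's RT window. A single interferent per target is used
#' (rather than one per charge-state entry) because an isobaric analyte
#' shares the target's full charge envelope. Targets for which no distinct
#' isobar can be found within bounded attempts are skipped with a warning.
#'
#' @param mixture a `sample_mixture`.
#' @param sil inclusion list from [schedule_targets()].
#' @param per_target interferents per target sequence.
#' @param tol_ppm tolerance the interferent must satisfy (checked; the
#'   construction is exact).
#' @param seed integer seed.
#' @param abundance_meanlog,abundance_sdlog interferent abundance law.
#' @return the mixture with interferent rows appended (`source =
#'   "interferent"`).
#' @export
spike_interferents <- function(mixture, sil, per_target = 1L, tol_ppm = 10,
                               seed = 1L, abundance_meanlog = log(1e5),
                               abundance_sdlog = 1) {
  stopifnot(per_target >= 0)
  if (per_target == 0L || nrow(sil) == 0L) return(mixture)
  gradient <- attr(mixture, "gradient_min")
  if (is.null(gradient)) gradient <- max(sil$t_stop)
  entries <- sil[sil$mods == "", , drop = FALSE]
  # one representative entry per target sequence (prefer 2+, the most
  # common immunopeptide charge)
  entries <- entries[order(entries$sequence, abs(entries$z - 2L)), , drop = FALSE]
  entries <- entries[!duplicated(entries$sequence), , drop = FALSE]
  taken <- c(mixture$sequence, unique(sil$sequence))
  with_seed(seed, {
    new_rows <- list()
    for (i in seq_len(nrow(entries))) {
      e <- entries[i, ]
      fr_t <- fragment_mzs(peptidoform(e$sequence, charge = 1L), 1L)
      for (k in seq_len(per_target)) {
        # prefer isobars sharing few fragment m/z with the target, as
        # unrelated real-world isobars do; keep the least-overlapping
        # candidate if none falls below the overlap ceiling
        cand <- NULL; best_ov <- Inf
        for (att in seq_len(50L)) {
          s <- .isobar_of(e$sequence)
          if (s == e$sequence || s %in% taken) next
          st <- .match_stats(peaklist(fr_t$mz, rep(1, nrow(fr_t))),
                             fragment_mzs(peptidoform(s, charge = 1L), 1L), 20)
          ov <- mean(st$matched)
          if (ov < best_ov) { best_ov <- ov; cand <- s }
          if (ov <= 0.3) break
        }
        if (is.null(cand)) {
          warning("no isobaric rearrangement found for ", e$sequence, "; skipped")
          next
        }
        m <- monoisotopic_mass(cand)
        if (abs(delta_ppm(precursor_mz(m, e$z), e$mz)) > tol_ppm) next
        taken <- c(taken, cand)
        len <- nchar(cand)
        cpz <- numeric(3); cpz[e$z] <- 0.8
        cpz[-e$z] <- 0.2 / 2
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          sequence = cand, length = len,
          abundance = stats::rlnorm(1L, abundance_meanlog, abundance_sdlog),
          rt_apex = stats::runif(1L, max(0, e$t_start), min(gradient, e$t_stop)),
          rt_sigma = mixture$rt_sigma[1L],
          p_z1 = cpz[1L], p_z2 = cpz[2L], p_z3 = cpz[3L],
          source = "interferent", is_target = FALSE,
          neutral_mass = m
        )
      }
    }
    if (length(new_rows)) {
      out <- rbind(as.data.frame(mixture), do.call(rbind, new_rows))
      attr(out, "gradient_min") <- attr(mixture, "gradient_min")
      attr(out, "ratio") <- attr(mixture, "ratio")
      class(out) <- class(mixture)
      out
    } else mixture
  })
}
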