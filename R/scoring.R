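# Spectrum scoring: binning, fast cross-correlation (SEQUEST/Comet
# convention), dCn, ppm error, fragment matching, hyperscore, normalized
# spectral contrast angle, and the real-time-search filter predicate.
#
# The vendor real-time search is closed source; the reconstruction here
# follows the published fast cross-correlation identity: unit bins of
# 1.0005079 Da, square-rooted intensities, 10-segment regional
# normalization to 50, and background subtraction over +/-75 bins.

.XCORR_BIN <- 1.0005079
.XCORR_MAX_MZ <- 2500
.XCORR_BG_HALF <- 75L       # background mean over tau = -75..+75 (1/151)
.XCORR_THEO_MAIN <- 50
.XCORR_THEO_FLANK <- 25
.XCORR_DIVISOR <- 1e4

# package-level memo cache for theoretical spectra / fragment tables
.ipasim_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, fn) {
  v <- .ipasim_cache[[key]]
  if (is.null(v)) {
    v <- fn()
    .ipasim_cache[[key]] <- v
  }
  v
}

#' Construct a peak list
#'
#' An MS2 (or MS1) peak list with optional precursor annotation. Peaks are
#' sorted by m/z; duplicate m/z values are merged by summing intensities so
#' the m/z vector is strictly increasing.
#'
#' @param mz numeric m/z values (Th).
#' @param intensity non-negative intensities.
#' @param precursor_mz,precursor_charge precursor annotation (optional).
#' @return object of class `peaklist`.
#' @export
peaklist <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity,
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge)),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %d peaks, precursor %.4f (%s+)\n",
              length(x$mz), x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  invisible(x)
}

#' Bin a peak list onto the cross-correlation grid
#'
#' Intensities are square-rooted, assigned to bins by `round(mz /
#' bin_width)`, and colliding peaks keep the maximum.
#'
#' @param pl a [peaklist()].
#' @param bin_width bin width in Da (SEQUEST convention 1.0005079).
#' @param max_mz upper end of the binned range.
#' @return object of class `binned_spectrum` with fields `values`,
#'   `bin_width`, `max_mz`.
#' @export
bin_spectrum <- function(pl, bin_width = .XCORR_BIN, max_mz = .XCORR_MAX_MZ) {
  if (length(pl$mz) == 0L) stop("empty spectrum: no peaks to bin")
  n <- as.integer(round(max_mz / bin_width)) + 1L
  idx <- as.integer(round(pl$mz / bin_width)) + 1L
  keep <- idx >= 1L & idx <= n
  values <- numeric(n)
  if (any(keep)) {
    sq <- sqrt(pl$intensity[keep])
    ik <- idx[keep]
    o <- order(sq)           # ascending, so the last write per bin is the max
    values[ik[o]] <- sq[o]
  }
  structure(list(values = values, bin_width = bin_width, max_mz = max_mz),
            class = "binned_spectrum")
}

#' Regional normalization of a binned spectrum
#'
#' The binned range is split into 10 equal-width segments and each segment
#' is scaled so its maximum is 50; all-zero segments are untouched.
#'
#' @param bs a `binned_spectrum`.
#' @return normalized `binned_spectrum`.
#' @export
region_normalize <- function(bs) {
  y <- bs$values
  n <- length(y)
  seg <- ceiling(n / 10)
  for (s in seq_len(10L)) {
    lo <- (s - 1L) * seg + 1L
    hi <- min(s * seg, n)
    if (lo > hi) break
    m <- max(y[lo:hi])
    if (m > 0) y[lo:hi] <- y[lo:hi] * (.XCORR_THEO_MAIN / m)
  }
  bs$values <- y
  bs
}

#' Full cross-correlation preprocessing
#'
#' Regional normalization followed by background subtraction:
#' `y'[i] = y[i] - (1/151) * sum_{tau=-75..75} y[i+tau]`, zero-padded at the
#' edges. The subtraction makes the plain dot product with a theoretical
#' spectrum equal to the offset-corrected cross-correlation.
#'
#' @param bs a `binned_spectrum`.
#' @return preprocessed `binned_spectrum`.
#' @export
xcorr_preprocess <- function(bs) {
  bs <- region_normalize(bs)
  y <- bs$values
  n <- length(y)
  h <- .XCORR_BG_HALF
  w <- 2L * h + 1L
  pad <- c(numeric(h), y, numeric(h))
  cs <- cumsum(pad)
  win <- cs[w:(n + w - 1L)] - c(0, cs[seq_len(n - 1L)])
  bs$values <- y - win / w
  bs
}

#' Theoretical sparse spectrum of a peptidoform
#'
#' Value 50 at every b/y fragment bin and 25 at the two flanking bins,
#' max-combined on collisions.
#'
#' @param p a [peptidoform()].
#' @param bin_width,max_mz binning grid (must match the observed spectrum).
#' @param max_frag_charge maximum fragment charge.
#' @return data.frame with `idx` (bin index) and `val`.
#' @export
theoretical_peaks <- function(p, bin_width = .XCORR_BIN,
                              max_mz = .XCORR_MAX_MZ, max_frag_charge = 1L) {
  key <- paste("theo", p$sequence, mod_signature(p$mods),
               min(max_frag_charge, p$charge), bin_width, max_mz, sep = "\r")
  .cache_get(key, function() {
    fr <- fragment_mzs(p, max_frag_charge)
    n <- as.integer(round(max_mz / bin_width)) + 1L
    ctr <- as.integer(round(fr$mz / bin_width)) + 1L
    idx <- c(ctr, ctr - 1L, ctr + 1L)
    val <- c(rep(.XCORR_THEO_MAIN, length(ctr)),
             rep(.XCORR_THEO_FLANK, 2L * length(ctr)))
    keep <- idx >= 1L & idx <= n
    idx <- idx[keep]; val <- val[keep]
    mx <- tapply(val, idx, max)
    data.frame(idx = as.integer(names(mx)), val = as.numeric(mx))
  })
}

#' Fast cross-correlation score
#'
#' Dot product of the theoretical sparse spectrum with a preprocessed
#' observed spectrum, divided by 10^4.
#'
#' @param p a [peptidoform()].
#' @param bs_pre observed `binned_spectrum`, already passed through
#'   [xcorr_preprocess()].
#' @param max_frag_charge maximum fragment charge for the theoretical side.
#' @return unitless score.
#' @export
xcorr <- function(p, bs_pre, max_frag_charge = 1L) {
  tp <- theoretical_peaks(p, bs_pre$bin_width, bs_pre$max_mz, max_frag_charge)
  sum(tp$val * bs_pre$values[tp$idx]) / .XCORR_DIVISOR
}

#' Normalized score drop between best and runner-up candidates
#'
#' `(X1 - X2) / X1` for a positive best score; 1.0 for a single candidate
#' (a lone confident hit must not be rejected for lack of a runner-up);
#' 0.0 when the best score is non-positive.
#'
#' @param xcorrs candidate scores (any order).
#' @return dCn in `[0, 1]` under the usual conditions.
#' @export
delta_cn <- function(xcorrs) {
  if (length(xcorrs) == 0L) stop("no candidates: cannot compute dCn")
  s <- sort(xcorrs, decreasing = TRUE)
  if (s[1L] <= 0) return(0)
  if (length(s) == 1L) return(1)
  (s[1L] - s[2L]) / s[1L]
}

#' Signed relative mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z in Th.
#' @return `(observed - theoretical) / theoretical * 1e6` (signed; filters
#'   take the absolute value).
#' @export
delta_ppm <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("domain error: theoretical m/z must be > 0")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

# Fast fragment-matching core shared by match_fragments(), the hyperscore
# path and the spectral angle: returns matched peak intensities per
# fragment (0 if unmatched) plus per-series counts and sums, without
# building data.frames.
.match_stats <- function(pl, frags, tol_ppm) {
  nf <- nrow(frags)
  np <- length(pl$mz)
  obs <- numeric(nf)
  peak_mz <- rep(NA_real_, nf)
  matched <- logical(nf)
  if (np > 0L && nf > 0L) {
    i <- findInterval(frags$mz, pl$mz)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, np)
    best <- hi
    use_lo <- abs(frags$mz - pl$mz[lo]) <= abs(frags$mz - pl$mz[hi])
    best[use_lo] <- lo[use_lo]   # exact ties prefer the lower-m/z peak
    dist <- abs(frags$mz - pl$mz[best])
    # closed interval; tiny relative slack keeps the boundary robust to
    # floating-point representation of the tolerance itself
    matched <- dist <= frags$mz * tol_ppm * 1e-6 * (1 + 1e-9)
    obs[matched] <- pl$intensity[best[matched]]
    peak_mz[matched] <- pl$mz[best[matched]]
  }
  is_b <- frags$series == "b"
  list(obs = obs, matched = matched, peak_mz = peak_mz,
       n_b = sum(matched & is_b), n_y = sum(matched & !is_b),
       sum_I_b = sum(obs[matched & is_b]), sum_I_y = sum(obs[matched & !is_b]))
}

#' Match theoretical fragments against an observed peak list
#'
#' Each theoretical fragment is matched to the nearest observed peak within
#' `tol_ppm` (closed interval; exact distance ties prefer the lower-m/z
#' peak). One observed peak may satisfy several fragments when their windows
#' overlap it.
#'
#' @param pl observed [peaklist()].
#' @param frags data.frame from [fragment_mzs()].
#' @param tol_ppm matching tolerance in ppm.
#' @return list with `matches` (frags plus `peak_mz`, `peak_intensity`,
#'   `matched`), per-series counts `n_b`, `n_y` and intensity sums
#'   `sum_I_b`, `sum_I_y`.
#' @export
match_fragments <- function(pl, frags, tol_ppm = 20) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  st <- .match_stats(pl, frags, tol_ppm)
  matches <- cbind(frags,
                   data.frame(peak_mz = st$peak_mz,
                              peak_intensity = ifelse(st$matched, st$obs, NA_real_),
                              matched = st$matched))
  list(matches = matches, n_b = st$n_b, n_y = st$n_y,
       sum_I_b = st$sum_I_b, sum_I_y = st$sum_I_y)
}

#' Hyperscore from matched fragment counts and intensity sums
#'
#' `ln(n_b! * n_y! * max(sum_I_b, 1) * max(sum_I_y, 1))` with factorial
#' arguments capped at 64; 0 when nothing matched.
#'
#' @param n_b,n_y matched b/y fragment counts.
#' @param sum_I_b,sum_I_y matched intensity sums.
#' @return unitless score.
#' @export
#' @examples
#' hyperscore(2, 2, 100, 100) # log(40000)
hyperscore <- function(n_b, n_y, sum_I_b, sum_I_y) {
  if (n_b < 0 || n_y < 0) stop("domain error: negative fragment counts")
  if (n_b + n_y == 0) return(0)
  lfactorial(min(n_b, 64L)) + lfactorial(min(n_y, 64L)) +
    log(max(sum_I_b, 1)) + log(max(sum_I_y, 1))
}

#' Normalized spectral contrast angle
#'
#' Cosine similarity of square-rooted intensities over the theoretical
#' fragment positions (unmatched theoretical position contributes an
#' observed 0; observed peaks off the theoretical positions are ignored),
#' mapped to `1 - (2/pi) * acos(cos theta)` in `[0, 1]`. The theoretical
#' side is flat (equal weight per fragment).
#'
#' @param pl observed [peaklist()].
#' @param p a [peptidoform()].
#' @param tol_ppm fragment matching tolerance.
#' @param max_frag_charge maximum fragment charge.
#' @return value in `[0, 1]`; 0 for a zero-norm observed vector.
#' @export
spectral_angle <- function(pl, p, tol_ppm = 20, max_frag_charge = 1L) {
  frags <- fragment_mzs(p, max_frag_charge)
  st <- .match_stats(pl, frags, tol_ppm)
  v <- sqrt(st$obs)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  cth <- sum(v) / (nv * sqrt(length(v)))
  cth <- min(max(cth, -1), 1)
  1 - (2 / pi) * acos(cth)
}

#' Real-time-search filter configuration
#'
#' Thresholds applied to a scouting-scan PSM before a high-sensitivity scan
#' is triggered. `max_search_ms` is carried as metadata only (on the
#' instrument the search runs during the next scan's fill time).
#'
#' @param xcorr_min minimum cross-correlation (default 0.4).
#' @param dcn_min minimum dCn (default 0).
#' @param ppm_max maximum absolute precursor mass error in ppm (default 5).
#' @param charges admissible charge states.
#' @param max_search_ms real-time search time cap, metadata.
#' @return object of class `rts_filter_config`.
#' @export
rts_filter_config <- function(xcorr_min = 0.4, dcn_min = 0, ppm_max = 5,
                              charges = 1:3, max_search_ms = 40) {
  stopifnot(xcorr_min >= 0, dcn_min >= 0, ppm_max >= 0)
  structure(list(xcorr_min = xcorr_min, dcn_min = dcn_min, ppm_max = ppm_max,
                 charges = as.integer(charges), max_search_ms = max_search_ms),
            class = "rts_filter_config")
}

#' Real-time-search filter predicate
#'
#' @param s list (or one-row data.frame) with `xcorr`, `dcn`, `delta_ppm`
#'   and `charge`.
#' @param cfg an [rts_filter_config()].
#' @return `TRUE` iff all thresholds pass.
#' @export
rtsf_pass <- function(s, cfg) {
  isTRUE(s$xcorr >= cfg$xcorr_min &&
           s$dcn >= cfg$dcn_min &&
           abs(s$delta_ppm) <= cfg$ppm_max &&
           as.integer(s$charge) %in% cfg$charges)
}
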