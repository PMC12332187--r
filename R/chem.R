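# Peptide chemistry: residue masses, peptidoforms, precursor m/z and
# theoretical b/y fragments. Monoisotopic masses only; no isotope envelopes.

.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047679, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)

.PROTON <- 1.007276
.WATER  <- 18.010565
.MET_OX <- 15.994915

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' @return named numeric vector, one-letter code to residue mass in Da.
#' @export
residue_masses <- function() .AA_MONO

#' Fixed mass constants
#'
#' Proton and water monoisotopic masses, and the methionine-oxidation mass
#' shift, all in Da.
#'
#' @return named list with `proton`, `water`, `met_ox`.
#' @export
mass_constants <- function() {
  list(proton = .PROTON, water = .WATER, met_ox = .MET_OX)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(.AA_MONO))
  if (length(bad))
    stop("alphabet error: unknown residue letter(s): ",
         paste(unique(bad), collapse = ", "))
  chars
}

#' Construct a peptidoform
#'
#' A peptide sequence with variable modifications (position/delta pairs) and a
#' precursor charge. Methionine oxidation (+15.994915 Da) is only allowed on
#' M residues; other deltas are accepted at any position so future
#' modifications need no type change.
#'
#' @param sequence uppercase string over the 20-letter amino-acid alphabet.
#' @param mods `NULL` or a data.frame with columns `pos` (1-based) and
#'   `delta` (Da).
#' @param charge integer precursor charge (>= 1).
#' @return object of class `peptidoform`.
#' @export
#' @examples
#' peptidoform("SIINFEKM", mods = data.frame(pos = 8, delta = 15.994915),
#'             charge = 2)
peptidoform <- function(sequence, mods = NULL, charge = 2L) {
  chars <- .check_sequence(sequence)
  if (is.null(mods)) mods <- data.frame(pos = integer(), delta = numeric())
  if (!all(c("pos", "delta") %in% names(mods)))
    stop("mods must have columns 'pos' and 'delta'")
  mods <- data.frame(pos = as.integer(mods$pos), delta = as.numeric(mods$delta))
  if (nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > length(chars)))
      stop("modification error: position outside sequence")
    if (anyDuplicated(mods$pos))
      stop("modification error: duplicated position")
    ox <- abs(mods$delta - .MET_OX) < 1e-6
    if (any(ox & chars[mods$pos] != "M"))
      stop("modification error: Met oxidation on a non-M residue")
    mods <- mods[order(mods$pos), , drop = FALSE]
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  structure(list(sequence = sequence, mods = mods, charge = charge),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  sig <- mod_signature(x$mods)
  cat(sprintf("<peptidoform> %s%s %d+\n", x$sequence,
              if (nzchar(sig)) paste0(" [", sig, "]") else "", x$charge))
  invisible(x)
}

#' Modification signature string
#'
#' Canonical `pos:delta` representation used in compound ids and tables;
#' empty string for the unmodified form.
#'
#' @param mods data.frame with `pos` and `delta`.
#' @return character scalar, e.g. `"3:+15.994915"`.
#' @export
mod_signature <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  mods <- mods[order(mods$pos), , drop = FALSE]
  paste(sprintf("%d:%+.6f", as.integer(mods$pos), mods$delta), collapse = ";")
}

#' Parse a modification signature back into a data.frame
#'
#' @param sig signature as produced by [mod_signature()].
#' @return data.frame with `pos` and `delta`.
#' @export
parse_mod_signature <- function(sig) {
  if (is.na(sig) || !nzchar(sig)) return(data.frame(pos = integer(), delta = numeric()))
  parts <- strsplit(sig, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(kv, `[`, "", 1L)),
             delta = as.numeric(vapply(kv, `[`, "", 2L)))
}

#' Monoisotopic neutral mass of a peptidoform
#'
#' Sum of residue masses plus water plus modification deltas.
#'
#' @param p a [peptidoform()] or a plain sequence string.
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("GG") # 132.05349
monoisotopic_mass <- function(p) {
  if (is.character(p)) p <- peptidoform(p, charge = 1L)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  sum(.AA_MONO[chars]) + .WATER + sum(p$mods$delta)
}

#' Precursor m/z from neutral mass and charge
#'
#' @param neutral_mass neutral monoisotopic mass in Da (vectorised).
#' @param charge positive integer charge (vectorised).
#' @return m/z in Th.
#' @export
#' @examples
#' precursor_mz(1000, 2) # 501.003638
precursor_mz <- function(neutral_mass, charge) {
  if (any(charge <= 0)) stop("domain error: charge must be >= 1")
  (neutral_mass + charge * .PROTON) / charge
}

#' Theoretical b/y fragment ions
#'
#' Singly to `max_frag_charge`-charged b and y ions with ordinals
#' `1..L-1`. Modifications on prefix residues shift b ions, on suffix
#' residues y ions. Fragment charge is additionally capped at the precursor
#' charge.
#'
#' @param p a [peptidoform()].
#' @param max_frag_charge maximum fragment charge to emit.
#' @return data.frame with `series`, `ordinal`, `charge`, `mz`.
#' @export
fragment_mzs <- function(p, max_frag_charge = 1L) {
  if (is.character(p)) p <- peptidoform(p, charge = 1L)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) stop("degenerate peptide: length < 2")
  res <- unname(.AA_MONO[chars])
  if (nrow(p$mods)) res[p$mods$pos] <- res[p$mods$pos] + p$mods$delta
  prefix <- cumsum(res)
  total <- prefix[L]
  ord <- seq_len(L - 1L)
  b_neutral <- prefix[ord]
  y_neutral <- total - prefix[L - ord] + .WATER
  zmax <- max(1L, min(as.integer(max_frag_charge), p$charge))
  out <- vector("list", zmax)
  for (z in seq_len(zmax)) {
    out[[z]] <- data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      ordinal = c(ord, ord),
      charge = z,
      mz = c((b_neutral + z * .PROTON) / z, (y_neutral + z * .PROTON) / z)
    )
  }
  do.call(rbind, out)
}

.mod_subsets <- function(sites, max_mods) {
  subsets <- list(integer())
  k_max <- min(length(sites), max_mods)
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) {
      cmb <- utils::combn(seq_along(sites), k, simplify = FALSE)
      subsets <- c(subsets, lapply(cmb, function(ii) sites[ii]))
    }
  }
  subsets
}

#' Enumerate precursors of a sequence over variable modifications and charges
#'
#' Builds the cartesian product of modification-site subsets (up to
#' `max_mods` sites) with the requested charge states, in deterministic
#' order: the unmodified form first, then subsets by size and position tuple,
#' each with charges ascending.
#'
#' @param sequence peptide sequence.
#' @param varmods list with `residue` (one-letter code carrying the variable
#'   modification) and `delta` (Da). Default: methionine oxidation.
#' @param max_mods maximum number of simultaneous modifications.
#' @param charges integer vector of charge states.
#' @return data.frame with `sequence`, `mods` (signature), `n_mods`,
#'   `charge`, `neutral_mass`, `mz`, `compound_id`.
#' @export
#' @examples
#' nrow(enumerate_precursors("SIINFEKM")) # 2 forms x 3 charges = 6
enumerate_precursors <- function(sequence,
                                 varmods = list(residue = "M", delta = 15.994915),
                                 max_mods = 3L, charges = 1:3) {
  chars <- .check_sequence(sequence)
  sites <- if (is.null(varmods)) integer() else which(chars == varmods$residue)
  subsets <- .mod_subsets(sites, max_mods)
  charges <- sort(unique(as.integer(charges)))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    pos <- subsets[[i]]
    mods <- data.frame(pos = pos, delta = rep(varmods$delta, length(pos)))
    sig <- mod_signature(mods)
    mass <- monoisotopic_mass(peptidoform(sequence, mods, charge = 1L))
    rows[[i]] <- data.frame(
      sequence = sequence,
      mods = sig,
      n_mods = length(pos),
      charge = charges,
      neutral_mass = mass,
      mz = precursor_mz(mass, charges),
      compound_id = if (nzchar(sig)) paste0(sequence, "[", sig, "]") else sequence
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
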