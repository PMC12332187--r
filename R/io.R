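# Readers/writers for the plain-text formats the simulator exchanges:
# peptide FASTA (one record per peptide, class annotation in the header),
# MGF peak lists, and target/ground-truth TSV tables.

#' Write a peptide FASTA file
#'
#' One record per peptide; headers follow `pep_<n> class=<label>`.
#' Duplicate sequences are collapsed with a warning.
#'
#' @param targets data.frame with `sequence` and optionally `class`.
#' @param path output file.
#' @return invisibly, the number of records written.
#' @export
write_peptide_fasta <- function(targets, path) {
  if (nrow(targets) == 0L) stop("no target peptides to write")
  cls <- if ("class" %in% names(targets)) as.character(targets$class) else
    rep("other", nrow(targets))
  dup <- duplicated(targets$sequence)
  if (any(dup)) {
    warning(sum(dup), " duplicate sequence(s) collapsed")
    cls <- cls[!dup]
    targets <- targets[!dup, , drop = FALSE]
  }
  seqs <- Biostrings::AAStringSet(targets$sequence)
  names(seqs) <- sprintf("pep_%04d class=%s", seq_len(length(seqs)), cls)
  tryCatch(Biostrings::writeXStringSet(seqs, filepath = path),
           error = function(e) stop("failed to write FASTA '", path, "': ",
                                    conditionMessage(e)))
  invisible(length(seqs))
}

#' Read a peptide FASTA file
#'
#' @param path FASTA file written by [write_peptide_fasta()] (or compatible).
#' @return data.frame with `id`, `sequence`, `class` (NA when the header
#'   carries no class annotation).
#' @export
read_peptide_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  id <- vapply(strsplit(hdr, "\\s+"), `[`, "", 1L)
  cls <- rep(NA_character_, length(hdr))
  m <- regmatches(hdr, regexpr("class=\\S+", hdr))
  has <- grepl("class=", hdr)
  cls[has] <- sub("^class=", "", m)
  data.frame(id = id, sequence = as.character(seqs), class = cls)
}

#' Read a target peptide TSV
#'
#' Expects at least a `sequence` column; optional `class`, rank columns and
#' `rt_min` pass through untouched.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_target_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sequence" %in% names(df))
    stop("schema error: target table needs a 'sequence' column")
  df
}

#' Write peak lists to an MGF file
#'
#' @param peaklists named list of [peaklist()] objects; names become TITLEs.
#' @param path output file.
#' @return invisibly, the number of spectra written.
#' @export
write_mgf <- function(peaklists, path) {
  con <- file(path, "w")
  on.exit(close(con))
  titles <- names(peaklists)
  if (is.null(titles)) titles <- sprintf("spectrum_%d", seq_along(peaklists))
  for (i in seq_along(peaklists)) {
    pl <- peaklists[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", titles[i]), con)
    writeLines(sprintf("PEPMASS=%.6f", pl$precursor_mz), con)
    if (!is.na(pl$precursor_charge))
      writeLines(sprintf("CHARGE=%d+", pl$precursor_charge), con)
    if (length(pl$mz))
      writeLines(sprintf("%.6f %.6f", pl$mz, pl$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(length(peaklists))
}

#' Read an MGF file
#'
#' @param path MGF file.
#' @return named list of [peaklist()] objects (names from TITLE).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      title <- NA_character_; pm <- NA_real_; z <- NA_integer_
      mzs <- numeric(); ints <- numeric()
      i <- i + 1L
      while (i <= length(lines) && lines[i] != "END IONS") {
        ln <- lines[i]
        if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
        else if (startsWith(ln, "PEPMASS=")) pm <- as.numeric(sub("^PEPMASS=", "", ln))
        else if (startsWith(ln, "CHARGE=")) z <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "[ \t]+")[[1L]])
          mzs <- c(mzs, xy[1L]); ints <- c(ints, xy[2L])
        }
        i <- i + 1L
      }
      pl <- peaklist(mzs, ints, precursor_mz = pm, precursor_charge = z)
      out[[if (is.na(title)) length(out) + 1L else title]] <- pl
    }
    i <- i + 1L
  }
  out
}

#' Write a ground-truth peptide table
#'
#' @param peptidome data.frame from [generate_peptidome()] or a mixture.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_ground_truth_tsv <- function(peptidome, path) {
  cols <- intersect(c("sequence", "abundance", "rt_apex", "rt_sigma",
                      "source", "is_target"), names(peptidome))
  utils::write.table(peptidome[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
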