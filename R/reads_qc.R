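## read-level quality filter: a read is rejected iff it contains more than
## `n_threshold` unknown nucleotides (N) or more than `lowq_threshold` bases
## at Phred quality <= q_cutoff. Both comparisons are strict ("more than").

#' Decide, per read, whether it passes the quality rules
#'
#' @param n_frac numeric vector, fraction of N bases per read.
#' @param lowq_frac numeric vector, fraction of bases with quality
#'   <= `q_cutoff` per read.
#' @param n_threshold maximum tolerated N fraction (exclusive).
#' @param lowq_threshold maximum tolerated low-quality fraction (exclusive).
#' @return list with logical `keep` and a `qc_report`.
#' @keywords internal
qc_decide <- function(n_frac, lowq_frac, n_threshold = 0.10, lowq_threshold = 0.50) {
  fail_n <- n_frac > n_threshold
  fail_q <- lowq_frac > lowq_threshold
  keep <- !(fail_n | fail_q)
  ## a read failing both rules is tallied once, under the N-fraction rule
  rep <- qc_report(n_input = length(keep),
                   n_rejected_n_fraction = sum(fail_n),
                   n_rejected_quality = sum(fail_q & !fail_n),
                   n_passed = sum(keep))
  list(keep = keep, report = rep)
}

qc_report <- function(n_input, n_rejected_n_fraction, n_rejected_quality, n_passed) {
  stopifnot(n_input == n_passed + n_rejected_n_fraction + n_rejected_quality)
  structure(list(n_input = n_input,
                 n_rejected_n_fraction = n_rejected_n_fraction,
                 n_rejected_quality = n_rejected_quality,
                 n_passed = n_passed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d reads in, %d passed, %d rejected (N-fraction %d, low-quality %d)\n",
              x$n_input, x$n_passed, x$n_input - x$n_passed,
              x$n_rejected_n_fraction, x$n_rejected_quality))
  invisible(x)
}

#' Filter in-memory read records
#'
#' @param records list of records, each a list with `id`, `sequence`
#'   (character over A/C/G/T/N) and `qualities` (integer Phred scores, same
#'   length as the sequence).
#' @param n_threshold,q_cutoff,lowq_threshold filter parameters; a read is
#'   rejected iff its N fraction exceeds `n_threshold` or its fraction of
#'   bases with quality `<= q_cutoff` exceeds `lowq_threshold` (both
#'   strictly).
#' @return list with `passed` (the surviving records, input order
#'   preserved) and `report` (a `qc_report`).
#' @export
filter_reads <- function(records, n_threshold = 0.10, q_cutoff = 20,
                         lowq_threshold = 0.50) {
  stopifnot(n_threshold > 0, n_threshold <= 1,
            lowq_threshold > 0, lowq_threshold <= 1, q_cutoff >= 0)
  n_frac <- lowq_frac <- numeric(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    len <- nchar(r$sequence)
    if (len != length(r$qualities))
      stop(sprintf("record '%s': sequence length %d != %d quality scores",
                   r$id, len, length(r$qualities)))
    bases <- strsplit(r$sequence, "")[[1]]
    n_frac[i] <- sum(bases == "N") / len
    lowq_frac[i] <- sum(r$qualities <= q_cutoff) / len
  }
  dec <- qc_decide(n_frac, lowq_frac, n_threshold, lowq_threshold)
  list(passed = records[dec$keep], report = dec$report)
}

#' Filter a FASTQ file
#'
#' Streams a FASTQ file (plain or gzip) through the read-level quality
#' rules and writes the surviving reads, order preserved. Qualities are
#' decoded as Phred+33 by default; pass `phred = 64` for legacy encodings.
#'
#' @param infile input FASTQ path (`.gz` accepted).
#' @param outfile output FASTQ path, or `NULL` to skip writing.
#' @param n_threshold,q_cutoff,lowq_threshold see [filter_reads()].
#' @param phred quality encoding offset, 33 or 64.
#' @return the `qc_report` (invisibly also written alongside if `outfile`
#'   is given, as `<outfile>.qc.json`).
#' @export
filter_fastq <- function(infile, outfile = NULL, n_threshold = 0.10,
                         q_cutoff = 20, lowq_threshold = 0.50, phred = 33) {
  stopifnot(phred %in% c(33, 64))
  validate_fastq_structure(infile)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(infile, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", infile, "': ", conditionMessage(e)))
  quals <- S4Vectors::mcols(seqs)$qualities
  lens <- Biostrings::width(seqs)
  if (any(lens != Biostrings::width(quals)))
    stop("FASTQ record with sequence/quality length mismatch in '", infile, "'")
  n_frac <- as.vector(Biostrings::letterFrequency(seqs, "N")) / lens
  qmat_lowq <- vapply(seq_along(seqs), function(i) {
    q <- as.integer(charToRaw(as.character(quals[[i]]))) - phred
    sum(q <= q_cutoff)
  }, integer(1))
  lowq_frac <- qmat_lowq / lens
  dec <- qc_decide(n_frac, lowq_frac, n_threshold, lowq_threshold)
  if (!is.null(outfile)) {
    out <- seqs[dec$keep]
    Biostrings::writeXStringSet(out, outfile, format = "fastq",
                                qualities = quals[dec$keep],
                                compress = grepl("\\.gz$", outfile))
    jsonlite::write_json(unclass(dec$report), paste0(outfile, ".qc.json"),
                         auto_unbox = TRUE)
  }
  dec$report
}

## cheap structural check so malformed files fail with a line number
## instead of a cryptic downstream decode error
validate_fastq_structure <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ '", path, "': truncated record near line ",
         length(lines))
  for (i in seq(1, length(lines), by = 4)) {
    if (!startsWith(lines[i], "@"))
      stop("malformed FASTQ '", path, "': expected '@' header at line ", i)
    if (!startsWith(lines[i + 2], "+"))
      stop("malformed FASTQ '", path, "': expected '+' separator at line ", i + 2)
    if (nchar(lines[i + 1]) != nchar(lines[i + 3]))
      stop("FASTQ record at line ", i, ": sequence length ",
           nchar(lines[i + 1]), " != quality length ", nchar(lines[i + 3]))
  }
  invisible(TRUE)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(as.data.frame(unclass(report)), path, sep = "\t")
  invisible(path)
}
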