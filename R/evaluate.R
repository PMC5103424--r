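#' Sequence identity
#'
#' `SI = matches / read_length`: the number of matched bases divided by the
#' full read length (not the aligned span), so unaligned tails count against
#' the read.
#'
#' @param matches integer number of matched bases.
#' @param read_length integer read length, >= 1.
#' @return `matches / read_length` as a fraction in `[0, 1]`.
#' @export
sequence_identity <- function(matches, read_length) {
  if (any(read_length < 1L))
    abort_validation("sequence_identity: read_length must be >= 1")
  if (any(matches < 0L) || any(matches > read_length))
    abort_validation("sequence_identity: matches must lie in [0, read_length]")
  matches / read_length
}

#' Parse a BLAT PSL file into per-read sequence-identity records
#'
#' Accepts a headerless PSL or one with the 5-line BLAT header.  For reads
#' with several alignments the one with the maximal `matches` field is kept
#' (ties broken by file order).  SI is computed against the full read length:
#' the `qSize` column by default, or the supplied `read_lengths`.  Reads
#' present in `read_lengths` but absent from the PSL are reported as
#' unmapped (`mapped = FALSE`, `si = NA`) and are excluded from summaries.
#'
#' @param psl path to a 21-column PSL file.
#' @param read_lengths optional named integer vector of read lengths, used
#'   both as the SI denominator and to enumerate unmapped reads.
#' @return data.frame with columns `read_id`, `matches`, `read_length`,
#'   `si`, `mapped`.
#' @export
parse_psl <- function(psl, read_lengths = NULL) {
  lines <- readLines(psl)
  if (length(lines) && startsWith(lines[1L], "psLayout"))
    lines <- lines[-seq_len(min(5L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    hits <- data.frame(read_id = character(0), matches = integer(0),
                       qsize = integer(0), stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 21L))
      abort_parse(sprintf("parse_psl: malformed PSL line %d (%d fields, expected 21)",
                          which(nf < 21L)[1L], nf[which(nf < 21L)[1L]]))
    matches <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
    qsize <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 11L)))
    if (anyNA(matches) || anyNA(qsize))
      abort_parse(sprintf("parse_psl: non-numeric matches/qSize at line %d",
                          which(is.na(matches) | is.na(qsize))[1L]))
    hits <- data.frame(read_id = vapply(fields, `[[`, "", 10L),
                       matches = matches, qsize = qsize,
                       stringsAsFactors = FALSE)
  }
  o <- order(-hits$matches)              # stable: file order among ties
  best <- hits[o, , drop = FALSE][!duplicated(hits$read_id[o]), , drop = FALSE]
  out <- data.frame(read_id = best$read_id,
                    matches = best$matches,
                    read_length = best$qsize,
                    stringsAsFactors = FALSE)
  if (!is.null(read_lengths)) {
    known <- out$read_id %in% names(read_lengths)
    if (any(known))
      out$read_length[known] <- as.integer(read_lengths[out$read_id[known]])
    absent <- setdiff(names(read_lengths), out$read_id)
    if (length(absent)) {
      out <- rbind(out, data.frame(read_id = absent, matches = NA_integer_,
                                   read_length = as.integer(read_lengths[absent]),
                                   stringsAsFactors = FALSE))
    }
  }
  out$mapped <- !is.na(out$matches)
  out$si <- ifelse(out$mapped,
                   out$matches / out$read_length, NA_real_)
  rownames(out) <- NULL
  out[, c("read_id", "matches", "read_length", "si", "mapped")]
}

#' Summarize sequence identity at thresholds
#'
#' For each threshold `t`, the fraction of mapped reads with `SI >= t`
#' (inclusive).  With no mapped reads all fractions are `NA` rather than 0.
#'
#' @param records data.frame from [parse_psl()] (needs `si` and `mapped`),
#'   or a bare numeric vector of SI values (all treated as mapped).
#' @param thresholds numeric thresholds, any order.
#' @return named numeric vector of fractions, one per threshold.
#' @export
si_summary <- function(records, thresholds = c(0.9, 0.8, 0.7)) {
  si <- if (is.data.frame(records)) records$si[records$mapped] else records
  si <- si[!is.na(si)]
  out <- if (!length(si)) {
    rep(NA_real_, length(thresholds))
  } else {
    vapply(thresholds, function(t) mean(si >= t), numeric(1))
  }
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Count error types from gapped read-vs-truth alignments
#'
#' Each alignment is a pair of equal-length gapped rows (`-` for gaps).
#' Aligned columns are classified as: mismatch (both bases present, unequal),
#' insertion (read base over a truth gap), deletion (truth base over a read
#' gap).  An indel whose base equals an adjacent truth base is additionally
#' counted as a homopolymer-length (HC) error -- it changes the length of a
#' run rather than its content -- and contributes to the `hc1` subset when
#' that truth run has length 1 (so a run that did not look like a
#' homopolymer at all was still miscalled; catching these is precisely why
#' runs of length one keep their HC count).
#'
#' @param alignments data.frame with character columns `read_row` and
#'   `truth_row` (one gapped pair per row), e.g. a simulator truth table.
#' @return list of class `error_tally` with `total_bases` (read bases across
#'   all pairs), `insert_err`, `delete_err`, `mismatch_err`, `hc_err`,
#'   `hc1_err`.
#' @export
tally_errors <- function(alignments) {
  if (!is.data.frame(alignments) ||
      !all(c("read_row", "truth_row") %in% names(alignments)))
    abort_validation("tally_errors: need columns 'read_row' and 'truth_row'")
  tot <- ins <- del <- mis <- hc <- hc1 <- 0L
  for (i in seq_len(nrow(alignments))) {
    a <- strsplit(alignments$read_row[i], "", fixed = TRUE)[[1L]]
    b <- strsplit(alignments$truth_row[i], "", fixed = TRUE)[[1L]]
    if (length(a) != length(b))
      abort_validation(sprintf("tally_errors: ragged alignment row %d", i))
    tb <- b[b != "-"]                       # ungapped truth
    nt <- length(tb)
    runs <- rle(tb)
    run_id <- rep(seq_along(runs$lengths), runs$lengths)
    tpos <- cumsum(b != "-")                # truth position left of/at column
    tot <- tot + sum(a != "-")
    for (j in seq_along(a)) {
      if (a[j] == "-" && b[j] != "-") {
        del <- del + 1L
        t <- tpos[j]
        if ((t > 1L && tb[t - 1L] == b[j]) || (t < nt && tb[t + 1L] == b[j]))
          hc <- hc + 1L                     # deleted base shortens a run >= 2
      } else if (a[j] != "-" && b[j] == "-") {
        ins <- ins + 1L
        t <- tpos[j]
        match_prev <- t >= 1L && tb[t] == a[j]
        match_next <- t < nt && tb[t + 1L] == a[j]
        if (match_prev || match_next) {
          hc <- hc + 1L                     # inserted base lengthens a run
          ref_t <- if (match_prev) t else t + 1L
          if (runs$lengths[run_id[ref_t]] == 1L) hc1 <- hc1 + 1L
        }
      } else if (a[j] != "-" && b[j] != "-" && a[j] != b[j]) {
        mis <- mis + 1L
      }
    }
  }
  structure(list(total_bases = tot, insert_err = ins, delete_err = del,
                 mismatch_err = mis, hc_err = hc, hc1_err = hc1),
            class = "error_tally")
}

#' @export
print.error_tally <- function(x, ...) {
  cat(sprintf(paste0("error_tally over %d read bases: insert %d, delete %d, ",
                     "mismatch %d, HC %d (HC=1: %d)\n"),
              x$total_bases, x$insert_err, x$delete_err, x$mismatch_err,
              x$hc_err, x$hc1_err))
  invisible(x)
}

#' Sequence identity of reads against their source references
#'
#' Globally aligns each read within its reference (read global, reference
#' local) with [Biostrings::pairwiseAlignment()] and returns
#' `matches / read length` per read.  Used to compare raw and corrected
#' reads against known truth transcripts.
#'
#' @param reads character vector of read sequences.
#' @param refs character vector of reference sequences, parallel to `reads`.
#' @return numeric vector of SI fractions.
#' @export
pairwise_si <- function(reads, refs) {
  if (length(reads) != length(refs))
    abort_validation("pairwise_si: 'reads' and 'refs' must be parallel")
  vapply(seq_along(reads), function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = reads[i], subject = refs[i], type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(pa) / nchar(reads[i])
  }, numeric(1))
}

#' Gapped alignment rows of a read against its reference
#'
#' Convenience for feeding externally corrected reads into [tally_errors()]
#' or per-base provenance accuracy checks.
#'
#' @param read,ref sequences (single strings).
#' @return list with `read_row` and `truth_row` (equal-length gapped rows
#'   covering the read globally and the reference locally).
#' @export
align_rows <- function(read, ref) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = read, subject = ref, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  list(read_row = as.character(Biostrings::alignedPattern(pa)),
       truth_row = as.character(Biostrings::alignedSubject(pa)))
}
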