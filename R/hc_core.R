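#' Homopolymer compression of sequencing reads
#'
#' Homopolymer compression (HC) replaces every maximal run of identical bases
#' by a single base of that type and records the run length in a parallel
#' count array.  Insertion/deletion errors that only change the length of a
#' homopolymer run disappear in compressed space, which is what makes
#' short-read to long-read alignment of high-indel-error reads feasible.
#' Counts are recorded for *every* compressed base, including runs of length
#' one, so that run lengths everywhere -- not only at collapsed positions --
#' can be corrected from short-read evidence.
#'
#' @param seq single sequence string over `A`,`C`,`G`,`T`,`N` (lower case is
#'   accepted and uppercased; `N` compresses like any other symbol).
#' @param id read identifier to carry through.
#' @return A [compressed_reads] object of length 1 with fields `id`, `cps`
#'   (compressed sequence) and `hcc` (list of integer HC count vectors;
#'   `sum(hcc[[i]])` equals the raw read length).
#' @examples
#' cr <- compress_read("AAACGGTTCTTA")
#' cr$cps        # "ACGTCTA"
#' cr$hcc[[1]]   # 3 1 2 2 1 2 1
#' @seealso [decompress()], [compress_reads()]
#' @export
compress_read <- function(seq, id = "read") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    abort_validation("compress_read: 'seq' must be a single non-empty string")
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  new_compressed_reads(id = as.character(id),
                       cps = paste(r$values, collapse = ""),
                       hcc = list(as.integer(r$lengths)))
}

#' Compress a set of reads
#'
#' @param reads data.frame with columns `id` and `seq` (and optionally
#'   `qual`, which is ignored: quality strings play no role downstream).
#' @return A [compressed_reads] object, one record per input row.
#' @export
compress_reads <- function(reads) {
  reads <- validate_raw_reads(reads)
  n <- nrow(reads)
  cps <- character(n)
  hcc <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rle(strsplit(toupper(reads$seq[i]), "", fixed = TRUE)[[1L]])
    cps[i] <- paste(r$values, collapse = "")
    hcc[[i]] <- as.integer(r$lengths)
  }
  new_compressed_reads(id = reads$id, cps = cps, hcc = hcc)
}

#' Expand a homopolymer-compressed sequence
#'
#' Inverse of [compress_read()]: each compressed base is repeated according
#' to its HC count.
#'
#' @param cps compressed sequence (single string).
#' @param hcc integer vector of HC counts, one per compressed base, all >= 1.
#' @return The expanded sequence string.
#' @examples
#' decompress("ACGTCTA", c(3, 1, 2, 2, 1, 2, 1))  # "AAACGGTTCTTA"
#' @export
decompress <- function(cps, hcc) {
  if (!is.character(cps) || length(cps) != 1L || is.na(cps))
    abort_validation("decompress: 'cps' must be a single string")
  hcc <- as.integer(hcc)
  if (nchar(cps) != length(hcc))
    abort_validation(sprintf(
      "decompress: cps has %d bases but hcc has %d counts",
      nchar(cps), length(hcc)))
  if (length(hcc) && (anyNA(hcc) || any(hcc < 1L)))
    abort_validation("decompress: all HC counts must be integers >= 1")
  if (!nchar(cps)) return("")
  paste(strrep(strsplit(cps, "", fixed = TRUE)[[1L]], hcc), collapse = "")
}

#' Reverse-complement compressed reads
#'
#' Reverse-strand alignments report the short read in its reverse-complement
#' orientation; the stored forward-orientation HC counts must be reversed in
#' step with the bases before they can vote.  Applying the transform twice
#' returns the input.
#'
#' @param cr a [compressed_reads] object.
#' @return A [compressed_reads] object with each `cps` reverse-complemented
#'   (`N` maps to `N`) and each HC count vector reversed.
#' @export
reverse_orientation <- function(cr) {
  cr <- validate_compressed_reads(cr)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(cr$cps)))
  new_compressed_reads(id = cr$id, cps = unname(rc),
                       hcc = lapply(cr$hcc, rev))
}

#' Write and read paired .cps/.hcc files
#'
#' The compressed sequences are stored as plain FASTA in the `.cps` file.
#' The `.hcc` file holds one line per read, in the same order as the `.cps`
#' records: `>id<TAB>c1,c2,...,cn`, where the `ci` are the HC counts in
#' compressed-read order (counts of 1 included).  The pair round-trips
#' byte-stably: writing the same reads twice yields identical files.
#'
#' @param cr a [compressed_reads] object.
#' @param cps_path,hcc_path output (input) file paths.
#' @return `write_cps_hcc` returns the paths invisibly; `read_cps_hcc`
#'   returns a [compressed_reads] object.
#' @export
write_cps_hcc <- function(cr, cps_path, hcc_path) {
  cr <- validate_compressed_reads(cr)
  dna <- Biostrings::DNAStringSet(cr$cps)
  names(dna) <- cr$id
  Biostrings::writeXStringSet(dna, cps_path, width = 80L)
  lines <- if (length(cr$id)) {
    paste0(">", cr$id, "\t",
           vapply(cr$hcc, function(x) paste(x, collapse = ","), character(1)))
  } else character(0)
  writeLines(lines, hcc_path)
  invisible(c(cps = cps_path, hcc = hcc_path))
}

#' @rdname write_cps_hcc
#' @export
read_cps_hcc <- function(cps_path, hcc_path) {
  dna <- Biostrings::readDNAStringSet(cps_path, format = "fasta")
  ids <- sub("\\s.*$", "", names(dna))
  cps <- as.character(dna)
  lines <- readLines(hcc_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(ids))
    abort_parse(sprintf(
      "read_cps_hcc: %d records in %s but %d lines in %s",
      length(ids), cps_path, length(lines), hcc_path))
  hcc <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^>([^\t]+)\t(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L)
      abort_parse(sprintf("read_cps_hcc: malformed .hcc line %d: %s",
                          i, lines[i]))
    if (m[2L] != ids[i])
      abort_parse(sprintf(
        "read_cps_hcc: record %d id mismatch: '%s' in .cps vs '%s' in .hcc",
        i, ids[i], m[2L]))
    counts <- suppressWarnings(as.integer(strsplit(m[3L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(counts) || any(counts < 1L))
      abort_parse(sprintf("read_cps_hcc: record '%s': non-positive or non-numeric HC count", ids[i]))
    if (length(counts) != nchar(cps[i]))
      abort_parse(sprintf(
        "read_cps_hcc: record '%s': %d HC counts for a %d-base compressed sequence",
        ids[i], length(counts), nchar(cps[i])))
    hcc[[i]] <- counts
  }
  new_compressed_reads(id = unname(ids), cps = unname(cps), hcc = hcc)
}

#' Read raw reads from FASTA or FASTQ
#'
#' The format is sniffed from the first record marker (`>` FASTA, `@`
#' FASTQ).  Sequences are uppercased so case never breaks a homopolymer run;
#' FASTQ qualities are carried along but unused by the correction pipeline.
#'
#' @param path FASTA or FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual` (`NA` for FASTA).
#' @export
read_reads <- function(path) {
  if (!file.exists(path))
    abort_validation(paste0("read_reads: no such file: ", path))
  first <- substr(trimws(readLines(path, n = 1L)), 1L, 1L)
  if (length(first) == 0L || is.na(first) || !nzchar(first)) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (first == ">") {
    dna <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(dna))
  } else if (first == "@") {
    dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(dna)$qualities)
  } else {
    abort_parse(paste0("read_reads: cannot determine format of ", path))
  }
  data.frame(id = sub("\\s.*$", "", names(dna)),
             seq = toupper(unname(as.character(dna))),
             qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param ids,seqs character vectors of equal length.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return The path, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 80L) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

# ---- containers --------------------------------------------------------

#' Compressed read sets
#'
#' A `compressed_reads` object is a length-parallel record set: `id` and
#' `cps` are character vectors and `hcc` is a list of integer vectors, one HC
#' count per compressed base.  Invariants: no two adjacent `cps` characters
#' are equal, every count is >= 1, and `length(hcc[[i]]) == nchar(cps[i])`.
#'
#' @param id,cps,hcc parallel fields, see description.
#' @return A `compressed_reads` object.
#' @name compressed_reads
NULL

new_compressed_reads <- function(id, cps, hcc) {
  structure(list(id = id, cps = cps, hcc = hcc), class = "compressed_reads")
}

validate_compressed_reads <- function(cr) {
  if (!inherits(cr, "compressed_reads"))
    abort_validation("expected a 'compressed_reads' object")
  if (length(cr$id) != length(cr$cps) || length(cr$cps) != length(cr$hcc))
    abort_validation("compressed_reads: ragged fields")
  cr
}

validate_raw_reads <- function(reads) {
  if (!is.data.frame(reads) || !all(c("id", "seq") %in% names(reads)))
    abort_validation("raw reads must be a data.frame with 'id' and 'seq'")
  if (nrow(reads) && any(!nzchar(reads$seq) | is.na(reads$seq)))
    abort_validation("raw reads: empty or missing sequence")
  reads
}

#' @export
length.compressed_reads <- function(x) length(x$id)

#' @export
`[.compressed_reads` <- function(x, i) {
  new_compressed_reads(id = x$id[i], cps = x$cps[i], hcc = x$hcc[i])
}

#' @export
print.compressed_reads <- function(x, ...) {
  cat(sprintf("compressed_reads with %d record(s)\n", length(x)))
  n <- min(length(x), 5L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s: %s (raw length %d)\n", x$id[i],
                if (nchar(x$cps[i]) > 40)
                  paste0(substr(x$cps[i], 1, 40), "...") else x$cps[i],
                sum(x$hcc[[i]])))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}
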