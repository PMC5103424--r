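#' Default external-aligner arguments
#'
#' Compressed long reads still carry the long-read errors that survive
#' homopolymer compression (substitutions, inserted bases that differ from
#' their neighbours, deleted length-1 runs), so compressed short reads
#' diverge from them by several percent.  The defaults therefore use short
#' seeds, a dense minimizer window and permissive chain/alignment scores, and
#' request SAM output with local alignment so that read ends extending past a
#' long-read end appear as soft clips (which drive end extension).
#'
#' @return character vector of minimap2 arguments.
#' @export
default_aligner_args <- function() {
  c("-a", "-k9", "-w2", "-A1", "-B2", "-O2,16", "-E2,1", "-s20", "-m15")
}

#' Align compressed short reads to compressed long reads
#'
#' Thin subprocess contract around an external SAM-emitting aligner
#' (minimap2 by default).  Everything downstream consumes SAM, so any
#' aligner producing SAM against the compressed long-read "references" can
#' be substituted, and a pre-computed SAM can be supplied to the pipeline
#' instead.
#'
#' @param lr_cps path to the compressed long-read FASTA (the references).
#' @param sr_cps path to the compressed short-read FASTA (the queries).
#' @param out_sam output SAM path.
#' @param aligner executable name or path.
#' @param aligner_args character vector of extra arguments.
#' @param threads threads passed to the aligner (`-t`).
#' @return `out_sam`, invisibly.
#' @export
run_aligner <- function(lr_cps, sr_cps, out_sam = tempfile(fileext = ".sam"),
                        aligner = "minimap2",
                        aligner_args = default_aligner_args(),
                        threads = 1L) {
  bin <- Sys.which(aligner)
  if (!nzchar(bin))
    abort_config(paste0("aligner binary not found on PATH: ", aligner))
  for (p in c(lr_cps, sr_cps))
    if (!file.exists(p)) abort_validation(paste0("run_aligner: no such file: ", p))
  args <- c(aligner_args, "-t", as.integer(threads), lr_cps, sr_cps)
  err_file <- tempfile(fileext = ".stderr")
  on.exit(unlink(err_file), add = TRUE)
  status <- suppressWarnings(system2(bin, args, stdout = out_sam, stderr = err_file))
  if (!identical(status, 0L))
    abort_aligner(paste0("aligner exited with status ", status, ":\n",
                         paste(readLines(err_file, warn = FALSE), collapse = "\n")))
  invisible(out_sam)
}

#' Parse a SAM file into alignment records
#'
#' Keeps mapped primary alignments only (secondary and supplementary records
#' are dropped so that each short read votes at most once per long read).
#' SAM's 1-based `POS` is converted to a 0-based `lr_start`.  The edit
#' distance is taken from the `NM` tag when present and otherwise recomputed
#' from the `=`/`X`/`I`/`D` CIGAR operations.  Records whose CIGAR contains
#' hard clips or padding (`H`, `P`) are skipped with a warning.
#'
#' @param sam path to a SAM file with `@SQ` headers for the long-read ids.
#' @param sr_store a [compressed_reads] object resolving every mapped short
#'   read id (used only to verify resolvability here; the corrector uses it
#'   for base/HC lookup).
#' @return data.frame with columns `lr_id`, `sr_id`, `strand` (`+`/`-`),
#'   `lr_start` (0-based), `cigar`, `edit_distance`, `aligned_sr_len`
#'   (compressed short-read bases consumed by `M`/`=`/`X`/`I`).
#' @export
parse_sam <- function(sam, sr_store) {
  sr_store <- validate_compressed_reads(sr_store)
  bam <- Rsamtools::asBam(sam, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (!length(x$qname)) {
    return(data.frame(lr_id = character(0), sr_id = character(0),
                      strand = character(0), lr_start = integer(0),
                      cigar = character(0), edit_distance = integer(0),
                      aligned_sr_len = integer(0), stringsAsFactors = FALSE))
  }
  nm <- x$tag$NM
  recs <- data.frame(lr_id = as.character(x$rname),
                     sr_id = x$qname,
                     strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
                     lr_start = x$pos - 1L,
                     cigar = x$cigar,
                     edit_distance = if (is.null(nm)) NA_integer_ else as.integer(nm),
                     stringsAsFactors = FALSE)
  if (!nrow(recs)) {
    recs$aligned_sr_len <- integer(0)
    return(recs)
  }
  bad <- grepl("[HP]", recs$cigar)
  if (any(bad)) {
    warning(sprintf("parse_sam: skipped %d record(s) with unsupported CIGAR ops (H/P)",
                    sum(bad)))
    recs <- recs[!bad, , drop = FALSE]
  }
  missing_sr <- setdiff(recs$sr_id, sr_store$id)
  if (length(missing_sr))
    abort_parse(paste0("parse_sam: short-read id(s) not in store: ",
                       paste(utils::head(missing_sr, 5L), collapse = ", ")))
  ops <- GenomicAlignments::explodeCigarOps(recs$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(recs$cigar)
  recs$aligned_sr_len <- mapply(function(o, l) sum(l[o %in% c("M", "=", "X", "I")]),
                                ops, lens)
  recompute <- is.na(recs$edit_distance)
  if (any(recompute)) {
    recs$edit_distance[recompute] <- mapply(
      function(o, l) sum(l[o %in% c("X", "I", "D")]),
      ops[recompute], lens[recompute])
  }
  rownames(recs) <- NULL
  recs
}

#' Alignment error rate in percent
#'
#' `100 * edit_distance / aligned_sr_len`: the edit distance relative to the
#' number of compressed short-read bases the alignment consumed.
#'
#' @param recs alignment-record data.frame from [parse_sam()].
#' @return numeric vector of percentages.
#' @export
alignment_error_rate <- function(recs) {
  if (any(recs$aligned_sr_len < 1L))
    abort_validation("alignment_error_rate: aligned_sr_len must be >= 1")
  100 * recs$edit_distance / recs$aligned_sr_len
}

#' Drop alignments exceeding the maximum error rate
#'
#' A record is kept iff its error rate is less than or equal to
#' `max_error_rate` (a record strictly greater is dropped, so a rate exactly
#' at the threshold survives).
#'
#' @param recs alignment-record data.frame.
#' @param max_error_rate threshold in percent (default 15, the scale of raw
#'   long-read error).
#' @return The filtered data.frame.
#' @export
filter_by_error_rate <- function(recs, max_error_rate = 15) {
  if (!nrow(recs)) return(recs)
  keep <- alignment_error_rate(recs) <= max_error_rate
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write/read the long-read to short-read mapping table
#'
#' A regenerable TSV with stable column order `lr_id`, `sr_id`, `strand`,
#' `lr_start`, `cigar`, `edit_distance`.
#'
#' @param recs alignment-record data.frame.
#' @param path TSV path.
#' @return `write_mapping_tsv` returns the path invisibly; `read_mapping_tsv`
#'   returns the records with `aligned_sr_len` recomputed from the CIGARs.
#' @export
write_mapping_tsv <- function(recs, path) {
  cols <- c("lr_id", "sr_id", "strand", "lr_start", "cigar", "edit_distance")
  data.table::fwrite(recs[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @export
read_mapping_tsv <- function(path) {
  recs <- as.data.frame(data.table::fread(path, sep = "\t",
                                          colClasses = list(character = c("lr_id", "sr_id", "strand", "cigar"))))
  if (!nrow(recs)) {
    recs$aligned_sr_len <- integer(0)
    return(recs)
  }
  ops <- GenomicAlignments::explodeCigarOps(recs$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(recs$cigar)
  recs$aligned_sr_len <- mapply(function(o, l) sum(l[o %in% c("M", "=", "X", "I")]),
                                ops, lens)
  recs
}
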