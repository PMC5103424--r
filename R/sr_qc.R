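#' Short-read quality-control configuration
#'
#' Very short reads and reads riddled with `N`s poison the compressed-space
#' alignment, so they are excluded before compression.  The length cutoff
#' applies to the raw (uncompressed) read length.
#'
#' @param min_length keep reads of at least this many raw bases (default 40;
#'   a 40 bp read is kept, a 39 bp read is dropped).
#' @param max_n_fraction drop reads whose fraction of `N` bases strictly
#'   exceeds this value (default 0.05).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_length = 40L, max_n_fraction = 0.05) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 1L)
    abort_validation("qc_config: min_length must be an integer >= 1")
  if (!is.numeric(max_n_fraction) || is.na(max_n_fraction) ||
      max_n_fraction < 0 || max_n_fraction > 1)
    abort_validation("qc_config: max_n_fraction must be in [0, 1]")
  structure(list(min_length = min_length, max_n_fraction = max_n_fraction),
            class = "qc_config")
}

#' Filter poor-quality short reads
#'
#' Partitions the input into kept and dropped reads.  A read is dropped iff
#' its raw length is below `cfg$min_length` (reason `too_short`) or its `N`
#' fraction strictly exceeds `cfg$max_n_fraction` (reason `too_many_n`);
#' length is checked first when both apply.
#'
#' @param reads data.frame with columns `id`, `seq` (and optionally `qual`).
#' @param cfg a [qc_config()].
#' @return list with `kept` (data.frame, subset of `reads`) and `dropped`
#'   (data.frame with columns `id`, `reason`).
#' @export
qc_filter <- function(reads, cfg = qc_config()) {
  reads <- validate_raw_reads(reads)
  if (!inherits(cfg, "qc_config")) abort_validation("cfg must be a qc_config")
  if (!nrow(reads)) {
    return(list(kept = reads,
                dropped = data.frame(id = character(0), reason = character(0),
                                     stringsAsFactors = FALSE)))
  }
  len <- nchar(reads$seq)
  n_count <- nchar(reads$seq) - nchar(gsub("N", "", toupper(reads$seq), fixed = TRUE))
  too_short <- len < cfg$min_length
  too_many_n <- !too_short & (n_count / len > cfg$max_n_fraction)
  drop <- too_short | too_many_n
  list(kept = reads[!drop, , drop = FALSE],
       dropped = data.frame(
         id = reads$id[drop],
         reason = ifelse(too_short[drop], "too_short", "too_many_n"),
         stringsAsFactors = FALSE))
}

#' Write the dropped-read log
#'
#' @param dropped the `dropped` element returned by [qc_filter()].
#' @param path output TSV path (columns `id`, `reason`).
#' @return The path, invisibly.
#' @export
write_qc_log <- function(dropped, path) {
  data.table::fwrite(dropped, path, sep = "\t")
  invisible(path)
}
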