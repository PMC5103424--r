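#' Correction parameters
#'
#' @param scf Short-Reads Coverage Frequency, an integer percentage in
#'   `[0, 100]` (default 60).  A candidate symbol is adopted as soon as its
#'   frequency over all votes in the column strictly exceeds `scf/100`;
#'   if no symbol qualifies, the most frequent one wins (ties broken by
#'   first arrival).  Lower values stop the scan sooner (faster, less
#'   stringent); 100 demands unanimity-beating frequency and always falls
#'   through to the plain majority.
#' @param scd Short-reads Coverage Depth, minimum number of votes a column
#'   needs before it is corrected (default 0 = disabled; all mapped short
#'   reads are used).  When positive, columns with fewer votes are treated
#'   as uncovered -- a compatibility switch with depth-filtering correctors.
#' @return A `correction_config` list.
#' @export
correction_config <- function(scf = 60L, scd = 0L) {
  scf <- as.integer(scf); scd <- as.integer(scd)
  if (is.na(scf) || scf < 0L || scf > 100L)
    abort_validation("correction_config: scf must be an integer in [0, 100]")
  if (is.na(scd) || scd < 0L)
    abort_validation("correction_config: scd must be an integer >= 0")
  structure(list(scf = scf, scd = scd), class = "correction_config")
}

#' Select the consensus candidate for one column
#'
#' Scans the votes in arrival order.  At each new distinct symbol its
#' frequency over *all* votes in the column is computed; the first symbol
#' whose frequency strictly exceeds `scf/100` is returned immediately.  With
#' the default `scf = 60` and a typical concordant column this stops after a
#' single distinct symbol, which is what makes the per-column cost
#' effectively constant.  If no symbol qualifies, the symbol with the highest
#' frequency is returned, ties broken by first occurrence in the list.  The
#' returned HC count is the one attached to the first vote carrying the
#' winning symbol.
#'
#' @param symbols character vector of votes in arrival order (`A`,`C`,`G`,
#'   `T`,`N` or `-` for a gap vote).
#' @param hc_counts integer HC counts parallel to `symbols` (gap votes carry
#'   1; defaults to all 1 for convenience in frequency-only uses).
#' @param scf percentage threshold, see [correction_config()].
#' @return list with `symbol`, `hc_count`, `scans` (number of distinct
#'   symbols examined) and `freq` (the winning symbol's frequency).
#' @examples
#' select_candidate(c("A", "A", "A", "C", "A", "G"), scf = 60)  # A after 1 scan
#' select_candidate(c("G", "A", "A", "A", "C", "A"), scf = 60)  # A after 2 scans
#' select_candidate(c("G", "A", "A", "A", "C", "A"), scf = 10)  # G after 1 scan
#' @export
select_candidate <- function(symbols, hc_counts = rep(1L, length(symbols)),
                             scf = 60L) {
  if (!length(symbols))
    abort_validation("select_candidate: empty vote list")
  if (length(hc_counts) != length(symbols))
    abort_validation("select_candidate: hc_counts must parallel symbols")
  scf <- as.numeric(scf)
  if (is.na(scf) || scf < 0 || scf > 100)
    abort_validation("select_candidate: scf must be in [0, 100]")
  n <- length(symbols)
  distinct <- symbols[!duplicated(symbols)]          # first-occurrence order
  counts <- vapply(distinct, function(s) sum(symbols == s), integer(1))
  freq <- counts / n
  hit <- which(freq > scf / 100)
  if (length(hit)) {
    i <- hit[1L]; scans <- i
  } else {
    i <- which.max(counts)                           # ties -> first occurrence
    scans <- length(distinct)
  }
  winner <- distinct[i]
  list(symbol = unname(winner),
       hc_count = as.integer(hc_counts[match(winner, symbols)]),
       scans = as.integer(scans),
       freq = unname(freq[i]))
}

#' Correct one long read from its layout
#'
#' Traverses the compressed long-read positions in order, visiting the
#' insertion slots after each position in rank order.  Covered columns are
#' resolved by [select_candidate()]; a winning base is decompressed on the
#' fly (`strrep(symbol, hc_count)`) and emitted as `sr_corrected`, a winning
#' gap emits nothing (the long-read base is deleted, or a proposed insertion
#' rejected).  Uncovered positions emit the raw long-read base expanded with
#' its own HC count, tagged `retained`.  Contiguous overhang columns at the
#' read ends (soft-clipped short-read bases reaching past the read) are
#' resolved the same way and prepended/appended as `extended`; the first
#' missing overhang position terminates the extension on that side.
#'
#' @param lr length-1 [compressed_reads] object (the raw long read).
#' @param layout the [build_layout()] result for this read.
#' @param cfg a [correction_config()].
#' @return An object of class `correction_result`: list with `lr_id`, `ecLR`
#'   (the full corrected sequence), `lrLR` (the subsequence between the
#'   left-most and right-most short-read-covered points, `NA` if the read is
#'   uncovered), `left_ec`/`right_ec` (0-based ecLR coordinates of that span,
#'   `NA` if none) and `provenance` (per-ecLR-base tag: `sr_corrected`,
#'   `retained` or `extended`).
#' @export
correct_long_read <- function(lr, layout, cfg = correction_config()) {
  lr <- validate_compressed_reads(lr)
  if (!inherits(layout, "lr_layout"))
    abort_validation("correct_long_read: 'layout' must come from build_layout()")
  if (!inherits(cfg, "correction_config"))
    abort_validation("correct_long_read: 'cfg' must be a correction_config")
  if (layout$lr_id != lr$id[1L])
    abort_validation("correct_long_read: layout is for a different read")
  n <- nchar(lr$cps[1L])
  if (layout$n != n)
    hc_abort("correct_long_read: layout length disagrees with the read",
             "hcorrect_internal_error")
  v <- layout$votes
  if (nrow(v) && any(v$rank > 0L & (v$pos < 0L | v$pos >= n)))
    hc_abort("correct_long_read: layout references impossible positions",
             "hcorrect_internal_error")

  lr_chars <- strsplit(lr$cps[1L], "", fixed = TRUE)[[1L]]
  lr_hcc <- lr$hcc[[1L]]

  # group votes per column, preserving arrival order within each column
  pos <- rank <- symbol <- hc <- NULL  # data.table NSE
  cols <- if (nrow(v)) {
    v[, list(syms = list(symbol), hcs = list(hc)), keyby = list(pos, rank)]
  } else NULL
  col_key <- if (!is.null(cols)) paste(cols$pos, cols$rank) else character(0)
  col_of <- function(p, k) {
    i <- match(paste(p, k), col_key)
    if (is.na(i)) NULL else list(syms = cols$syms[[i]], hcs = cols$hcs[[i]])
  }
  covered <- function(column) {
    !is.null(column) && (cfg$scd == 0L || length(column$syms) >= cfg$scd)
  }
  ranks_at <- integer(0)
  if (!is.null(cols)) {
    ins <- cols[cols$rank > 0L, ]
    if (nrow(ins)) {
      ranks_at <- tapply(ins$rank, ins$pos, max)
    }
  }
  max_rank <- function(p) {
    r <- ranks_at[as.character(p)]
    if (is.na(r) || !length(r)) 0L else as.integer(r)
  }

  chunks <- character(0); tags <- character(0)
  emit <- function(text, tag) {
    if (nchar(text)) {
      chunks[[length(chunks) + 1L]] <<- text
      tags[[length(tags) + 1L]] <<- tag
    }
  }
  resolve <- function(column) {
    select_candidate(column$syms, column$hcs, cfg$scf)
  }

  # left extension: contiguous overhang columns ending at position -1
  if (!is.na(layout$left)) {
    p <- -1L
    ext <- list()
    while (TRUE) {
      column <- col_of(p, 0L)
      if (!covered(column)) break
      ext[[length(ext) + 1L]] <- column
      p <- p - 1L
    }
    for (column in rev(ext)) {
      w <- resolve(column)
      if (w$symbol != "-") emit(strrep(w$symbol, w$hc_count), "extended")
    }
  }

  for (p in seq_len(n) - 1L) {
    column <- col_of(p, 0L)
    if (covered(column)) {
      w <- resolve(column)
      if (w$symbol != "-") emit(strrep(w$symbol, w$hc_count), "sr_corrected")
    } else {
      emit(strrep(lr_chars[p + 1L], lr_hcc[p + 1L]), "retained")
    }
    mr <- max_rank(p)
    if (mr > 0L) {
      for (k in seq_len(mr)) {
        column <- col_of(p, k)
        if (!covered(column)) next
        w <- resolve(column)
        if (w$symbol != "-") emit(strrep(w$symbol, w$hc_count), "sr_corrected")
      }
    }
  }

  # right extension: contiguous overhang columns starting at position n
  if (!is.na(layout$right)) {
    p <- n
    while (TRUE) {
      column <- col_of(p, 0L)
      if (!covered(column)) break
      w <- resolve(column)
      if (w$symbol != "-") emit(strrep(w$symbol, w$hc_count), "extended")
      p <- p + 1L
    }
  }

  ecLR <- paste(chunks, collapse = "")
  provenance <- rep(tags, nchar(chunks))
  # lrLR spans from the first to the last short-read-derived base (corrected
  # or extended); interior uncovered stretches stay inside the span.
  sr_derived <- which(provenance != "retained")
  has_span <- length(sr_derived) > 0L
  left_mark <- if (has_span) sr_derived[1L] - 1L else NA_integer_     # 0-based
  right_mark <- if (has_span) sr_derived[length(sr_derived)] - 1L else NA_integer_
  structure(list(
    lr_id = lr$id[1L],
    ecLR = ecLR,
    lrLR = if (has_span) substr(ecLR, left_mark + 1L, right_mark + 1L) else NA_character_,
    left_ec = left_mark,
    right_ec = right_mark,
    provenance = provenance),
    class = "correction_result")
}

#' Correct a set of long reads
#'
#' Convenience wrapper: per long read, subsets the alignment records, builds
#' the layout and corrects.
#'
#' @param lrs [compressed_reads] of the long reads.
#' @param recs alignment records (already filtered by error rate).
#' @param sr_store [compressed_reads] of the short reads.
#' @param cfg a [correction_config()].
#' @return list of `correction_result`, in long-read order.
#' @export
correct_reads <- function(lrs, recs, sr_store, cfg = correction_config()) {
  lrs <- validate_compressed_reads(lrs)
  by_lr <- if (nrow(recs)) split(seq_len(nrow(recs)), recs$lr_id) else list()
  lapply(seq_along(lrs$id), function(i) {
    lr <- lrs[i]
    sub <- recs[by_lr[[lr$id]] %||% integer(0), , drop = FALSE]
    correct_long_read(lr, build_layout(lr, sub, sr_store), cfg)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write corrected reads
#'
#' `corrected_LR_full.fa` receives the full ecLR of every read, in input
#' order; `corrected_LR.fa` receives the lrLR (the short-read-covered span)
#' only for reads with at least one covered column.
#'
#' @param results list of `correction_result`.
#' @param lr_path path for `corrected_LR.fa`.
#' @param full_path path for `corrected_LR_full.fa`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_corrected <- function(results, lr_path = "corrected_LR.fa",
                            full_path = "corrected_LR_full.fa") {
  ids <- vapply(results, `[[`, "", "lr_id")
  ec <- vapply(results, `[[`, "", "ecLR")
  lrlr <- vapply(results, `[[`, "", "lrLR")
  write_fasta(ids, ec, full_path)
  keep <- !is.na(lrlr) & nzchar(lrlr)
  write_fasta(ids[keep], lrlr[keep], lr_path)
  invisible(c(lrLR = lr_path, full = full_path))
}

#' Write the per-read provenance log
#'
#' TSV with columns `lr_id`, `left_ec`, `right_ec`, `n_corrected`,
#' `n_retained`, `n_extended`.
#'
#' @param results list of `correction_result`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_provenance_log <- function(results, path) {
  tab <- data.frame(
    lr_id = vapply(results, `[[`, "", "lr_id"),
    left_ec = vapply(results, function(r) as.integer(r$left_ec), integer(1)),
    right_ec = vapply(results, function(r) as.integer(r$right_ec), integer(1)),
    n_corrected = vapply(results, function(r) sum(r$provenance == "sr_corrected"), integer(1)),
    n_retained = vapply(results, function(r) sum(r$provenance == "retained"), integer(1)),
    n_extended = vapply(results, function(r) sum(r$provenance == "extended"), integer(1)),
    stringsAsFactors = FALSE)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("correction_result '%s': ecLR %d bp (%d corrected / %d retained / %d extended)%s\n",
              x$lr_id, nchar(x$ecLR),
              sum(x$provenance == "sr_corrected"),
              sum(x$provenance == "retained"),
              sum(x$provenance == "extended"),
              if (is.na(x$lrLR)) ", uncovered" else
                sprintf(", lrLR [%d, %d]", x$left_ec, x$right_ec)))
  invisible(x)
}
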