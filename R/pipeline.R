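#' Pipeline configuration
#'
#' Collects paths and parameters for the end-to-end run.  All values can come
#' from a flat `key=value` configuration file ([read_pipeline_config()]);
#' explicit arguments override file values.
#'
#' @param lr path to the long-read FASTA/FASTQ.
#' @param sr path to the single-end short-read FASTA/FASTQ.
#' @param workdir output directory (created if needed).
#' @param sam optional pre-computed SAM of compressed short reads against
#'   compressed long reads; when supplied the aligner is not invoked.
#' @param psl optional BLAT PSL for evaluation convenience (not used by the
#'   correction stages).
#' @param threads number of chunks the short-read set is split into for
#'   compression/QC, and threads handed to the aligner; results are
#'   independent of this value.
#' @param scf,scd see [correction_config()].
#' @param min_length,max_n_fraction see [qc_config()].
#' @param max_error_rate see [filter_by_error_rate()].
#' @param aligner,aligner_args external aligner executable and arguments
#'   (string arguments are split on whitespace).
#' @param seed integer seed recorded in the log (the correction itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lr, sr, workdir, sam = NULL, psl = NULL,
                            threads = 1L, scf = 60L, scd = 0L,
                            min_length = 40L, max_n_fraction = 0.05,
                            max_error_rate = 15, aligner = "minimap2",
                            aligner_args = default_aligner_args(),
                            seed = 1L) {
  threads <- as.integer(threads)
  if (is.na(threads) || threads < 1L)
    abort_validation("pipeline_config: threads must be an integer >= 1")
  if (is.character(aligner_args) && length(aligner_args) == 1L)
    aligner_args <- strsplit(trimws(aligner_args), "\\s+")[[1L]]
  cfg <- list(lr = lr, sr = sr, workdir = workdir, sam = sam, psl = psl,
              threads = threads,
              qc = qc_config(min_length, max_n_fraction),
              correction = correction_config(scf, scd),
              max_error_rate = as.numeric(max_error_rate),
              aligner = aligner, aligner_args = aligner_args,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; unknown keys are
#' rejected.  Recognized keys: `lr`, `sr`, `workdir`, `sam`, `psl`,
#' `threads`, `scf`, `scd`, `min_length`, `max_n_fraction`,
#' `max_error_rate`, `aligner`, `aligner_args`, `seed`.
#'
#' @param path configuration file.
#' @param overrides named list of values that take precedence over the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    abort_config(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    abort_config(paste0("malformed config line: ", lines[which(bad)[1L]]))
  vals <- stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                          vapply(kv, function(m) m[2L], character(1)))
  known <- c("lr", "sr", "workdir", "sam", "psl", "threads", "scf", "scd",
             "min_length", "max_n_fraction", "max_error_rate", "aligner",
             "aligner_args", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  vals[names(overrides)] <- overrides
  numeric_keys <- c("threads", "scf", "scd", "min_length", "max_n_fraction",
                    "max_error_rate", "seed")
  for (k in intersect(names(vals), numeric_keys))
    vals[[k]] <- as.numeric(vals[[k]])
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    hc_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
             "hcorrect_stage_error")
  })
}

split_chunks <- function(n, k) {
  if (n == 0L) return(list())
  k <- min(k, n)
  split(seq_len(n), rep(seq_len(k), each = ceiling(n / k), length.out = n))
}

#' Run the full correction pipeline
#'
#' Stages: read inputs; short-read QC; homopolymer compression of both sets
#' (the short-read set is processed in `threads` independent chunks whose
#' concatenation is chunk-count-invariant); alignment of compressed short
#' reads to compressed long reads (skipped when a SAM is supplied); error-rate
#' filtering; per-read layout construction and correction; output of
#' `corrected_LR.fa`, `corrected_LR_full.fa`, the `.cps`/`.hcc` pairs, the
#' mapping TSV, the provenance log and a per-stage count log.
#'
#' @param cfg a [pipeline_config()].
#' @return The work directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    abort_validation("run_pipeline: cfg must be a pipeline_config")
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[hcorrect] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  lr_raw <- stage("read_lr", {
    if (!file.exists(cfg$lr)) abort_validation(paste0("long-read file not found: ", cfg$lr))
    read_reads(cfg$lr)
  })
  sr_raw <- stage("read_sr", {
    if (!file.exists(cfg$sr)) abort_validation(paste0("short-read file not found: ", cfg$sr))
    read_reads(cfg$sr)
  })
  note("input: %d long reads, %d short reads", nrow(lr_raw), nrow(sr_raw))

  # QC + compression of short reads, chunked; per-read operations, so the
  # concatenated result is independent of the chunk count.
  chunks <- split_chunks(nrow(sr_raw), cfg$threads)
  qc_res <- stage("sr_qc", {
    parts <- lapply(chunks, function(ix) qc_filter(sr_raw[ix, , drop = FALSE], cfg$qc))
    list(kept = do.call(rbind, c(lapply(parts, `[[`, "kept"),
                                 list(sr_raw[0, , drop = FALSE]))),
         dropped = do.call(rbind, c(lapply(parts, `[[`, "dropped"),
                                    list(data.frame(id = character(0),
                                                    reason = character(0))))))
  })
  write_qc_log(qc_res$dropped, file.path(cfg$workdir, "sr_dropped.tsv"))
  note("QC: kept %d short reads, dropped %d", nrow(qc_res$kept), nrow(qc_res$dropped))

  comp <- stage("compress", {
    sr_parts <- lapply(split_chunks(nrow(qc_res$kept), cfg$threads),
                       function(ix) compress_reads(qc_res$kept[ix, , drop = FALSE]))
    sr_cps <- if (length(sr_parts)) {
      new_compressed_reads(
        id = unlist(lapply(sr_parts, `[[`, "id"), use.names = FALSE),
        cps = unlist(lapply(sr_parts, `[[`, "cps"), use.names = FALSE),
        hcc = do.call(c, lapply(sr_parts, `[[`, "hcc")))
    } else new_compressed_reads(character(0), character(0), list())
    list(lr = compress_reads(lr_raw), sr = sr_cps)
  })
  lr_cps_path <- file.path(cfg$workdir, "LR.cps.fa")
  sr_cps_path <- file.path(cfg$workdir, "SR.cps.fa")
  write_cps_hcc(comp$lr, lr_cps_path, file.path(cfg$workdir, "LR.hcc"))
  write_cps_hcc(comp$sr, sr_cps_path, file.path(cfg$workdir, "SR.hcc"))

  sam_path <- if (!is.null(cfg$sam) && nzchar(cfg$sam)) {
    note("alignment: using supplied SAM %s", cfg$sam)
    cfg$sam
  } else {
    stage("align", run_aligner(lr_cps_path, sr_cps_path,
                               file.path(cfg$workdir, "sr_vs_lr.sam"),
                               aligner = cfg$aligner,
                               aligner_args = cfg$aligner_args,
                               threads = cfg$threads))
  }

  recs <- stage("parse_sam", parse_sam(sam_path, comp$sr))
  note("alignment: %d mapped primary records", nrow(recs))
  recs <- stage("filter", filter_by_error_rate(recs, cfg$max_error_rate))
  note("alignment: %d records within max_error_rate %.1f%%",
       nrow(recs), cfg$max_error_rate)
  write_mapping_tsv(recs, file.path(cfg$workdir, "lr_sr_mapping.tsv"))

  results <- stage("correct", correct_reads(comp$lr, recs, comp$sr, cfg$correction))
  write_corrected(results,
                  lr_path = file.path(cfg$workdir, "corrected_LR.fa"),
                  full_path = file.path(cfg$workdir, "corrected_LR_full.fa"))
  write_provenance_log(results, file.path(cfg$workdir, "provenance.tsv"))
  n_cov <- sum(vapply(results, function(r) !is.na(r$lrLR), logical(1)))
  note("correction: %d ecLRs written, %d with a covered span (lrLR)",
       length(results), n_cov)

  writeLines(log_lines, file.path(cfg$workdir, "pipeline.log"))
  invisible(cfg$workdir)
}
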