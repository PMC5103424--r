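#' Simulation parameters
#'
#' Defaults emulate a desk-scale SMRT transcriptome regime: a handful of
#' ~1 kb transcripts; long reads with ~15 % total error split 1 % substitution
#' / 8 % insertion / 6 % deletion, with indels concentrated inside
#' homopolymer runs; accurate fixed-length 75 bp short reads sampled to 20x
#' coverage, error-free by default (real short reads are > 98 % accurate, and
#' the correction model treats them as truth).
#'
#' `homopolymer_bias` multiplies the per-base indel probability inside runs
#' of length >= 2 relative to isolated bases.  The base rates are rescaled so
#' the *average* indel rate over a transcript stays at the nominal
#' `lr_ins_rate`/`lr_del_rate`; the bias redistributes errors toward runs
#' without inflating the total.
#'
#' @param n_transcripts number of reference transcripts.
#' @param transcript_len_range integer `(min, max)` transcript length in bases.
#' @param lr_sub_rate,lr_ins_rate,lr_del_rate per-base long-read error
#'   probabilities (defaults 0.01, 0.08, 0.06; total ~ 0.15).
#' @param homopolymer_bias indel-rate multiplier inside runs >= 2 (default 3).
#' @param sr_len short-read length in bases (default 75).
#' @param sr_coverage short-read fold coverage per transcript (default 20).
#' @param sr_err_rate short-read substitution rate (default 0).
#' @param seed integer seed; every output is byte-reproducible under it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 5L,
                       transcript_len_range = c(800L, 1200L),
                       lr_sub_rate = 0.01, lr_ins_rate = 0.08,
                       lr_del_rate = 0.06, homopolymer_bias = 3,
                       sr_len = 75L, sr_coverage = 20, sr_err_rate = 0,
                       seed = 1L) {
  p <- list(n_transcripts = as.integer(n_transcripts),
            transcript_len_range = as.integer(transcript_len_range),
            lr_sub_rate = lr_sub_rate, lr_ins_rate = lr_ins_rate,
            lr_del_rate = lr_del_rate, homopolymer_bias = homopolymer_bias,
            sr_len = as.integer(sr_len), sr_coverage = sr_coverage,
            sr_err_rate = sr_err_rate, seed = as.integer(seed))
  rates <- c(p$lr_sub_rate, p$lr_ins_rate, p$lr_del_rate, p$sr_err_rate)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    abort_validation("sim_params: error rates must lie in [0, 1]")
  if (p$n_transcripts < 0L)
    abort_validation("sim_params: n_transcripts must be >= 0")
  if (length(p$transcript_len_range) != 2L ||
      any(p$transcript_len_range < 1L) ||
      p$transcript_len_range[1L] > p$transcript_len_range[2L])
    abort_validation("sim_params: degenerate transcript_len_range")
  if (p$homopolymer_bias < 1)
    abort_validation("sim_params: homopolymer_bias must be >= 1")
  if (p$sr_len < 1L || p$sr_coverage < 0)
    abort_validation("sim_params: invalid short-read regime")
  structure(p, class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

#' Generate reference transcripts
#'
#' Uniform-random sequences with lengths drawn uniformly from the configured
#' range; deterministic under the seed.
#'
#' @param p a [sim_params()].
#' @return data.frame with columns `id`, `seq`.
#' @export
generate_reference <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  withr::with_seed(p$seed, {
    lens <- sample(seq(p$transcript_len_range[1L], p$transcript_len_range[2L]),
                   p$n_transcripts, replace = TRUE)
    data.frame(
      id = sprintf("t%d", seq_len(p$n_transcripts)),
      seq = vapply(lens, function(L)
        paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  })
}

# Per-base indel weight: homopolymer_bias inside runs >= 2, rescaled so the
# transcript-average weight is 1 (nominal rates stay nominal).
run_weights <- function(chars, bias) {
  n <- length(chars)
  if (n == 1L) return(1)
  in_run <- c(chars[-n] == chars[-1L], FALSE) | c(FALSE, chars[-n] == chars[-1L])
  w <- ifelse(in_run, bias, 1)
  w / mean(w)
}

#' Simulate noisy long reads
#'
#' One full-length long read per transcript.  Each truth base is deleted with
#' probability `lr_del_rate * w`, substituted with probability `lr_sub_rate`,
#' and followed by an inserted uniform-random base with probability
#' `lr_ins_rate * w`, where `w` is the run-aware weight (see [sim_params()]).
#' The exact gapped read/truth alignment of every read is recorded, so
#' injected errors can be recovered without realignment.
#'
#' @param transcripts data.frame from [generate_reference()].
#' @param p a [sim_params()].
#' @return list with `reads` (data.frame `id`, `seq`) and `truth`
#'   (data.frame `read_id`, `transcript_id`, `start`, `read_row`,
#'   `truth_row`).
#' @export
simulate_long_reads <- function(transcripts, p) {
  stopifnot(inherits(p, "sim_params"))
  withr::with_seed(p$seed + 1L, {
    n <- nrow(transcripts)
    reads <- data.frame(id = sprintf("lr_%s", transcripts$id),
                        seq = character(n), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = reads$id, transcript_id = transcripts$id,
                        start = rep(0L, n), read_row = character(n),
                        truth_row = character(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      b <- strsplit(transcripts$seq[i], "", fixed = TRUE)[[1L]]
      L <- length(b)
      w <- run_weights(b, p$homopolymer_bias)
      u <- stats::runif(L)
      p_del <- pmin(p$lr_del_rate * w, 1)
      deleted <- u < p_del
      substituted <- !deleted & u < p_del + p$lr_sub_rate
      inserted <- stats::runif(L) < pmin(p$lr_ins_rate * w, 1)
      read_base <- b
      if (any(substituted)) {
        read_base[substituted] <- vapply(b[substituted], function(x)
          sample(setdiff(BASES, x), 1L), character(1))
      }
      read_base[deleted] <- "-"
      ins_base <- character(L)
      ins_base[inserted] <- sample(BASES, sum(inserted), replace = TRUE)
      rrow <- character(0); trow <- character(0)
      rrow <- as.vector(rbind(read_base, ifelse(inserted, ins_base, "")))
      trow <- as.vector(rbind(b, ifelse(inserted, "-", "")))
      rrow <- rrow[nzchar(rrow)]; trow <- trow[nzchar(trow)]
      truth$read_row[i] <- paste(rrow, collapse = "")
      truth$truth_row[i] <- paste(trow, collapse = "")
      reads$seq[i] <- gsub("-", "", truth$read_row[i], fixed = TRUE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate accurate short reads
#'
#' Fixed-length substrings sampled uniformly along each transcript to the
#' target fold coverage (`round(coverage * len / sr_len)` reads per
#' transcript), with independent substitutions at `sr_err_rate`.  Transcripts
#' shorter than `sr_len` are skipped with a warning.
#'
#' @param transcripts data.frame from [generate_reference()].
#' @param p a [sim_params()].
#' @return data.frame with columns `id`, `seq`.
#' @export
simulate_short_reads <- function(transcripts, p) {
  stopifnot(inherits(p, "sim_params"))
  withr::with_seed(p$seed + 2L, {
    out <- vector("list", nrow(transcripts))
    for (i in seq_len(nrow(transcripts))) {
      L <- nchar(transcripts$seq[i])
      if (p$sr_len > L) {
        warning(sprintf("simulate_short_reads: transcript '%s' (%d bp) shorter than sr_len; skipped",
                        transcripts$id[i], L))
        next
      }
      n_reads <- round(p$sr_coverage * L / p$sr_len)
      if (n_reads < 1L) next
      starts <- sample.int(L - p$sr_len + 1L, n_reads, replace = TRUE)
      seqs <- substring(transcripts$seq[i], starts, starts + p$sr_len - 1L)
      if (p$sr_err_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          ch <- strsplit(s, "", fixed = TRUE)[[1L]]
          hit <- stats::runif(length(ch)) < p$sr_err_rate
          if (any(hit)) {
            ch[hit] <- vapply(ch[hit], function(x)
              sample(setdiff(BASES, x), 1L), character(1))
          }
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      out[[i]] <- data.frame(
        id = sprintf("%s_sr%d", transcripts$id[i], seq_len(n_reads)),
        seq = seqs, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(id = character(0), seq = character(0),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Write/read a truth table
#'
#' TSV with columns `read_id`, `transcript_id`, `start`, `read_row`,
#' `truth_row`; the gapped rows reconstruct every simulated read exactly.
#'
#' @param truth the `truth` element of [simulate_long_reads()].
#' @param path TSV path.
#' @return `write_truth_tsv` returns the path invisibly; `read_truth_tsv`
#'   the data.frame.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
}

#' Simulate a complete dataset on disk
#'
#' Writes `ref.fa`, `lr.fa`, `sr.fa` and `truth.tsv` under `dir`.
#'
#' @param p a [sim_params()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
simulate_dataset <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(p)
  lr <- simulate_long_reads(ref, p)
  sr <- simulate_short_reads(ref, p)
  paths <- c(ref = file.path(dir, "ref.fa"), lr = file.path(dir, "lr.fa"),
             sr = file.path(dir, "sr.fa"), truth = file.path(dir, "truth.tsv"))
  write_fasta(ref$id, ref$seq, paths["ref"])
  write_fasta(lr$reads$id, lr$reads$seq, paths["lr"])
  write_fasta(sr$id, sr$seq, paths["sr"])
  write_truth_tsv(lr$truth, paths["truth"])
  invisible(paths)
}
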