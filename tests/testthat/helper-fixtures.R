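# Shared fixture builders. Everything is generated in code; no stored data.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

new_cr <- function(id, cps, hcc) {
  hcorrect:::new_compressed_reads(id = id, cps = cps, hcc = hcc)
}

# Minimal SAM writer for hand-built alignment fixtures.
# recs: data.frame with qname, flag, rname, pos (1-based), cigar, seq,
# and optionally nm (NM tag; NA to omit).
write_sam <- function(path, refs, recs) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$id, refs$len))
  body <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    line <- paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar, "*", 0, 0,
                  r$seq, "*", sep = "\t")
    if (!is.null(recs$nm) && !is.na(r$nm))
      line <- paste0(line, "\tNM:i:", r$nm)
    line
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Random layout fixture: one compressed LR plus synthetic alignment records
# built directly in compressed space (CIGARs constructed to be walkable by
# definition). Returns lr, sr_store, recs.
random_layout_fixture <- function(n_sr = 6L) {
  lr_raw <- rand_seq(sample(120:200, 1))
  lr <- compress_read(lr_raw, id = "LR")
  n <- nchar(lr$cps[1])
  sr_ids <- sprintf("sr%02d", seq_len(n_sr))
  sr_cps <- character(n_sr); sr_hcc <- vector("list", n_sr)
  recs <- NULL
  lr_chars <- strsplit(lr$cps[1], "", fixed = TRUE)[[1]]
  for (i in seq_len(n_sr)) {
    start <- sample.int(n - 30L, 1L) - 1L          # 0-based
    sr_chars <- character(0); ops <- character(0); lens <- integer(0)
    lead_s <- sample(0:2, 1)
    if (lead_s > 0) {
      sr_chars <- c(sr_chars, sample(c("A", "C", "G", "T"), lead_s, TRUE))
      ops <- c(ops, "S"); lens <- c(lens, lead_s)
    }
    ref_pos <- start
    n_seg <- sample(2:4, 1)
    for (s in seq_len(n_seg)) {
      m <- sample(3:8, 1)
      m <- min(m, n - ref_pos)
      if (m < 1) break
      seg <- lr_chars[(ref_pos + 1):(ref_pos + m)]
      if (runif(1) < 0.3) seg[sample.int(m, 1)] <- sample(c("A", "C", "G", "T"), 1)
      sr_chars <- c(sr_chars, seg)
      ops <- c(ops, "M"); lens <- c(lens, m)
      ref_pos <- ref_pos + m
      if (s < n_seg && ref_pos < n - 10L) {
        if (runif(1) < 0.5) {
          k <- sample(1:2, 1)
          sr_chars <- c(sr_chars, sample(c("A", "C", "G", "T"), k, TRUE))
          ops <- c(ops, "I"); lens <- c(lens, k)
        } else {
          k <- sample(1:2, 1)
          ops <- c(ops, "D"); lens <- c(lens, k)
          ref_pos <- ref_pos + k
        }
      }
    }
    trail_s <- sample(0:2, 1)
    if (trail_s > 0) {
      sr_chars <- c(sr_chars, sample(c("A", "C", "G", "T"), trail_s, TRUE))
      ops <- c(ops, "S"); lens <- c(lens, trail_s)
    }
    cigar <- paste0(lens, ops, collapse = "")
    hcc <- sample(1:3, length(sr_chars), TRUE)
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      sr_cps[i] <- paste(sr_chars, collapse = ""); sr_hcc[[i]] <- hcc
    } else {
      # store the forward orientation; build_layout re-orients for voting
      oriented <- new_cr(sr_ids[i], paste(sr_chars, collapse = ""), list(hcc))
      fwd <- reverse_orientation(oriented)
      sr_cps[i] <- fwd$cps[1]; sr_hcc[[i]] <- fwd$hcc[[1]]
    }
    recs <- rbind(recs, data.frame(
      lr_id = "LR", sr_id = sr_ids[i], strand = strand, lr_start = start,
      cigar = cigar, edit_distance = 0L,
      aligned_sr_len = sum(lens[ops %in% c("M", "I")]),
      stringsAsFactors = FALSE))
  }
  list(lr = lr, sr_store = new_cr(sr_ids, sr_cps, sr_hcc), recs = recs)
}

# Small simulated dataset corrected end to end through the real aligner.
# Cached per session so several tests can share it.
corrected_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- sim_params(n_transcripts = 3L, transcript_len_range = c(500L, 700L),
                    seed = 11L)
    d <- withr::local_tempdir(.local_envir = teardown_env())
    ref <- generate_reference(p)
    lr <- simulate_long_reads(ref, p)
    sr <- simulate_short_reads(ref, p)
    lrr <- compress_reads(lr$reads)
    srr <- compress_reads(sr)
    write_cps_hcc(lrr, file.path(d, "lr.cps.fa"), file.path(d, "lr.hcc"))
    write_cps_hcc(srr, file.path(d, "sr.cps.fa"), file.path(d, "sr.hcc"))
    sam <- run_aligner(file.path(d, "lr.cps.fa"), file.path(d, "sr.cps.fa"),
                       file.path(d, "sr_vs_lr.sam"))
    recs <- filter_by_error_rate(suppressWarnings(parse_sam(sam, srr)))
    results <- suppressWarnings(correct_reads(lrr, recs, srr))
    cache <<- list(params = p, ref = ref, lr = lr, sr = sr, lrr = lrr,
                   srr = srr, recs = recs, results = results)
    cache
  }
})
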