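test_that("select_candidate follows the SCF scan-and-stop rule", {
  # concordant column: first symbol qualifies after one scan (4/6 > 0.6)
  r <- select_candidate(c("A", "A", "A", "C", "A", "G"), scf = 60)
  expect_equal(r$symbol, "A")
  expect_equal(r$scans, 1L)
  expect_equal(r$freq, 4 / 6)
  # leading minority symbol costs one extra scan
  r <- select_candidate(c("G", "A", "A", "A", "C", "A"), scf = 60)
  expect_equal(r$symbol, "A")
  expect_equal(r$scans, 2L)
  # a permissive threshold accepts the first symbol immediately
  r <- select_candidate(c("G", "A", "A", "A", "C", "A"), scf = 10)
  expect_equal(r$symbol, "G")
  expect_equal(r$scans, 1L)
  # no qualifier: highest frequency wins, ties to the first in the list
  r <- select_candidate(c("T", "C"), scf = 60)
  expect_equal(r$symbol, "T")
  expect_equal(r$scans, 2L)
  # the HC count comes from the first vote carrying the winning symbol
  r <- select_candidate(c("G", "A", "A"), hc_counts = c(9L, 5L, 2L), scf = 60)
  expect_equal(r$symbol, "A")
  expect_equal(r$hc_count, 5L)
  expect_error(select_candidate(character(0)), class = "hcorrect_validation_error")
})

test_that("select_candidate agrees with a brute-force frequency oracle", {
  set.seed(604)
  for (i in 1:300) {
    votes <- sample(c("A", "C", "G", "T", "-"), sample(1:12, 1), replace = TRUE)
    scf <- sample(c(10, 40, 60, 80), 1)
    r <- select_candidate(votes, scf = scf)
    counts <- table(votes)
    qualifies <- counts[r$symbol] / length(votes) > scf / 100
    is_maximal <- counts[r$symbol] == max(counts)
    if (scf > 50) {
      # above 50% at most one symbol can qualify, so the winner is maximal
      expect_true(is_maximal)
    } else {
      # otherwise: maximal, or the first symbol in arrival order to qualify
      first_qualifier <- unique(votes)[which(
        (counts / length(votes))[unique(votes)] > scf / 100)[1]]
      expect_true(is_maximal ||
                    (qualifies && identical(r$symbol, first_qualifier)))
    }
    if (is_maximal && !qualifies) {
      # fallback ties break to first occurrence
      maximal <- names(counts)[counts == max(counts)]
      expect_equal(r$symbol, unique(votes)[unique(votes) %in% maximal][1])
    }
  }
})

test_that("an uncovered read is retained verbatim with no lrLR", {
  lr <- compress_read("AAACGGTTCTTA", "LR")
  lay <- build_layout(lr, data.frame(), new_cr(character(0), character(0), list()))
  res <- correct_long_read(lr, lay)
  expect_equal(res$ecLR, "AAACGGTTCTTA")
  expect_true(all(res$provenance == "retained"))
  expect_true(is.na(res$lrLR))
  expect_true(is.na(res$left_ec) && is.na(res$right_ec))
})

test_that("run lengths are corrected from short-read HC counts (runs of 1 included)", {
  lr <- new_cr("LR", "ACGT", list(rep(1L, 4)))
  sr <- new_cr("s1", "ACGT", list(c(2L, 1L, 1L, 1L)))
  rec <- data.frame(lr_id = "LR", sr_id = "s1", strand = "+", lr_start = 0L,
                    cigar = "4M", edit_distance = 0L, aligned_sr_len = 4L)
  res <- correct_long_read(lr, build_layout(lr, rec, sr))
  expect_equal(res$ecLR, "AACGT")
  expect_true(all(res$provenance == "sr_corrected"))
  expect_equal(res$lrLR, "AACGT")
  expect_equal(c(res$left_ec, res$right_ec), c(0L, 4L))
})

test_that("a gap majority deletes the long-read base", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr(c("s1", "s2", "s3"),
               c("ACTC", "ACTC", "ACGTC"),
               list(rep(1L, 4), rep(1L, 4), rep(1L, 5)))
  recs <- data.frame(lr_id = "LR", sr_id = c("s1", "s2", "s3"), strand = "+",
                     lr_start = 0L, cigar = c("2M1D2M", "2M1D2M", "5M"),
                     edit_distance = 0L, aligned_sr_len = c(4L, 4L, 5L))
  res <- correct_long_read(lr, build_layout(lr, recs, sr))
  expect_equal(res$ecLR, "ACTC")          # gap wins 2/3 > 0.6 at position 2
})

test_that("insertion slots are resolved by the same vote", {
  lr <- new_cr("LR", "ACTC", list(rep(1L, 4)))
  sr <- new_cr(c("s1", "s2", "s3"),
               c("ACGTC", "ACGTC", "ACTC"),
               list(rep(1L, 5), rep(1L, 5), rep(1L, 4)))
  recs <- data.frame(lr_id = "LR", sr_id = c("s1", "s2", "s3"), strand = "+",
                     lr_start = 0L, cigar = c("2M1I2M", "2M1I2M", "4M"),
                     edit_distance = 0L, aligned_sr_len = c(5L, 5L, 4L))
  res <- correct_long_read(lr, build_layout(lr, recs, sr))
  expect_equal(res$ecLR, "ACGTC")         # insertion accepted 2/3 > 0.6
})

test_that("overhanging short reads extend the corrected read", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr("s1", "ACGTCGAG", list(c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L)))
  rec <- data.frame(lr_id = "LR", sr_id = "s1", strand = "+", lr_start = 0L,
                    cigar = "5M3S", edit_distance = 0L, aligned_sr_len = 5L)
  res <- correct_long_read(lr, build_layout(lr, rec, sr))
  expect_equal(res$ecLR, "ACGTCGGAG")     # 3 overhang columns, one with HC 2
  expect_equal(res$provenance[6:9], rep("extended", 4))
  # the covered span runs into the extension
  expect_equal(res$right_ec, nchar(res$ecLR) - 1L)
  expect_equal(res$lrLR, res$ecLR)
})

test_that("scd > 0 treats thin columns as uncovered", {
  lr <- new_cr("LR", "ACGT", list(rep(1L, 4)))
  sr <- new_cr("s1", "TCGT", list(rep(1L, 4)))
  rec <- data.frame(lr_id = "LR", sr_id = "s1", strand = "+", lr_start = 0L,
                    cigar = "4M", edit_distance = 1L, aligned_sr_len = 4L)
  lay <- build_layout(lr, rec, sr)
  # with the depth filter off the single dissenting read rewrites the base
  expect_equal(correct_long_read(lr, lay)$ecLR, "TCGT")
  # with scd = 2 the single-read column falls back to the raw base
  res <- correct_long_read(lr, lay, correction_config(scd = 2L))
  expect_equal(res$ecLR, "ACGT")
  expect_true(all(res$provenance == "retained"))
})

test_that("retained stretches are byte-identical and lrLR nests in ecLR", {
  set.seed(605)
  for (i in 1:15) {
    fix <- random_layout_fixture(n_sr = 3L)
    lay <- build_layout(fix$lr, fix$recs, fix$sr_store)
    res <- correct_long_read(fix$lr, lay)
    # conservation: provenance covers every emitted base
    expect_equal(length(res$provenance), nchar(res$ecLR))
    if (!is.na(res$lrLR)) {
      expect_equal(res$lrLR,
                   substr(res$ecLR, res$left_ec + 1L, res$right_ec + 1L))
      expect_true(grepl(res$lrLR, res$ecLR, fixed = TRUE))
    }
    # retained bases reproduce the decompressed raw read, in order
    ec_chars <- strsplit(res$ecLR, "")[[1]]
    kept <- ec_chars[res$provenance == "retained"]
    # reconstruct the retained image independently from the layout
    n <- nchar(fix$lr$cps[1])
    cov <- unique(lay$votes$pos[lay$votes$rank == 0L &
                                  lay$votes$pos >= 0L & lay$votes$pos < n])
    lr_chars <- strsplit(fix$lr$cps[1], "")[[1]]
    expected_kept <- as.character(unlist(lapply(
      setdiff(0:(n - 1L), cov) + 1L,
      function(j) rep(lr_chars[j], fix$lr$hcc[[1]][j]))))
    expect_equal(kept, expected_kept)
  }
})

test_that("error-free covering short reads reproduce the truth exactly", {
  set.seed(606)
  truth <- rand_seq(300)
  lr <- compress_read(truth, "LR")
  n <- nchar(lr$cps[1])
  # short reads spanning whole runs: windows of 15 compressed bases, step 5
  cstarts <- unique(c(seq(0L, n - 16L, by = 5L), n - 15L))
  lr_chars <- strsplit(lr$cps[1], "")[[1]]
  srs <- data.frame(
    id = sprintf("s%02d", seq_along(cstarts)),
    seq = vapply(cstarts, function(s)
      decompress(paste(lr_chars[(s + 1):(s + 15)], collapse = ""),
                 lr$hcc[[1]][(s + 1):(s + 15)]), character(1)))
  sr <- compress_reads(srs)
  recs <- data.frame(lr_id = "LR", sr_id = srs$id, strand = "+",
                     lr_start = cstarts, cigar = "15M",
                     edit_distance = 0L, aligned_sr_len = 15L)
  res <- correct_long_read(lr, build_layout(lr, recs, sr))
  expect_equal(res$ecLR, truth)
  expect_true(all(res$provenance == "sr_corrected"))
})

test_that("write_corrected emits full and covered-span files correctly", {
  cov <- structure(list(lr_id = "r1", ecLR = "ACGTACGT", lrLR = "CGTACG",
                        left_ec = 1L, right_ec = 6L,
                        provenance = c("retained", rep("sr_corrected", 6),
                                       "retained")),
                   class = "correction_result")
  uncov <- structure(list(lr_id = "r2", ecLR = "TTTT", lrLR = NA_character_,
                          left_ec = NA_integer_, right_ec = NA_integer_,
                          provenance = rep("retained", 4)),
                     class = "correction_result")
  d <- withr::local_tempdir()
  write_corrected(list(cov, uncov), file.path(d, "lr.fa"), file.path(d, "full.fa"))
  full <- read_reads(file.path(d, "full.fa"))
  expect_equal(full$id, c("r1", "r2"))
  expect_equal(full$seq, c("ACGTACGT", "TTTT"))
  lrlr <- read_reads(file.path(d, "lr.fa"))
  expect_equal(lrlr$id, "r1")
  expect_equal(lrlr$seq, "CGTACG")

  # zero reads -> two empty valid FASTA files
  write_corrected(list(), file.path(d, "e1.fa"), file.path(d, "e2.fa"))
  expect_equal(nrow(read_reads(file.path(d, "e1.fa"))), 0L)
  expect_equal(nrow(read_reads(file.path(d, "e2.fa"))), 0L)
})
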