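simple_rec <- function(sr_id, lr_start, cigar, strand = "+") {
  data.frame(lr_id = "LR", sr_id = sr_id, strand = strand,
             lr_start = lr_start, cigar = cigar, edit_distance = 0L,
             aligned_sr_len = 1L, stringsAsFactors = FALSE)
}

test_that("a single fully matching short read yields one vote per position", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr("s1", "ACGTC", list(c(2L, 1L, 1L, 1L, 3L)))
  lay <- build_layout(lr, simple_rec("s1", 0L, "5M"), sr)
  expect_equal(nrow(lay$votes), 5L)
  expect_equal(lay$votes$pos, 0:4)
  expect_equal(lay$votes$rank, rep(0L, 5))
  expect_equal(lay$votes$symbol, c("A", "C", "G", "T", "C"))
  expect_equal(lay$votes$hc, c(2L, 1L, 1L, 1L, 3L))
  expect_equal(lay$left, 0L)
  expect_equal(lay$right, 4L)
})

test_that("mismatch votes line up in record order at the same column", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr(c("s1", "s2", "s3"),
               c("ACGTC", "ACGTC", "ACGAC"),
               list(rep(1L, 5), rep(1L, 5), rep(1L, 5)))
  recs <- rbind(simple_rec("s1", 0L, "5M"), simple_rec("s2", 0L, "5M"),
                simple_rec("s3", 0L, "5M"))
  lay <- build_layout(lr, recs, sr)
  col <- lay$votes[lay$votes$pos == 3L & lay$votes$rank == 0L, ]
  expect_equal(col$symbol, c("T", "T", "A"))
  # layout is invariant to input record order (records sorted internally)
  lay2 <- build_layout(lr, recs[c(3, 1, 2), ], sr)
  expect_identical(as.data.frame(lay$votes), as.data.frame(lay2$votes))
})

test_that("soft clips past the read ends populate overhang columns", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr("s1", "TTACGTCGG", list(rep(1L, 9)))
  lay <- build_layout(lr, simple_rec("s1", 0L, "2S5M2S"), sr)
  left <- lay$votes[lay$votes$pos < 0L, ]
  expect_equal(left$pos, c(-2L, -1L))
  expect_equal(left$symbol, c("T", "T"))
  right <- lay$votes[lay$votes$pos >= 5L, ]
  expect_equal(right$pos, c(5L, 6L))
  expect_equal(right$symbol, c("G", "G"))
  # covered extremes ignore the overhangs
  expect_equal(lay$left, 0L)
  expect_equal(lay$right, 4L)
})

test_that("deletions vote gaps and spanning reads gap-vote insertion slots", {
  lr <- new_cr("LR", "ACGTC", list(rep(1L, 5)))
  sr <- new_cr(c("s1", "s2"),
               c("ACTC", "ACGGTC"),
               list(rep(1L, 4), rep(1L, 6)))
  recs <- rbind(simple_rec("s1", 0L, "2M1D2M"),    # deletes LR pos 2
                simple_rec("s2", 0L, "3M1I2M"))    # inserts G after pos 2
  lay <- build_layout(lr, recs, sr)
  del_col <- lay$votes[lay$votes$pos == 2L & lay$votes$rank == 0L, ]
  expect_equal(del_col$symbol, c("-", "G"))        # s1 gap, s2 base
  ins_col <- lay$votes[lay$votes$rank == 1L, ]
  expect_equal(ins_col$pos, c(2L, 2L))
  # s1 spans the junction without inserting -> gap vote; s2 votes its base
  expect_equal(ins_col$symbol[ins_col$ord == 1L], "-")
  expect_equal(ins_col$symbol[ins_col$ord == 2L], "G")
})

test_that("reverse-strand records vote with re-oriented bases and counts", {
  lr <- new_cr("LR", "ACGT", list(rep(1L, 4)))
  # aligned (oriented) form should be ACGT with counts 4,3,2,1;
  # the store holds the forward orientation: revcomp ACGT with reversed counts
  oriented <- new_cr("s1", "ACGT", list(c(4L, 3L, 2L, 1L)))
  fwd <- reverse_orientation(oriented)
  lay <- build_layout(lr, simple_rec("s1", 0L, "4M", strand = "-"), fwd)
  expect_equal(lay$votes$symbol, c("A", "C", "G", "T"))
  expect_equal(lay$votes$hc, c(4L, 3L, 2L, 1L))
})

test_that("records walking past the long-read end are rejected with a warning", {
  lr <- new_cr("LR", "ACGT", list(rep(1L, 4)))
  sr <- new_cr("s1", "ACGTAC", list(rep(1L, 6)))
  expect_warning(lay <- build_layout(lr, simple_rec("s1", 2L, "6M"), sr),
                 "past the long-read end")
  expect_equal(nrow(lay$votes), 0L)
})

test_that("column conservation and covered extremes hold on random layouts", {
  set.seed(603)
  for (i in 1:25) {
    fix <- random_layout_fixture()
    lay <- build_layout(fix$lr, fix$recs, fix$sr_store)
    n <- nchar(fix$lr$cps[1])
    inside <- lay$votes[lay$votes$pos >= 0L & lay$votes$pos < n, ]
    # non-gap votes inside the read == M/=/X/I bases of the records
    ops <- GenomicAlignments::explodeCigarOps(fix$recs$cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(fix$recs$cigar)
    expected <- sum(mapply(function(o, l) sum(l[o %in% c("M", "=", "X", "I")]),
                           ops, lens))
    expect_equal(sum(inside$symbol != "-"), expected)
    # left/right against an independent reference-space computation
    covered <- unlist(mapply(function(o, l, s) {
      r <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        paste0(l, o, collapse = ""), pos = s + 1L, ops = c("M", "=", "X", "D"))[[1]]
      unlist(lapply(seq_along(r), function(j)
        seq(BiocGenerics::start(r)[j], BiocGenerics::end(r)[j])))
    }, ops, lens, fix$recs$lr_start, SIMPLIFY = FALSE)) - 1L
    expect_equal(lay$left, min(covered))
    expect_equal(lay$right, max(covered))
  }
})
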