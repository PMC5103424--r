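#' Build the per-position candidate layout for one compressed long read
#'
#' Walks each accepted alignment's CIGAR and collects, for every covered
#' compressed long-read position, the ordered list of `(symbol, HC count)`
#' votes cast by the aligned short reads:
#'
#' * `M`/`=`/`X` operations vote the short-read base and its HC count at
#'   successive long-read positions (insertion rank 0);
#' * `I` operations vote at insertion slots keyed to the preceding long-read
#'   position, one slot per inserted base (ranks 1..k);
#' * `D` operations vote the gap symbol `-` (HC count 1, never expanded) at
#'   each deleted long-read position;
#' * terminal `S` (soft-clip) bases that extend past a long-read end populate
#'   overhang columns at positions outside `[0, n)`, which the corrector uses
#'   to extend the read.
#'
#' Every short read that spans an insertion slot without inserting there
#' additionally votes a gap at that slot, so insertions are accepted or
#' rejected by the same frequency rule as substitutions.  Records are sorted
#' by `(lr_start, sr_id)` before voting, which makes vote order -- and hence
#' the corrector's "first in the list" tie-break -- deterministic and
#' independent of input order or chunking.  Reverse-strand records vote with
#' the reverse-complemented compressed sequence and reversed HC counts.
#'
#' @param lr a length-1 [compressed_reads] object (the long read).
#' @param recs alignment records for this long read (see [parse_sam()]).
#' @param sr_store [compressed_reads] object resolving all `sr_id`s.
#' @return An object of class `lr_layout`: list with `lr_id`, `n` (compressed
#'   long-read length), `votes` (data.table with columns `pos`, `rank`,
#'   `symbol`, `hc`, `ord`, ordered by column then vote arrival), `left` and
#'   `right` (extreme covered positions inside the read, `NA` if uncovered).
#' @export
build_layout <- function(lr, recs, sr_store) {
  lr <- validate_compressed_reads(lr)
  sr_store <- validate_compressed_reads(sr_store)
  if (length(lr) != 1L)
    abort_validation("build_layout: 'lr' must contain exactly one read")
  n <- nchar(lr$cps[1L])
  if (nrow(recs) && any(recs$lr_id != lr$id[1L]))
    abort_validation("build_layout: records referencing a different long read")

  empty <- data.table::data.table(pos = integer(0), rank = integer(0),
                                  symbol = character(0), hc = integer(0),
                                  ord = integer(0))
  if (!nrow(recs)) {
    return(structure(list(lr_id = lr$id[1L], n = n, votes = empty,
                          left = NA_integer_, right = NA_integer_),
                     class = "lr_layout"))
  }

  recs <- recs[order(recs$lr_start, recs$sr_id), , drop = FALSE]
  idx <- match(recs$sr_id, sr_store$id)
  if (anyNA(idx))
    abort_validation("build_layout: unresolvable short-read id")
  ops_all <- GenomicAlignments::explodeCigarOps(recs$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(recs$cigar)

  pieces <- vector("list", nrow(recs))
  span <- matrix(NA_integer_, nrow(recs), 2L)  # aligned LR interval [s, e)
  n_rejected <- 0L
  for (r in seq_len(nrow(recs))) {
    sr <- sr_store[idx[r]]
    if (recs$strand[r] == "-") sr <- reverse_orientation(sr)
    sr_chars <- strsplit(sr$cps[1L], "", fixed = TRUE)[[1L]]
    sr_hcc <- sr$hcc[[1L]]
    ops <- ops_all[[r]]; lens <- lens_all[[r]]
    lrp <- recs$lr_start[r]   # next LR position (0-based)
    si <- 1L                  # next SR base (1-based)
    pos <- integer(0); rank <- integer(0); sym <- character(0); hc <- integer(0)
    ok <- TRUE
    for (j in seq_along(ops)) {
      op <- ops[j]; len <- lens[j]
      if (op %in% c("M", "=", "X")) {
        if (lrp + len > n || si + len - 1L > length(sr_chars)) { ok <- FALSE; break }
        k <- seq_len(len)
        pos <- c(pos, lrp + k - 1L); rank <- c(rank, integer(len))
        sym <- c(sym, sr_chars[si + k - 1L]); hc <- c(hc, sr_hcc[si + k - 1L])
        lrp <- lrp + len; si <- si + len
      } else if (op == "I") {
        if (si + len - 1L > length(sr_chars)) { ok <- FALSE; break }
        if (lrp > 0L) {  # needs a preceding LR base to anchor the slot
          k <- seq_len(len)
          pos <- c(pos, rep.int(lrp - 1L, len)); rank <- c(rank, k)
          sym <- c(sym, sr_chars[si + k - 1L]); hc <- c(hc, sr_hcc[si + k - 1L])
        }
        si <- si + len
      } else if (op == "D") {
        if (lrp + len > n) { ok <- FALSE; break }
        k <- seq_len(len)
        pos <- c(pos, lrp + k - 1L); rank <- c(rank, integer(len))
        sym <- c(sym, rep.int("-", len)); hc <- c(hc, rep.int(1L, len))
        lrp <- lrp + len
      } else if (op == "S") {
        if (si + len - 1L > length(sr_chars)) { ok <- FALSE; break }
        k <- seq_len(len)
        if (j == 1L) {
          p <- lrp - rev(k)            # positions just left of lr_start
          keep <- p < 0L
        } else if (j == length(ops)) {
          p <- lrp + k - 1L            # positions from the current LR end on
          keep <- p >= n
        } else {
          keep <- logical(len)         # internal clip: ignore
          p <- integer(len)
        }
        if (any(keep)) {
          pos <- c(pos, p[keep]); rank <- c(rank, integer(sum(keep)))
          sym <- c(sym, sr_chars[(si + k - 1L)[keep]])
          hc <- c(hc, sr_hcc[(si + k - 1L)[keep]])
        }
        si <- si + len
      } else {
        ok <- FALSE; break   # N or other ops unsupported in this context
      }
    }
    if (!ok) { n_rejected <- n_rejected + 1L; next }
    span[r, ] <- c(recs$lr_start[r], lrp)
    if (length(pos)) {
      pieces[[r]] <- data.table::data.table(pos = pos, rank = rank,
                                            symbol = sym, hc = hc, ord = r)
    }
  }
  if (n_rejected > 0L)
    warning(sprintf("build_layout: rejected %d record(s) walking past the long-read end",
                    n_rejected))

  votes <- data.table::rbindlist(pieces)
  if (!nrow(votes)) {
    return(structure(list(lr_id = lr$id[1L], n = n, votes = empty,
                          left = NA_integer_, right = NA_integer_),
                     class = "lr_layout"))
  }

  # Spanning reads vote a gap at insertion slots they bridge without using.
  rank <- pos <- ord <- NULL  # data.table NSE
  slots <- unique(votes[rank > 0L, list(pos, rank)])
  if (nrow(slots)) {
    spans <- data.table::data.table(ord = seq_len(nrow(recs)),
                                    s = span[, 1L], e = span[, 2L])
    spans <- spans[!is.na(spans$s)]
    cand <- spans[, {
      sel <- slots$pos >= s & slots$pos + 1L < e
      list(pos = slots$pos[sel], rank = slots$rank[sel])
    }, by = ord]
    if (nrow(cand)) {
      cand <- cand[!votes[rank > 0L], on = c("pos", "rank", "ord")]
      if (nrow(cand)) {
        votes <- rbind(votes,
                       data.table::data.table(pos = cand$pos, rank = cand$rank,
                                              symbol = "-", hc = 1L,
                                              ord = cand$ord))
      }
    }
  }
  data.table::setorder(votes, pos, rank, ord)

  inside <- votes$pos[votes$pos >= 0L & votes$pos < n]
  structure(list(lr_id = lr$id[1L], n = n, votes = votes,
                 left = if (length(inside)) min(inside) else NA_integer_,
                 right = if (length(inside)) max(inside) else NA_integer_),
            class = "lr_layout")
}

#' @export
print.lr_layout <- function(x, ...) {
  cat(sprintf("lr_layout for '%s': %d compressed bases, %d vote(s), covered [%s, %s]\n",
              x$lr_id, x$n, nrow(x$votes), x$left, x$right))
  invisible(x)
}
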