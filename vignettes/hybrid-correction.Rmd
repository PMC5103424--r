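---
title: "Hybrid long-read error correction by homopolymer-compressed short-read consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid long-read error correction by homopolymer-compressed short-read consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcorrect)
```

## The problem and the model

SMRT transcriptome long reads carry roughly 15 % random error, dominated by
single-base insertions and deletions that cluster in homopolymer runs.
Short reads from the same sample are short but highly accurate (> 98 %). The
correction model treats the short reads as the evidence and the long read as
a scaffold: wherever enough short-read evidence covers the long read, the
evidence wins; wherever none does, the raw long read is retained.

A direct alignment of short reads to 15 %-error long reads fails, because the
indel density breaks seed matching. The key transform is homopolymer
compression (HC): every maximal run of identical bases is replaced by one
base, and the run length is stored in a parallel integer array. Two
properties make this work:

* most long-read indels only change homopolymer run lengths, so they vanish
  in compressed space — compressed short reads and compressed long reads are
  far more similar than their raw forms;
* the count arrays make the transform lossless, so consensus decisions made
  in compressed space can be expanded back to base space exactly.

We record an HC count for *every* compressed base, including runs of length
one. That is deliberate: a run of length 1 in the long read may well be a
run of length 2 in the truth (or vice versa), and the only way to correct it
is to carry the short-read count for that position too. The count array is
indexed implicitly by position; no separate index array is stored.

## The voting rule

After alignment, each compressed long-read position accumulates an ordered
candidate list of `(base, HC count)` votes from the short reads covering it.
Deletions vote an explicit gap symbol; each inserted base gets its own
insertion-slot column keyed `(position, rank)`; and every short read that
bridges an insertion slot without inserting there votes a gap in that slot,
so insertions must beat the same frequency bar as substitutions.

A column is resolved by a scan-and-stop rule controlled by the
short-reads coverage frequency (SCF, an integer percent, default 60):

1. walk the votes in arrival order; at each previously unseen base compute
   its frequency over the whole column;
2. the first base whose frequency **strictly** exceeds `SCF/100` wins
   immediately;
3. if no base qualifies, the most frequent base wins, ties broken by first
   arrival.

With concordant coverage the scan stops after a single distinct symbol, so
the per-column cost is effectively constant — that, not the asymptotics, is
what makes the corrector fast. The strictness of the comparison matters for
reproducibility: a column of exactly 60 % agreement at SCF = 60 falls
through to the next symbol or the fallback. The winning base is expanded
with the HC count of the *first* vote that carried it (the vote the scan
stopped at); averaging counts across votes would cost a second pass for no
demonstrated benefit, and keeps behaviour identical to the single-scan cost
model.

Because "first in the list" is order-sensitive, alignment records are sorted
by `(lr_start, sr_id)` before voting. This makes every output deterministic
and independent of input order and of how the short-read file was chunked
across threads.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `scf` | 60 | percent | frequency a base must strictly exceed to win a column; higher = stricter, more fallbacks |
| `scd` | 0 (off) | votes | minimum column depth; columns below it are treated as uncovered. Kept only as a compatibility switch — accurate short reads make depth filtering unnecessary |
| `min_length` | 40 | bases (raw) | QC: reads shorter than this are dropped (a 40 bp read is kept) |
| `max_n_fraction` | 0.05 | fraction | QC: drop reads whose N fraction strictly exceeds this |
| `max_error_rate` | 15 | percent | drop alignments with `100*NM/aligned_sr_bases` strictly above this; matches the raw long-read error scale |
| `threads` | 1 | — | chunking of the short-read set and aligner threads; results are invariant to it |

QC applies to the raw (uncompressed) length — the length cutoff describes
sequenced bases, not compressed ones — and runs before compression. `N` is
treated as an ordinary fifth symbol during compression; QC already removes
N-heavy reads, and special-casing `N` in runs would only complicate the
inverse transform.

## Alignment contract

The aligner is a subprocess contract: anything that writes SAM against the
compressed long reads as references can be used, and a pre-computed SAM can
be passed to the pipeline directly. The default is minimap2 with
`-a -k9 -w2 -A1 -B2 -O2,16 -E2,1 -s20 -m15`: compressed-space divergence
between accurate short reads and a 15 %-error long read is still several
percent (substitutions, inserted off-run bases and deleted length-1 runs
survive compression), so short seeds, a dense minimizer window and permissive
chain scores are needed for ~60 bp compressed queries. Local alignment is
intentional: overhangs at the long-read ends then appear as soft clips,
which is exactly the evidence used to extend the read.

From each SAM we keep mapped primary records only (one vote per short read),
convert 1-based `POS` to 0-based coordinates at the parse boundary (all
internal coordinates are 0-based, half-open), take the edit distance from
`NM` when present and otherwise recompute it from `=`/`X`/`I`/`D`
operations, and re-orient reverse-strand reads (reverse-complemented
compressed bases, reversed HC counts) before voting. The error-rate
denominator is the number of compressed short-read bases the alignment
consumed (`M`/`=`/`X`/`I`); using the full read length would let heavily
clipped alignments pass on the strength of bases that were never aligned.

## Correction pass, span and extension

The corrector traverses compressed positions `0..n-1`, visiting each
position's insertion slots in rank order. Covered columns emit the winner's
expansion (tag `sr_corrected`), gap winners emit nothing, uncovered
positions emit the raw read's own expansion (tag `retained`). Overhang
columns are resolved with the same rule and appended or prepended (tag
`extended`); the extension stops at the first overhang offset no short read
reaches, so an extension can never contain holes. Insertions proposed before
the first aligned long-read base have no anchorable slot and are ignored.

Two output sequences are emitted per read: the full corrected read (ecLR)
and the lrLR, its span between the outermost short-read-derived bases. We
define that span over provenance — from the first to the last base tagged
`sr_corrected` or `extended` — so end extensions, which are short-read
evidence by construction, fall inside the lrLR while uncovered flanks fall
outside. Interior uncovered stretches remain inside the span, retained
verbatim. A read with no covered column yields no lrLR record at all: a
covered span needs at least one covered point, so nothing is written for it
to the lrLR file (the ecLR, equal to the raw read, still appears in the full
file). Note the corrected span length generally differs from the covered raw
span length, since correction changes run lengths and indels.

## Evaluation definitions

Sequence identity is `SI = matches / read length` — the full read length,
not the aligned span, so unalignable tails count against the read. When
summarizing a PSL file, the best alignment per read is the one with maximal
`matches` (ties: first in file), and threshold summaries (`SI >= 0.9` etc.)
are inclusive and computed over mapped reads only.

Error tallies classify gapped read-vs-truth columns as mismatch, insertion
or deletion. An indel whose base equals an adjacent truth base is
additionally a homopolymer (HC) error — it changed a run's length, not its
content — and when that truth run has length 1 it enters the `HC = 1`
subset. This operational definition is pinned by the tests; "HC error" has
no universally agreed definition, and we count only indels (not mismatches at
length-1 runs) because a mismatch changes content, not run length.

## The simulator

`sim_params()` defaults encode the study regime: 5 transcripts of 800–1200
bp; long reads with per-base substitution/insertion/deletion rates
0.01/0.08/0.06 (~15 % total, indel-dominated); error-free 75 bp short reads
at 20-fold coverage. Indel probabilities are multiplied by
`homopolymer_bias` (default 3) inside runs of length >= 2, and the base rate
is rescaled so the transcript-average indel rate stays at its nominal value
— the bias redistributes errors toward runs rather than inflating the total,
keeping "15 % error" and "3x enrichment in runs" simultaneously true. Errors
are placed by independent per-base Bernoulli draws; the exact gapped
read/truth alignment of every read is recorded, so injected errors are
recoverable without realignment. All outputs are byte-reproducible under the
seed (reference, long-read and short-read stages draw from seed, seed+1 and
seed+2 respectively, so regenerating one stage never perturbs another).

What the simulator does *not* emulate: chimeric reads, adapter artifacts,
quality-score structure, coverage bias along transcripts, or a trained
platform error profile. Passing tests on simulated data therefore
demonstrate the correction logic under the stated error model, not
performance on any particular instrument's reads.

## Numerical and degenerate-input choices

* Empty sequences, ragged count arrays, non-positive counts, and empty vote
  columns are rejected with classed validation errors; empty read sets and
  header-only SAM files flow through as empty results.
* CIGARs containing `H`/`P` are skipped with a warning; records whose CIGAR
  walks past the compressed read end are rejected with a warning.
* Sequences are uppercased on input so letter case never splits a run.
* Gap votes carry a fixed HC count of 1 and are never expanded.
* With `scd > 0`, a thin rank-0 column falls back to the retained raw base,
  a thin insertion slot is skipped, and a thin overhang column terminates
  the extension on that side.

## Test problem sizes

The property suite round-trips 10,000 random reads (lengths 1–500 over
`{A,C,G,T,N}`) through compression, checks the voting rule against a
brute-force frequency oracle on 1,000 random columns, and verifies layout
conservation and span invariants on randomized synthetic layouts. The
recovery test runs the full pipeline (simulation, minimap2 alignment,
correction) on the default 5-transcript regime and checks that bases the
corrector marked `sr_corrected` match the truth at >= 99 % while the raw
reads sit at or below 90 % nucleotide accuracy (matches over alignment
columns — deletions count as errors), and that corrected reads beat their
raw versions in sequence identity on at least 95 % of covered reads. These
sizes keep the whole suite within a couple of minutes on one CPU while
leaving the binomial noise on every asserted rate far smaller than the
margins being tested.

## Known limitations

* A short read whose end falls mid-run votes a truncated HC count at its
  terminal column. The first-vote rule makes such votes rarely decisive
  (the earliest-starting read usually supplies the first vote, and its ends
  lie elsewhere), but residual run-length errors near coverage boundaries
  are possible.
* Correction quality is bounded by compressed-space mapping: regions whose
  surviving divergence defeats the aligner stay uncovered and are retained
  as-is.
* One pass only: no iterative re-alignment against the corrected read, no
  quality scores on output, and corrected reads are hybrid consensus
  sequences, not single-molecule observations.
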