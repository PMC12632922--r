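---
title: "Move-structure indexing of pangenomes: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Move-structure indexing of pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A pangenome is a collection of closely related genomes indexed jointly — for
example hundreds of haplotypes of one species. Its total length `n` grows
linearly with the number of haplotypes, but its information content does not:
the Burrows–Wheeler transform (BWT) of the concatenated collection groups
characters by the lexicographic order of their right contexts, so repeated
context produces maximal equal-letter *runs*, and the run count `r` grows far
more slowly than `n`. `n / r` is the effective compression ratio, and
`O(r)`-sized indexes are what make full-text queries on pangenomes practical.

`moveindex` implements one such index, the *move structure*: a single table
with one row per (possibly split) BWT run, supporting the LF-mapping — the
bijection that steps right-to-left through the text — in constant-ish time
with high locality of reference, plus the *Pseudo Matching Length* (PML)
query used for read classification.

## The model

Let `T` be the concatenated DNA collection over `{A,C,G,T}` with one terminal
sentinel `$` that sorts before every base. Writing `L = BWT(T)`,

* `LF(i) = C(L[i]) + rank_{L[i]}(i, L)`, where `C(c)` counts text symbols
  smaller than `c` and `rank_c(i, L)` counts occurrences of `c` in `L[1..i]`.
* Each move row stores its run symbol `c`, length `l`, the offset `f` of the
  LF image of the row head inside its *destination row*, and the destination
  row id `xi`. A BWT offset is carried as a pair `(u, v)` — row index plus
  0-based in-row offset — so `LF(u, v)` is `v'' = f[u] + v` starting at row
  `xi[u]`, followed by a *fast-forward* scan that walks forward row by row
  while `v''` overflows the current row's length.
* For every pair of adjacent same-symbol runs a *threshold* splits the gap
  between them: on a mismatch, offsets before the threshold reposition up to
  the earlier run's tail, offsets at or after it reposition down to the later
  run's head. This is what directs the PML recurrence
  `PML[k] = PML[k+1] + 1` on a match, `0` on a mismatch, computed right to
  left from the final BWT offset.

PMLs are a positionwise *lower bound* on the matching statistics
`MS[k]` (the longest prefix of `P[k..m]` occurring in `T`). The bound is
sound for *any* reposition choice — a reposition always lands on a row whose
symbol matches, so every subsequent increment witnesses a real substring —
and thresholds only make the bound tighter, not correct-er. The test suite
checks both: soundness against a quadratic matching-statistics oracle, and
the exact trace against an independent step-by-step implementation that
works on global BWT offsets with no move table at all.

## Row splitting

Two transforms are applied to the maximal-run partition before pointers are
computed, in a fixed order, and pointers (`f`, `xi`) are derived once on the
final row set so they never need remapping:

1. **Thresholds-splitting** cuts every row at each distinct strictly-interior
   threshold it contains (coincident cut points from different symbols are
   cut once). Afterwards every row-relative threshold sits at `0` or at the
   row length, so *one bit per mismatch symbol* (3 bits for DNA) replaces
   three full-width offsets — a 16-fold reduction relative to 16-bit
   threshold fields. There is at most one threshold per adjacent same-symbol
   run pair and at most `r` pairs, so the row count at most doubles; in
   practice the synthetic pangenome fixtures add ~8%.
2. **Length-splitting** caps the row length at `l_max = 2^length_bits - 1`,
   cutting a long run into `ceiling(l / l_max)` sub-runs, all but the last of
   length `l_max` (exact multiples produce no zero-length remainder). This
   bounds the `l` and `f` columns to `length_bits` bits each.

Splitting never changes a query result; the suite asserts bitwise-identical
PMLs across every combination of stages.

## The three id representations

The destination id `xi` is the widest column (36 bits by default). Because
LF is stable, the ids of same-symbol rows are non-decreasing — asserted at
build time — which enables two compressed forms:

* **blocked**: the table is divided into blocks of `b` rows; a checkpoint
  table `B` stores, per block and symbol, the id of the first row of that
  symbol at or after the block start (within the block); each row keeps only
  the 23-bit delta against its checkpoint. If a delta overflows, `b` is
  halved and the table rebuilt — mirroring the fact that very repetitive
  collections may need a smaller block size.
* **sampled**: checkpoints every `s` rows (the `S` table) and *no* per-row id
  at all. At query time the scan counts the BWT length of same-symbol rows
  between the checkpoint's first matching row and the query row, then
  fast-forwards that distance from the checkpointed destination. The scan
  touches at most `s - 1` rows; `s` trades index size against query time.

The bit-packed on-disk layouts are 8, 6 and 3 bytes per row for the
default / blocked / sampled variants (`c:2, l:11, f:11, xi:36, thr:3, spare:1`;
`c:2, l:10, f:10, delta:23, thr:3`; `c:2, l:9, f:9, thr:3, spare:1`), with
checkpoint ids stored at 40 bits — 20 bytes per checkpoint — which makes the
S table 13.33% / 6.67% / 3.33% of the row array at `s` = 50 / 100 / 200.
Narrower length fields force more length-splitting; that is the price of the
3-byte row, and the shipped defaults (11 / 10 / 9 bits) follow that tradeoff.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `length_bits` | 11 / 10 / 9 by variant | width of `l` and `f`; `l_max = 2^bits - 1` |
| `block_size` | 2048 rows | blocked checkpoint spacing; auto-halved on delta overflow |
| `sample_rate` | 50 rows | sampled checkpoint spacing; bounds the id scan |
| `policy` | `"substitute"` | non-ACGT bases become `A`, deterministically, with a count kept in the header |

## Conventions and numerical choices

* **Coordinates**: text and BWT offsets are 1-based (as in the standard BWT
  presentation); the in-row offset `v` is 0-based. Row indices are 1-based.
* **Threshold choice**: between two candidate-rich runs any valid threshold
  may be chosen; we take the *leftmost position of the minimum LCP value* in
  the half-open gap. A range-minimum argument shows this satisfies both
  defining LCP inequalities, and `verify_threshold()` re-checks them by
  brute force on every fixture.
* **Direction convention**: `v < t` repositions up, `v >= t` down — i.e. the
  threshold offset itself belongs to the "down" half. The trivialised bit
  stores "up" as threshold-at-`l`.
* **Sentinel row**: the 2-bit symbol field cannot encode a fifth symbol. The
  single sentinel row carries symbol code 0 in memory (so no scan ever
  matches it), the header records its index, and its destination id is the
  constant 1 (`LF` of the sentinel is BWT offset 1). Its serialized
  threshold bits cover `C,G,T` as if its symbol were `A`; the `A` direction
  at that single length-1 row is fixed by a rule recomputable from the row
  array alone — down iff an `A` row exists below it — applied identically at
  build and at load, so all variants and round-trips agree exactly. PML
  soundness is unaffected by this choice (see above); only the tightness of
  one row could be, and that row has length 1.
* **Multi-record input** is concatenated with a single terminal sentinel and
  no per-record separators, keeping the alphabet at 4+1 and the symbol field
  at 2 bits. Matches straddling a record boundary are therefore possible;
  record boundaries are kept in the text object for callers who care.
* **Fast-forward** has no hard bound (the balanced-splitting scheme that
  guarantees one is deliberately out of scope); a guard caps it at the row
  count to catch corruption, and the `stats` surface reports the measured
  mean, which is well below 1 on all fixtures.
* **PML recurrence**: `PML[m] = 0` literally, even when `P[m]` matches — the
  comparison at `k = m` still directs the first movement. Movement also
  happens at `k = 1`; it is harmless and keeps the loop uniform. The start
  position is the last BWT offset (any offset would do).
* **Absent query symbols** (possible on tiny or skewed references) yield
  `PML = 0` at that position with the walk left in place.

## The synthetic generator

`generate_pangenome()` emulates exactly the property that makes `O(r)`
indexes worthwhile: one random base genome plus closely related copies, so
`n` grows linearly with haplotype count while `r` barely moves (a suite test
measures this). The defaults — 20 haplotypes of a 50 kb base at 0.1%
substitution divergence with sparse short indels (rate 2e-4, length 1–10) —
are the package's standing study conditions for the regression statistics.
Reads are drawn uniformly with per-base substitution errors.

What the generator does *not* emulate: real variation spectra (structural
variants, CNVs, hotspots), sequencing error profiles (homopolymer indels,
quality-dependent errors), or contamination. Passing tests therefore
demonstrate correctness of the data structure and queries on
pangenome-shaped inputs, not classification accuracy on real sequencing
runs.

Adversarial fixtures complement it: a periodic text whose BWT runs exceed
`2^11 - 1` (forcing length-splitting at every shipped width), a short text
with a verified non-trivial threshold (forcing thresholds-splitting), and a
text with `r = n` where neither stage may add a single row. The latter two
were found by searching short seeded random texts for the desired property.

## Problem sizes used by the test and acceptance suites

All fixtures are generated in code at run time. The oracle sweeps use 50
seeded texts of 60–2,500 bases, checked at *every* BWT offset for all three
variants against the direct rank-formula LF; threshold verification is
exhaustive over every adjacent same-symbol run pair of the same texts; id
compression is compared row-by-row against uncompressed ids for block sizes
{8, 2048} and sampling rates {2, 50, 200}; PML properties use 50 (text,
read) pairs plus the analytic micro-fixture `ACACGT$`. The layout and
splitting statistics are measured on the 20-haplotype, 50 kb study fixture
(about 1 Mb of text). These sizes were chosen so that the brute-force
oracles — quadratic matching statistics, per-pair LCP range scans — remain
exhaustive rather than sampled.

## Known limitations

* PML is the only query: no count/locate, no suffix-array sampling, no
  SMEMs, no reverse-complement-aware search (query both strands explicitly
  if needed).
* Index construction is in-memory (suffix array by prefix doubling, LCP by
  Kasai's algorithm); it is intended for method-scale references, not for
  building human-pangenome-scale indexes.
* The classification-style assertion (reads from the indexed collection
  score far above unrelated reads) is a fixture-level sanity check, not a
  calibrated null model.
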