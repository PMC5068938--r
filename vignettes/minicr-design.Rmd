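---
title: "Designing miniCRISPR loci for type III RNA silencing: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing miniCRISPR loci for type III RNA silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicrdesign)
```

## The model

Type III (CMR/CSM) CRISPR effector complexes cleave RNA complementary to
the spacer portion of their crRNA. Whether the host machinery additionally
attacks the encoding DNA is decided by an antitag check: each mature crRNA
carries an 8-nt 5′ handle, the transcribed tail of the repeat, and if the
8 nt immediately 3′ of the protospacer on the target (the
protospacer-adjacent sequence, PAS) base-pair that handle, the locus is
treated as "self" — DNA interference is suppressed while RNA cleavage is
unaffected. Gene silencing designs therefore *want* PAS–handle
complementarity, the opposite of what DNA-editing guide design optimises.

Conventions used throughout the package:

* handle positions are numbered −8…−1, with −1 adjacent to the spacer; the
  `handle_rna` string is written 5′→3′, so its first character is −8;
* PAS positions are +1…+8 downstream of the protospacer; pairing is
  antiparallel, +i against −i;
* pair classes are Watson-Crick (`A:U`, `U:A`, `G:C`, `C:G`), G:U wobble
  (`G:U`, `U:G`) and mismatch;
* coordinates are 1-based inclusive everywhere except BED output (0-based
  half-open, per the BED standard).

Two acceptance criteria are implemented for protospacer selection:

* **full** — the PAS pairs at least `min_paired` (default 6) of the 8
  handle positions;
* **minimal** — the PAS pairs all of `minimal_positions` (default
  −3/−4/−5), the 3-nt motif that suffices to suppress DNA cleavage.

Whether wobble positions count toward either criterion is not settled by
the experimental literature: accepted designs display G:U pairs in their
PAS alignments, but reported pairing counts never state the convention.
We default to `wobble_counts_as_paired = TRUE` (a wobble pair stabilises an
RNA duplex, and the displayed designs suggest it was counted) and expose
the switch in `pas_config()`; the genome survey reports both settings.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `protospacer_length` | 37 | nt | the window length used for targeting spacers |
| `min_paired` | 6 | positions of 8 | full-criterion threshold |
| `minimal_positions` | −3,−4,−5 | handle positions | minimal antitag motif |
| `wobble_counts_as_paired` | TRUE | — | see above; configurable off |
| `min_separation` | 2 × protospacer length | nt | multiplexed spacers should hit well-separated positions |
| nonsense spacer length / threshold | 39 / 20 | nt / mismatches | control spacers must not match the target anywhere |
| `overlap` (flank primers) | 12 | nt | primer–primer overlap centred on the repeat midpoint |
| MOE primer total | 50 | nt | anchor-arm + repeat portion; with a 24-nt repeat the arm is 26 nt |
| qPCR `efficiency` | 1.0 | fraction | base 2 (classic 2^−ΔΔCt); supply the fitted value for correction |

The handle itself is always configuration input, never hard-coded: repeats
differ between loci and organisms, and the package derives the handle as
the transcribed final 8 nt of whatever repeat the user supplies
(`handle_from_repeat`). Examples in this package use `AUUGAAAG`, a
*Sulfolobus*-style handle.

## Ranking and tie-breaks

The experimental record gives no usable ranking signal beyond pairing
itself (constructs with thermodynamically favourable crRNA–target
interaction energies still silenced poorly in some positions), so the
scanner orders candidates deterministically by paired count (descending),
then Watson-Crick-only count (descending), then start position
(ascending). Interaction-energy scoring is exposed only as a pluggable
`energy_scorer` hook plus an optional threshold — the packaged model makes
no efficacy prediction.

`select_multiplex()` picks greedily in rank order subject to the
separation constraint and reports the true maximum feasible number of
picks (computed by interval scheduling over the candidate starts) when a
request is infeasible.

## Genome survey semantics

`survey_cds()` counts minimal-motif trinucleotides on the sense mRNA of
each CDS only — the PAS is a property of the targeted transcript.
Occurrences may overlap (every position is tested independently), and by
default only positions with at least `protospacer_length + 2` nt upstream
count, so that a full protospacer fits 5′ of the motif; the
`require_upstream_room = FALSE` setting preserves the literal trinucleotide
count. The motif set is enumerated exactly from the handle
(`minimal_motif_patterns`), and an exhaustive 64-trinucleotide equivalence
against `match_pas` is part of the test suite.

## OE-PCR simulation model

The construction route is simulated, not thermodynamically modelled:
annealing is exact string matching of a primer's 3′-terminal region
(default 12 nt), which keeps every step deterministic and makes failures
attributable to a specific join. The route is: flank units
(spacer–repeat–spacer products whose primers overlap on the repeat) →
fusion wherever one unit's terminal spacer equals another's initial spacer
→ amplification by the M primers, which bind the spacer arms of the
50-nt MOE primers so that only a correctly fused, arm-flanked fragment
amplifies → megaprimer insertion, replacing the span between the two arm
sites on a circular template. Duplicated inner spacers make fusion
ambiguous (two joins share a spacer), which is exactly why repeated-spacer
dosage constructs use the alternative inverse-PCR route: linearise through
the middle of the single spacer copy, then prime with an
(half-spacer + repeat + full spacer) overlap primer — 80 nt for the default
37-nt spacer / 24-nt repeat geometry. (The descriptive phrase
"one-and-a-half spacers" for that primer is reconciled here as
half + repeat + full, which matches both its length and its function of
regenerating the junction.) Template elimination by DpnI and ligation are
recorded as provenance notes only; they have no computational content.

Two structural choices in array assembly are inferences the simulation
makes explicit: the array closes with a terminal repeat (n spacers, n+1
repeats — the canonical CRISPR array structure), and the final retained
backbone spacer(s) downstream of the insertion point are kept. The locus
transcript starts at the first repeat (the leader is treated as promoter
only; the exact transcription start is not modelled) and crRNA 3′ ends are
left untrimmed, since 3′ maturation detail does not affect targeting by
the 5′-anchored handle-spacer model used here.

## The synthetic-data generator

`synth_target_transcript()` plants `k` fully Watson-Crick-paired
protospacer windows (one per equal-width block of the transcript, uniformly
placed) in a random background, then scrubs the background of accidental
windows that would pass the full criterion by mutating one paired PAS base
per offending window — never touching the planted PAS bases — until a scan
returns exactly the planted truth. `synth_cds_set()` does the analogue for
the minimal motif: backgrounds are scrubbed against the wobble-inclusive
pattern set and planted sites use Watson-Crick-only patterns with full
upstream room, so per-CDS counts hold under *either* wobble setting and
*either* upstream-room setting. CDS are laid on alternating strands with
random intergenic spacers, which exercises the reverse-complement path of
CDS extraction.

Defaults mirror the study conditions the package is built around: 37-nt
protospacers, a 2709-nt target transcript (a realistic single-gene mRNA,
the size of the α-amylase gene used as the motivating target), 39-nt /
>20-mismatch nonsense controls, a backbone of six 37-nt spacers behind a
497-nt leader with ~24-nt repeats, and a 40 % GC background typical of
*Sulfolobus* coding sequence.

One degenerate case is rejected up front: a handle that pairs its own
Watson-Crick complement at ≥ `min_paired` positions under a 1–7-nt frame
shift. For such handles every planted site forces frame-shifted neighbour
windows to pass using protected planted bases alone, so no background
scrub can produce an exact truth table; `synth_target_transcript()` raises
a classed error naming the shift overlap instead of looping.

What the fixtures do *not* emulate: codon structure, operon organisation,
RNA secondary structure and real intergenic composition. Passing tests on
fixtures therefore demonstrate the correctness of the scanning, counting,
assembly and simulation logic — not silencing efficacy on real transcripts,
which depends on structure and accessibility effects outside this
package's scope.

## Numerical choices

* ΔΔCt: replicate Cts are averaged arithmetically per sample/primer pair;
  replicate spread is propagated in Ct space assuming independence and
  reported on the percentage scale. Efficiency enters as the base
  `1 + E`; both the classic base-2 and the efficiency-corrected form are
  one call apart.
* Standard curves are ordinary least squares; a series narrower than
  2 log10 units warns, a zero-span series errors, and a non-negative slope
  errors (Ct must fall with template).
* Off-target search is ungapped Hamming distance at every offset —
  matching the mismatch-count criterion used for control spacers — and is
  exhaustively cross-checked against a brute-force oracle in the tests. No
  seed-and-extend heuristics: transcripts are small enough for exact
  search.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state.

## Problem sizes used in the packaged checks

The test suite and acceptance script run entirely on generated data:
transcripts of 0.3–2.7 knt, genomes of ~10 CDS (0.4–1.2 knt each), 50
random backbone/spacer sets for the OE-PCR round trip, and exhaustive
enumerations where the space is small (64 trinucleotides, all offsets, all
window positions). These sizes were chosen so every property is checked
against a brute-force oracle at full depth while the whole suite stays
interactive.

## Known limitations

* No thermodynamics anywhere: primer annealing is exact string matching,
  and crRNA–target energy is a user-supplied hook.
* No gapped alignment in off-target search.
* GenBank support is a minimal CDS-features-plus-sequence reader/writer,
  not a general parser.
* The survey counts motif availability, not predicted silencing strength;
  position effects on efficacy are explicitly out of scope.
* Multi-segment CDS are joined with a warning; archaeal annotations rarely
  need this and splice-level detail is untested territory.
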