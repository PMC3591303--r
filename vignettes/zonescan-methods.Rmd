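---
title: "zonescan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zonescan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `zonescan`, the parameters that
matter, the numerical and design choices that were genuinely open, and
what the synthetic-data tests do and do not demonstrate.

## The search model

`zonescan` is a seed-and-extend local similarity search for proteins.
Its premise is that in bulk annotation work most useful hits are strong
enough to leave several high-scoring word matches concentrated in a
narrow diagonal band of the query x subject matrix. The pipeline
therefore spends almost all of its time in two cheap stages — word
lookup and diagonal aggregation — and defers alignment and statistics to
the few surviving candidate regions.

### Diversified word index

A k-tuple is addressed by its base-20 positional code, so lookup is a
single array access. For every k-tuple `t` occurring in a query we
enumerate the neighbourhood

$$N(t) = \{\, t' : \mathrm{score}(t', t) \ge S,\; S = \alpha \cdot \mathrm{score}(t, t) \,\}$$

where `score` sums substitution-matrix weights position by position and
`alpha` (`approx`, in (0,1]) is the diversification level. Enumeration
walks the 20-way, k-level trie depth-first and prunes a branch as soon
as the prefix score plus the self-match score of the remaining suffix of
`t` falls below `S`; this bound is valid because every loaded matrix is
validated to have row-maximal self scores. `S` is real-valued; integer
match scores are compared against it directly (no rounding), and ties at
the threshold are included. The denominator of the ratio is the
*occurring query tuple's* self score — the tuple being diversified —
which is what makes the pruning bound exact.

The table is built in two passes so that all locations live in one
pre-sized arena: pass one counts exact occurrences and propagates counts
to all neighbours, the arena is then partitioned exactly, and pass two
re-runs the diversification to copy locations (with the suffix match
scores of key-vs-query tuple) into their regions. Re-running is cheaper
than caching the neighbourhoods of every occurring tuple. Each region
ends exactly full, and entry order within a region is unspecified — the
scan verifiably does not depend on it.

k-tuples containing residues outside the 20-letter alphabet (B, Z, X,
U, `*`) are skipped entirely: they contribute no index entries and are
never looked up. The alternative — inventing scores for ambiguity
codes — would put unvalidated weights into the seeding stage.

### Similarity zones

Each diagonal (constant `query_position - subject_position`, indexed
over the concatenation of all queries) carries running state: offset and
score of the last match, and a reference to the diagonal's current
similarity zone. The state is reused across subjects without clearing:
an entry is trusted only if its stored subject index matches the current
subject (lazy invalidation). On a hit, one of four situations applies:
unused, stale subject, different query, or an active zone of the same
query/subject pair. The first three start a fresh zone seeded with the
full word match score. In the fourth, the zone extends: a new match
overlapping the previous one by `o` residues contributes the
precomputed suffix score of its last `k - o` positions (no matrix
access in the inner loop), and a separation of `d` residues beyond the
word length costs the affine penalty `gip + gep * d`. If the extended
running score would drop to zero or below, the old zone stays active and
a fresh zone takes over the diagonal.

After every update the `mxshift` adjacent diagonals on each side are
searched for zones worth merging; the merge estimate adds both scores,
prorates the smaller zone by its non-overlapping subject fraction, and
subtracts the affine penalty on the diagonal distance. Zones whose
updated score crosses `kthresh` are recorded once in a hits array
(guarded by a sentinel hit index) and remain recorded even if later
updates never raise the score again.

Zone and hit arenas are pre-sized (2,000,000 zones, 65,536 hits, both
configurable); exhaustion degrades gracefully with a warning rather
than aborting, matching the streaming design.

### Zone clustering

After a subject is consumed, surviving hit zones of the same query are
clustered by single linkage and components are merged into their
first zone. The link condition was a genuinely open design point. The
natural rule — adjusted score sum exceeds the gap penalty on the
diagonal distance — turns out to also merge *alternative* placements of
one query region (tandem-repeat copies), which destroys exactly the
multiple similarities the long-repeat filter downstream exists to
arbitrate. `zonescan` therefore links two zones only when the merged
zone promises a better single alignment than either part alone:

$$\max(s_i, s_j) + \min(s_i, s_j)\,(1 - f) - \mathrm{gap}(d) > \max(s_i, s_j)$$

where `d` is the minimal diagonal distance and `f` is the weaker zone's
largest overlap fraction across the query and subject projections. For
collinear segments (no overlap in either projection) this reduces to
the natural rule with a "merging must gain" margin; for repeat copies
(full query overlap, disjoint subject intervals) the left side can
never exceed the right and the copies stay separate. The overlap
proration is linear; no principled non-linear form suggested itself and
the choice only gates which zones share an alignment band.

The merged score accumulates members in subject order, prorating each
for subject overlap with the region already covered and charging the
gap penalty to the nearest predecessor, floored at the best member
score. This is an estimate only — accurate scores come from the
alignment stage.

### Banded alignment

Each merged zone, widened by `band_extension` residues along the
diagonal and half that across it (clipped to the sequences), is aligned
by a three-state (match / query-gap / subject-gap) affine-gap dynamic
program restricted to the band, computing local Smith-Waterman scores
with full traceback. A gap of length L costs `gip + gep * L`, the first
gapped residue paying both. Memory is proportional to band area. An
alternative reading of the design — a global band-restricted
Needleman-Wunsch followed by extraction of the best-scoring local
sub-path — was considered and rejected in favour of direct banded local
DP: it is simpler, and when the optimum lies inside the band the two
coincide. The suite verifies that with a full-rectangle band the banded
score equals an independent unrestricted Smith-Waterman implementation
(Biostrings) on random and homologous pairs, and that banded scores are
monotone in band width and never exceed the full optimum.

Determinism: traceback ties prefer match/mismatch over query-consuming
gaps over subject-consuming gaps, and among equal-scoring end cells the
smallest subject, then query, coordinate wins. Identical inputs produce
byte-identical output.

### Filters, chaining, statistics

Filters never modify member alignments; they group, drop or chain.

* **Score filter** keeps alignments with `sw_score >= min_score`,
  applied after accurate scores exist.
* **Long-repeat filter** groups alignments of one pair whose query
  intervals overlap by at least 50% of the shorter interval while the
  subject intervals are disjoint (or the symmetric case) and keeps the
  best of each group. The 50% threshold is a package choice; the
  intent is "same region matched repeatedly elsewhere", and moderate
  changes to the fraction move no test.
* **Remote-segment merger** (off by default) chains collinear segments
  by DP over segments sorted by query start, bridging with
  `gap(max(q_gap, s_gap))`; a link is taken only when the chain beats
  leaving the segments separate. It matters precisely when zone scores
  under-estimate alignment scores (diverged homologs), since any pair
  the clustering already rejected on *zone* scores cannot profitably
  chain on those same scores.

E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)` with
`m` the query length and `n` the total residues scanned (whole-database
convention, no edge-effect correction). Gapped `(lambda, K)` pairs for
BLOSUM62 at the standard gap settings ship as a plain-text table; the
default 11/1 pair is (0.267, 0.041). For unlisted combinations the
package falls back to the ungapped lambda (unique positive root of
`sum p_i p_j exp(lambda s_ij) = 1`, found by bisection to residual
< 1e-9, uniform background by default for dataset independence) with a
rough K of 0.1 and a warning — E-values from that path are indicative
only. Consequently `zonescan` E-values are not numerically
interchangeable with SSEARCH or BLAST E-values; rankings for strong
hits are unaffected.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `ksize` (k) | 5 | residues | 3..6; index memory grows as 20^k (~13 MB of counters at 5, ~770 MB peak at 6) |
| `approx` | 0.85 | fraction of self score | dominant speed/sensitivity dial; useful range ~0.72-1.0 |
| `kthresh` | 18 | score units | zone detection threshold; higher = stricter and faster |
| `mxshift` | 3 | diagonals | lateral merge reach; gains saturate around 3-4 |
| `gip`, `gep` | 11, 1 | score units | standard BLOSUM62 affine pairing |
| `band_extension` | 16 | residues | margin around zones before alignment |
| `max_subject_len` | 50,000 | residues | sizes the pre-allocated diagonal array |
| `rpq` | 100 | hits | per-query report cap |
| `evalue_cutoff` | 10 | — | report threshold |

Defaults follow the standard pairing of BLOSUM62 with 11/1 gaps and a
word size of 5; `kthresh = 18` sits at the strict end of the useful
range, where zone detection is selective but a single strong 5-tuple
match can still trigger alignment.

## Synthetic data and what the tests show

`random_proteome()` draws i.i.d. residues (uniform by default, Robinson
background available), `mutate_homolog()` plants substitutions and
geometric-length indels with a ground-truth path, and
`make_repeat_protein()` / `make_fusion_protein()` build constructs with
known coordinates for the repeat filter and the merger. All generators
are pure functions of their seeds.

The headline check plants a homolog of a 300-residue query (20%
substitutions, two indels) among 50 random decoys and requires the
planted pair to rank first in at least 90 of 100 trials at default
parameters; in practice it ranks first in all of them, since a 20%
divergent homolog retains many exact 5-tuples while 300-residue random
decoys essentially never cross `kthresh = 18`.

What this does not show: real proteins are not i.i.d. strings. Natural
low-complexity regions, biased composition and genuine domain
repetition make real decoys harder than synthetic ones, and the
pipeline has no compositional score adjustment. The synthetic results
bound algorithmic correctness (oracle equivalences, determinism, score
identities), not field sensitivity on natural databases.

Problem sizes in the suite were chosen to keep the independent oracles
exact and affordable: diversification is checked against exhaustive
scoring of all 3,200,000 5-tuple codes for 50 tuples at four
thresholds; the full lookup table is checked against a brute-force
index at k = 3 (8,000 codes) over twenty 300-residue queries, where
exhaustive construction is tractable; the aligner against full
Smith-Waterman on pairs up to 200 residues.

## Known limitations

* E-values do not numerically match SSEARCH/BLAST (see above).
* Weighted k-tuple frequency scoring (down-weighting ubiquitous words)
  is not implemented.
* Gapped word matches are not supported in the index, by design.
* The scan is single-threaded; subjects longer than `max_subject_len`
  are rejected rather than split.
* Karlin-Altschul K for arbitrary matrices/backgrounds is not computed
  from first principles; only lambda is solved exactly.
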