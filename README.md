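# zonescan

Fast BLAST-like protein similarity search for R, built for bulk
annotation tasks (proteome-vs-database scans, metagenome ORF screening)
where most of what you want to find are relatively strong homologies and
raw throughput matters more than exhaustive sensitivity. `zonescan`
trades a controlled amount of sensitivity for speed and exposes the
dials that govern the trade.

## The algorithm

The engine is a seed-and-extend pipeline of hit accumulators and filters
ordered by increasing computational cost:

1. **Diversified k-tuple index.** The query set is indexed once in a
   direct-addressed lookup table over all 20^k tuple codes (default
   k = 5). Each k-tuple occurring in a query is *diversified*: a 20-way,
   k-level trie is searched depth-first for every tuple `t'` with

       score(t', t) >= approx * score(t, t)

   under the substitution matrix (BLOSUM62 by default), pruning any
   branch whose prefix score plus the best possible self-matching
   remainder already falls below the threshold. Locations are stored
   with precomputed suffix match scores, so the inner loop never touches
   the matrix. The table is built in two passes (count, then fill) into
   a single pre-sized entry arena.

2. **Diagonal similarity zones.** Subjects stream one record at a time.
   Every subject k-tuple is looked up; each hit updates per-diagonal
   running state (invalidated lazily across subjects) and either extends
   the diagonal's similarity zone — overlapping seeds contribute suffix
   scores, separations pay an affine gap penalty `gip + gep * L` — or
   starts a fresh zone. Nearby zones within `mxshift` adjacent diagonals
   merge on the fly; zones whose running score crosses `kthresh` enter
   the hits array. After the subject is consumed, surviving zones are
   clustered by single linkage and merged when a combined zone promises
   a better single alignment than either part.

3. **Banded alignment and statistics.** Each merged zone, extended by a
   band margin, is aligned with a banded three-state affine-gap
   Smith-Waterman DP whose time and memory scale with band area, not
   with the full m*n rectangle. Alignments pass a score filter, an
   optional long-repeat filter and an optional remote-segment merger,
   then receive Karlin-Altschul statistics

       E = K * m * n * exp(-lambda * S)

   with published gapped (lambda, K) pairs for the standard BLOSUM62
   gap settings, and are ranked per query (at most `rpq` reported) in
   BLAST-like formats: NCBI m8/m9 tabular, TAB/TABX, or rendered TEXT.

## Worked example

Hide a mutated homolog (20% substitutions, two indels) of a 300-residue
synthetic query among five random decoys and search with defaults:

```r
library(zonescan)

query   <- random_proteome(1, 300, seed = 7)
homolog <- mutate_homolog(query$seq, substitution_rate = 0.2,
                          n_indels = 2, seed = 8)
subjects <- rbind(
  data.frame(id = "homolog", desc = "planted relative", seq = homolog$seq),
  random_proteome(5, 300, seed = 9))

write_fasta(query, "query.fa")
write_fasta(subjects, "db.fa")

cfg <- parse_config(c("--query", "query.fa", "--subject", "db.fa",
                      "--omode", "NCBI_M8"))
run_search(cfg)
```

which logs the stage counters and prints one m8 hit line:

```
zonescan: indexed 1 queries, 3717 lookup entries (296 exact)
zonescan: 1 zones detected, 1 after merging; 1 alignments computed
zonescan: 1 hits reported
SYN0001	homolog	79.14	302	60	2	1	300	1	301	4.42e-146	501.9
```

Only the planted relative survives: it aligns over 302 columns at 79.1%
identity with 60 mismatches and 2 gap openings, covering query residues
1-300 and subject residues 1-301, with E-value 4.4e-146 and bit score
501.9. The five decoys produce no zone that crosses the detection
threshold.

The same search runs from a shell through the bundled CLI:

```sh
inst/cli/zonescan --query query.fa --subject db.fa --omode NCBI_M8
inst/cli/zonescan -h     # full parameter list with defaults
```

Key parameters (see `?search_params`): `--ksize` (word size, 3-6),
`--approx` (diversification level in (0,1]; lower = more sensitive and
slower), `--kthresh` (zone detection threshold), `--mxshift` (lateral
merge reach in diagonals), `--gip`/`--gep` (affine gap penalties),
`--rpq` (results per query), `--omode` (output format).

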