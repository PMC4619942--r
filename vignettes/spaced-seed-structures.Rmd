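---
title: "Spaced-seed data structures for de Bruijn graph assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spaced-seed data structures for de Bruijn graph assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacedseeds)
```

## The construct

A *spaced seed* here is a pair of k-mers `[k:k]` separated by a fixed gap of
`delta` bases. The template spans `2k + delta` bases of sequence but only the
`2k` seed bases are ever stored: the gap contributes specificity (the seed
"sees" a wide genomic context) at zero memory cost, and any sequencing error
that falls into the gap is invisible to the structure. Compared with a single
k-mer of length `2k`, the spaced seed reaches the uniqueness of much longer
k-mers — `uniqueness_curve()` quantifies this as the fraction of genomic
positions whose canonical seed occurs exactly once genome-wide — while its
hash-table record stays a constant `4k` bits of sequence content regardless
of `delta`. Against storing the full `2k + delta` bases, the spaced layout
(content `4k` bits plus a doubled, 16-bit extension field) wins strictly for
`delta > 8` and ties at `delta = 8`.

Sequences are 2-bit coded (`A=00, C=01, G=10, T=11`), chosen so that
complementation is a bitwise NOT. That makes the *XOR fold* — the packing of
a sequence XORed with the packing of its reverse complement — a
strand-invariant function, and every structure built on folded hashes is
automatically strand-canonical without ever computing a canonical form.

## The four-hash quadruple

For a concatenated seed `S` of length `2k`, four hash values are computed
over folds of four subsequences: the left k-mer (`xL`), the right k-mer
(`xR`), the odd positions (`xO`) and the even positions (`xE`). Under
reverse complementation the (L,R) pair and the (O,E) pair swap, so inserting
a seed and querying its reverse complement touch the same four bits of the
Bloom filter. The four values serve directly as the filter's `h = 4` hash
functions; with `hn/m = ln 2` (the optimal load from `h* = (m/n) ln 2`) the
false positive rate `f = (1 - e^{-hn/m})^h` is `0.5^4 = 6.25%`, and sizing
the human genome (`n = 3e9`) at that operating point costs about 2 GiB.

The hash function itself (`base_hash()`) is a salted FNV-1a byte
accumulation with a multiply–XOR avalanche finalizer: deterministic,
platform-independent, and empirically flipping 32 ± 4 of 64 output bits per
input-bit flip. Determinism across platforms mattered more than speed here,
which is why no SIMD or rolling-hash scheme is used.

### The fold halves the input entropy — choose k accordingly

The fold is symmetric: position `i` of `fold(x)` equals
`x_i XOR x_{n-1-i} XOR 11b`, which is the same value found at position
`n-1-i`. A k-base fold therefore takes only `4^ceiling(k/2)` distinct values
(for odd `k` the middle symbol is constant). This is a property of the
construction, not of the implementation: any strand-invariant input function
must identify `x` with its reverse complement, but the XOR fold collapses
far more than that single pair. The practical rule adopted throughout this
package is

> `4^ceiling(k/2)` must greatly exceed the number of distinct seeds,

otherwise single-hash collisions — which no increase of the filter size `m`
can dilute — dominate membership queries. At `k = 15` a 5 kb genome already
occupies a quarter of the 16,384-value fold space; at `k = 25` the space is
`4^13 ≈ 6.7e7` and collisions are negligible at desk scale. The package's
worked examples and tests use `k = 25` for whole-pipeline runs for exactly
this reason, and odd `k` is recommended throughout so that no k-mer is its
own reverse complement (an RC-palindrome folds to all-zero bits).

A related geometric fact drives filter sizing for assembly: a 1-base
extension probe shares its left k-mer and its odd positions with a true
seed, so only `xR` and `xE` discriminate it, and the false-extension rate
per probe scales as the *square* of the per-bit load rather than its fourth
power. `build_graph()` therefore sizes its filter from the distinct canonical
seed count at a four-hash target FPR of `1e-14` (per-bit load about `3e-4`)
by default — a few megabytes at toy scale — rather than the textbook
`ln 2` load.

## Counting: the cascade and the 1.4.3.-2 minifloat

Counting is staged. Stage 1 is the plain seed filter; it records first
observations. When an insert finds all four bits already set, the seed has
been seen at least twice and *cascades* to stage 2: a byte array of `m2`
counters addressed by a strand-*sensitive* hash pair — `x` for the seed as
presented, `x'` for its reverse complement. The pair must be
strand-sensitive (unlike the folded quadruple) because the update rules
carry strand information; this is the one place the package had to choose a
mechanism the design text leaves open.

Each byte is a 1.4.3.-2 minifloat: 1 sign bit, 4 exponent bits, 3 mantissa
bits, exponent bias −2. Subnormals decode to the mantissa itself, normalized
values to `(1 + t/8) · 2^(e+2)`; every count through 16 is exactly
representable, 17 is not, and the maximum finite value is 122,880 (the top
exponent is reserved and never produced — counters saturate). The sign bit
flags observation on both strands, and the pattern negative zero is reserved
as the hash-collision flag. The full update mapping on state classes
(zero, −0, nonzero) is total over all 9 cases; two readings the summary
table leaves open are resolved as: (−0, −0) collides (negative zero counts
as "nonzero" in the collision rule, guarding against secondary collisions),
and the degenerate case `x == x'` (an RC-palindromic seed, or a modulus
accident) is treated as a single coordinate that is set/incremented with the
sign never raised.

Beyond the exact range, "increment" is a Morris-style probabilistic step:
advance to the next representable value with probability `1/gap`. The
expected advance is exactly 1 in every state, so the decoded value is an
unbiased estimator of the true count; `mf_count_stream()` implements the
equivalent geometric skip-ahead so that concordance experiments with 10,000
replicates per logarithmic bin up to `10^4` run in milliseconds. Relative
error of the *mean* stays within 5% there; individual counters are noisier
(the mantissa step near `10^4` is 1,024).

## Error correction from hit patterns

A single base error in a queried seed is confined to one half (left/right)
and one parity (odd/even), so exactly two of the four hash values still hit,
in one of the four patterns `{L|R} × {O|E}`. The candidate positions are the
intersection of the missed half and missed parity — about `k/2` positions,
always inside the stored seed bases, never the gap. A substitution is
committed only when exactly one candidate restores the full `(1,1,1,1)`
pattern (and has a nonzero count, when a counter is supplied): ambiguity is
resolved in favour of precision over recall. Patterns with a single hit may
indicate two errors; the summary rules give them no action, so they are
inserted as novel sequence (a bounded two-substitution search was considered
and rejected as default behaviour — its candidate space grows quadratically
and its false-fix rate with it). The two-hit patterns `L+R` and `O+E`
localise nothing and are likewise treated as absent. Quality gating is
optional and applies only when qualities are provided: corrections commit
only at bases below Q20 by default.

## The toy assembler

`assemble_reads()` exists to demonstrate the data structures, not to compete
with production assemblers. While the filter is populated, auxiliary seeds
are captured: the first and last window of each read as *blunt* candidates
(initially two per read), and junction windows — detected when a read
crosses between already-observed and new territory and the boundary window
shows two or more observed extensions — as *branch* representatives; the
second sequence across a junction is necessarily caught. A periodic garbage
collection re-interrogates the blunt list and removes entries that have
since gained extensions; on a fully tiled linear target exactly the two true
ends survive.

Contig extension keeps the full span-length window as its state (the
starting window's gap bases come from the read of origin, which resolves the
transient start-up phase). Each step probes the four 1-base extensions for
full spaced-seed membership: the leading k-mer advances while the lagging
k-mer — drawn from sequence assembled `k + delta` bases earlier — must agree
simultaneously. That lagging-edge assertion is what lets a spaced seed walk
straight through an exact repeat of length up to `2k + delta - 2` that
fragments a contiguous 2k-mer graph. Extension stops at a blunt end (no
candidate), a branch (two or more candidates; the contig is terminated
rather than forked — the simplest faithful policy), or when a window
repeats (circular). Traversal order over the auxiliary list is sorted, so
assemblies are reproducible. Dead-end contigs that started from a branch
seed and extended fewer than `2k - 1` bases are trimmed: a false branch
survives `l` probes with probability `f^l`, so at `f = 6.25%` a length-10
false branch stays below 0.3% even after a `3e9`-fold Bonferroni correction.

The structure also answers queries at the small scale `k` (a lone k-mer's
folded hash against the same bit array, one hash value, elevated FPR). The
assembler uses it only behind the opt-in `two_scale` flag, as a fallback
when the full-scale probe finds nothing — which is precisely what happens at
a window-scale coverage dip, where every k-mer is observed but no full
`2k + delta` window is. With 150 bp reads at 30× over 5 kb, such dips occur
in roughly one genome in twenty, so the end-to-end examples enable the flag.

## The simulator, and what passing tests do not show

`sim_genome()` draws i.i.d. uniform bases (GC 0.5) and plants repeat
families (copies of one unit, non-overlapping, independently mutated at a
per-base divergence rate); `sim_reads()` draws uniform start positions,
random strands, and i.i.d. substitutions, with a constant quality string at
the Phred encoding of the error rate; `sim_counts()` fixes the replication
layout for counter-concordance runs (10,000 replicates per logarithmic bin
by default). Everything is deterministic under `set.seed()`.

This substrate deliberately omits much of real data: no indels (the
correction logic is substitution-based), no quality trajectories, no
platform error profiles, no coverage biases, no haplotypes. Passing tests
therefore demonstrate the data structures' contracts — strand symmetry,
exactness of counts in the unit-gap range, unbiasedness beyond it, repeat
resolution within the span — on clean substitution-only data, and nothing
about performance on real libraries.

## Problem sizes and numerical choices

The shipped tests and examples run at: 5 kb genomes, 150 bp reads, 30×
coverage, `k = 25`, `delta = 50` (span 100) for assembly and correction;
10,000 random seeds for empirical FPR checks at `k = 31`; 10,000 replicates
per bin up to `10^4` for counter concordance. These sizes were chosen so the
fold-entropy rule above holds with two orders of magnitude to spare and the
whole suite completes in about a minute. Other fixed choices: position =
hash mod `m` with no primality requirement (hash quality suffices); stage-2
default `m2 = m/8` bytes (the same memory as stage 1); strand counters in
the hash-table record saturate at `2^15 - 1` (15 usable bits); ties in
`bloom_size_for()` resolve to the smallest `m` meeting the target.

## Known limitations

The fold-entropy constraint on `k` is the important one and is inherent to
the XOR fold. Cascade counts are silently corrupted (not flagged) when a
*single* coordinate of an unrelated pair lands on a counting byte — only
double-coordinate clashes are detected, which is what the negative-zero flag
is for. The assembler is single-threaded, terminates at unresolved branches
instead of emitting a graph, and its two-scale fallback inherits the
single-hash FPR. Serialized filters are byte-order-fixed (little-endian
headers) but not versioned beyond a single format number.
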