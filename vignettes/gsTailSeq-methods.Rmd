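---
title: "gsTailSeq methods: tail calling, uridylation statistics and decay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gsTailSeq methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsTailSeq)
```

## The measurement model

Gene-specific TAIL-Seq targets a single transcript's 3′ end. After ligation
of a known linker (linker-1, `CTGTAGGCACCATCAAT`) to RNA 3′ termini and
amplification with a gene-specific forward primer, each informative read has
the layout

```
[3'-UTR anchor] [poly(A) tail A^L] [non-templated additions] [linker-1] ...
```

in cDNA space (uridine reads as T). Two landmark sequences therefore define
the tail without any genome alignment: the **anchor** — the sense-strand
3′-UTR terminal sequence that doubles as the gene-assignment criterion
(`TTTAAATGAAAAAGGTTGACAAAATAAA` for *Zc3h12a*,
`TGTTTAGACTGTCTTCAAACAAATAAA` for *Il6*) — and the **linker**, which marks
the RNA 3′ terminus. Everything strictly between anchor end and linker start
is the tail; its maximal 3′-terminal run of non-A bases is the block of
non-templated additions, and the remaining 5′ part is the poly(A) tract.

Addition classes follow the field's definitions: `mono_U` (exactly one U),
`oligo_U` (two or more U, the degradation-committed mark), `C_add`/`G_add`
(homopolymeric cytosine/guanine extensions), `none` (bare poly(A)), and
`mixed` for heterogeneous blocks (e.g. `UC`). Because additions are defined
as the maximal non-A suffix, a block can never contain A: terminal adenosines
are poly(A) by definition. This mirrors the class system used when such data
are reported, and is a documented limitation — genuine A-containing mixed
tails are not representable.

## Caller: algorithm and parameters

For each read the caller

1. **orients** the read: every configured anchor is scanned over both the
   read and its reverse complement (Hamming distance, N counts as mismatch);
   the strand with the fewer best mismatches wins, ties go to sense, and a
   read with no anchor within tolerance on either strand is `no_anchor`;
2. **assigns the gene** by fewest anchor mismatches; an exact tie between two
   genes is `ambiguous`;
3. **locates the anchor** at its leftmost within-tolerance occurrence
   (0-based, half-open coordinates throughout) and then **the linker** at the
   leftmost position at or after the anchor end — either the full linker or,
   when the read ends inside the linker, a prefix of at least
   `minLinkerPrefix` nt. No linker means `no_linker`;
4. **segments the tail** and classifies the addition block. In strict mode
   (default) the pre-addition segment must be pure A; an interrupted tract is
   `ambiguous`. Tolerant mode permits one non-A interruption per 20 nt,
   counted toward the poly(A) length, for data with appreciable error rates.

Defaults: `maxAnchorMismatch = 2` (over 27–28 nt anchors),
`maxLinkerMismatch = 1` (17 nt linker), `minLinkerPrefix = 10` nt. These
tolerate typical Illumina substitution error while keeping random matches
vanishingly rare (a 10 nt linker prefix with ≤ 1 mismatch has chance
≈ 3 × 10⁻⁵ per position under a uniform base model). All are configurable
in `TailCallerParam()`.

**Denominator decision.** Uridylation frequency is reported as the
percentage of *called* reads — anchor and linker both found and the tail
unambiguous. Reads failing either landmark have no defined tail, so
including them in a denominator would dilute frequencies with
non-measurements; whether the original analysis included linker-less reads
is not documented, so this package makes the choice explicit and counts the
excluded reads in per-status counters where attrition is auditable.

The Hamming-neighbourhood scan is implemented as a vectorised byte
comparison (`mismatchProfile()`), since anchor filtering replaces the usual
alignment stage and is on the hot path; the test suite checks it against a
naive O(n·m) double-loop oracle and against `Biostrings::matchPattern` over
thousands of randomized cases.

## Simulator: what it emulates, and what not

`simulateTailReads()` emits exactly the composition's reads — class
assignment is an exact partition, not multinomial sampling — so the
aggregate composition of a read set is deterministic and the caller can be
audited read by read (names encode the true class, length and block;
generator and caller share only the read bytes). Per-read draws (tail
lengths, oligo-U block length of 2–5 U, C/G block length of 1–2 nt, filler
bases, strand choice, substitution errors) flow from a single seeded RNG
stream, so identical inputs give byte-identical FASTQ.

The built-in fixtures transcribe the published per-condition compositions:
read totals, integer-rounded mono-/oligo-U percentages and C/G addition
counts, with class `none` absorbing the remainder
(`count = floor(pct/100 × total + 0.5)`; half-up rounding keeps exact .5
products stable). Quantities the publication does not print are synthetic
stand-ins, chosen once: the unstimulated *Zc3h12a* conditions use an 8%
mono-U / 10% oligo-U baseline (below the stimulated values, as LPS increases
uridylation), and the *Il6* fixtures carry no C/G additions. They are
labelled as stand-ins here and carry no acceptance weight.

Poly(A) length models default to discrete uniform: 5–60 nt for uridylated
classes and 10–120 nt otherwise, reflecting the shorter tails of uridylated
ends; the true underlying distributions are not published, so these are
parametric stand-ins, overridable per class via `polyARanges`. Because the
composition table cannot express `P(class | length)`,
`simulateCallProfiles()` generates call tables directly from a
length-dependent class probability for correlation-analysis scenarios.

Reads are single-end, 200 nt by default. The real protocol is 2 × 150 nt
paired-end with the tail information split across mates; one longer
synthetic read carries the same information (anchor 28 + poly(A) ≤ 120 +
additions ≤ 5 + linker 17 = 170 nt fits), and the mate-2 orientation is
represented by `antisenseFraction`. Qualities are constant Phred+33 'I' and
ignored by the caller. Not emulated: rRNA depletion, RNase T1
fragmentation, PCR duplication, PhiX spike-ins, quality-dependent errors,
indels. Consequently, a green test suite demonstrates correctness of the
computational pipeline under substitution error and strand mixture — not
robustness to every artefact of real libraries.

## Statistics

`summarizeUridylation()` counts classes over called reads;
`any_U = mono_U + oligo_U` counts pure-U tails only (whether mixed tails were
counted as uridylated in the original analysis is unstated; a
`countMixedAsU` flag includes U-containing mixed blocks). Frequencies are
kept at full precision and rounded half-up to integers only for comparison
with printed values. Zero called reads yield a flagged, `NA`-frequency
summary rather than a division error.

`binByPolyA()` bins called reads into half-open `[lo, hi)` poly(A)-length
bins — default width 10 nt with a final open-ended bin from 75 nt, a
conventional granularity for tail-length displays — and correlates per-bin
mono-U and oligo-U frequencies against bin midpoints (the open bin's
midpoint is `maxEdge + binWidth/2` by convention). Bins with fewer than
`minReads = 10` reads are excluded; fewer than 3 qualifying bins, or zero
frequency variance, flags the correlation undefined. The per-bin frequency
correlation matches how such figures present the relationship; a per-read
point-biserial alternative (`perRead = TRUE`) is provided since the original
computation mode is not documented. Pearson r/p use `stats::cor.test`
(t transform, n − 2 df); group comparisons use `stats::t.test` with pooled
variance by default — "Student's t test" taken at its word — with Welch's
variant behind a flag.

## Decay kinetics

`ddCtFoldChange()` implements ΔΔCt with amplification efficiency fixed at
2.0 (no standard-curve efficiencies are available; this is a modelling
assumption): `fold = 2^−(ΔCt_sample − ΔCt_baseline)`, the reference
transcript cancelling plate effects. Ct values outside 5–40 cycles warn.

`fitHalfLife()` fits `log A(t) = −k t + c` by least squares over all time
points including t = 0 and reports `t½ = ln 2 / k` with the log-linear fit's
r². Log-linear fitting is exact on noiseless exponentials and standard for
actinomycin-D chases; a nonlinear refinement on the natural scale
(`method = "nls"`) is available where late, near-zero points would otherwise
dominate on the log scale. The intercept absorbs abundance scaling, making
k scale-invariant. Fitted `k ≤ 0` reports an infinite half-life with a
warning rather than a negative one. How the published 30 vs 80 min values
were fitted is not stated; the log-linear choice is this package's.

Simulated decay noise is multiplicative log-normal with relative standard
deviation `noiseSd`, mean-one parameterisation
(`sdlog = sqrt(log(1 + noiseSd²))`, `meanlog = −sdlog²/2`), so noisy curves
are unbiased on the natural scale.

## Problem sizes and reproducibility

The shipped analyses are desk-scale by design: the six fixtures total 7,044
reads, round-trip property tests use 50 random compositions of up to ~40
reads, correlation scenarios use 2,000 reads × 100 null replicates on call
tables, and half-life recovery uses 200 seeded 6-point curves. All
randomness is seed-derived; `runPipeline()` writes a manifest (package
version, seed, full parameter set, artifact MD5 checksums) and rerunning an
identical configuration reproduces byte-identical tables.

## Known limitations

* Anchor assignment presumes the 3′-UTR terminus is unique to the gene
  panel; paralogous UTR ends would need longer anchors.
* Strict segmentation discards reads with any substitution inside the
  poly(A) tract, so at elevated error rates the called fraction drops and
  frequency denominators shrink (tolerant mode trades this against
  mis-measured lengths).
* Mixed additions containing A cannot be represented (maximal non-A block
  rule).
* No PCR-duplicate collapsing, no quality-aware calling, no indel handling,
  no multiple-testing correction across conditions.
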