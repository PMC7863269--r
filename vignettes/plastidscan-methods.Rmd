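---
title: "plastidscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastidscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidscan)
```

# Scope

`plastidscan` implements the comparative layer of a chloroplast-genome
study: quadripartite structure delimitation, microsatellite (SSR) scanning,
indel calling and slippage classification from a whole-genome multiple
alignment, sliding-window nucleotide diversity and hotspot ranking against
universal DNA barcodes, and distance-based phylogenetics from both sequence
and binary indel characters. A seeded simulator generates annotated
quadripartite genomes evolved along a known tree, with the true alignment,
event list and SSR catalogue attached, so every stage can be validated
end-to-end without any downloads.

Sequence assembly, annotation transfer, multiple alignment itself, and
maximum-likelihood / Bayesian tree inference are deliberately out of scope:
the package consumes and produces the standard formats those external tools
use (GenBank flat files, FASTA/GFF3, aligned FASTA, newick, NEXUS, relaxed
PHYLIP, VCF-style event records).

# Quadripartite structure

A plastome is modelled as a circular sequence carrying two identical
inverted-repeat arms (IRa/IRb) that split the circle into a large and a
small single-copy region (LSC, SSC). `detectQuadripartite()` finds the
*maximal exact* inverted-repeat pair by k-mer seeding (default `seedK = 25`)
of matches between the sequence and its reverse complement, followed by
ungapped maximal extension along the anti-diagonal (positions `a` and `b`
of the two arms satisfy `a + b = const` along a repeat). The sequence is
doubled internally, so arms spanning the record origin are found; reported
coordinates are on the canonical orientation (genome starts at the LSC
start, SSC follows IRb) with the applied rotation recorded.

Design notes:

* Exact matching (N never matches) is sufficient because plastome IRs are
  long and near-identical; it also makes the mirror invariant —
  `revcomp(IRb) == IRa`, byte-exact — testable, and the structure validity
  enforces `LSC + SSC + 2·IR == genome length` exactly.
* `minIr = 10000` by default: real plastome IRs are in the 15–30 kb range,
  and a high floor avoids spurious short repeats. Toy examples pass a
  smaller `minIr`.
* Several distinct pairs of equal maximal length abort with an ambiguity
  error listing the candidates rather than guessing.
* Deposited records whose two IR copies differ by a few bases at the
  boundaries would, under the exact-pair definition, yield the longest
  exactly mirrored core. A mismatch-tolerant fallback is intentionally not
  implemented; such genomes should be flagged by the caller (a known
  limitation, visible by comparing the detected arms with an external
  annotation).

GC content is `(G+C)/(A+C+G+T)` per region with N excluded from the
denominator; genomes over 1% N are rejected at construction. Gene counts
de-duplicate IR copies by suppressing genes wholly inside IRa — the
convention under which a fully annotated plastome yields counts like
113 = 79 protein-coding + 30 tRNA + 4 rRNA.

# Microsatellite scanning

`findSSRs()` reports maximal perfect tandem repeats with *primitive* motifs
of length 1–6 meeting per-length minimum repeat counts, default
`{10, 5, 4, 3, 3, 3}` (mono…hexa). These are the GMATA-style inclusive
minima; the thresholds object is user-configurable in case a strict
"greater than" reading is wanted. The scan compares the sequence with
itself shifted by `u` for each motif length; a run of `m` matches is a
stretch of length `m + u` with period `u`, and (by the Fine–Wilf property)
a stretch whose leading unit is non-primitive is exactly the stretch the
shorter-period scan reports with more units, so it is skipped at level `u`.
Whole units are reported from the leftmost phase. Loci contained inside
another reported locus are dropped; overlapping but non-nested loci are
both kept. Compound or interrupted repeats are not merged — only perfect
repeats count.

Motifs are reported as read on the forward strand of the canonical
orientation; `canonicalMotif()` provides the pooled (rotation- and
strand-independent) view. Per-genome tabulation counts IRa and IRb loci
separately by default (region label "IR"); `tabulateSSRs(dedupIr = TRUE)`
counts each IR tract once, matching copies through the canonicalized motif
because the IRa copy reads as the reverse complement. Both counting modes
are exposed because published per-genome totals do not always state which
convention they use.

# Indel calling and classification

`callIndels()` consumes an aligned set of whole genomes and a named
reference taxon. A maximal run of gap-bearing columns sharing one
per-taxon gap pattern is one event; identical spans shared by several taxa
therefore merge into a single multi-carrier event, while
overlapping-but-unequal spans split. This is the most conservative
reproducible granularity for counting discrete events shared across
species. Events are left-normalized — shifted to the leftmost equivalent
placement within repetitive context, as in VCF normalization — so
positions are stable across aligner idiosyncrasies. Polarity
(insertion/deletion) is relative to the reference only; no ancestral-state
inference is attempted.

An event is `SSR_related` when (a) its sequence is whole copies of a unit
of length 1–6 and (b) the allele carrying more copies forms, in phase with
the event and together with the adjacent reference sequence, a perfect
tandem run meeting the SSR threshold for that unit length. Tying the test
to the scanner's own thresholds avoids inventing a second repeat
definition: a 1-bp A indel next to nine A's is slippage (the long allele
reaches ten), next to eight it is not. Everything else is `non_SSR`.
Counting shared multi-species gaps once is the default tally; the
per-species view is available from the `carriers` column.

`buildIndelMatrix()` applies simple indel coding — one binary
presence/absence character per event (presence meaning the sequence is
present in that taxon) — and drops constant columns.

# Diversity, windows, markers

Site conventions: a column is *valid* when no row has a gap or N
(ambiguity codes other than N are collapsed to N); *variable* with at
least two distinct bases; *parsimony-informative* with at least two bases
each in at least two sequences. Percentage columns use the aligned length
as denominator, mirroring how such tables are usually printed, while pi
uses complete deletion:

pi = (1 / C(n,2)) * sum over pairs (i<j) of d_ij / L,

with `L` the number of valid columns and `d_ij` the pairwise differences
over them. pi over zero valid columns is an error, never 0.

`slidingWindowPi()` advances over alignment columns (default window 600,
step 100; the window midpoint is the natural x-axis). Windows with no
valid column carry `NA`. The trailing partial window (at least half a
window remaining) is emitted only on request: the defaults drop it, so a
1000-column alignment under 600/100 yields exactly five windows — the
convention of the widely used desktop tools this mirrors. Group analyses
(e.g. all taxa vs all-minus-one) re-strip gap-only columns per group
before windowing so coordinates stay comparable.

Markers are defined by anchor genes on the reference annotation: a genic
marker spans the gene; a spacer/composite marker spans from the end of the
upstream anchor to the start of the downstream anchor (so a composite like
rpl22–rps19–rpl2, anchored on its outer genes, includes everything between
them). Coordinates map through the reference row, keeping insertion
columns inside the interval. `markerReport()` scores each marker and the
named concatenations (universal barcodes rbcL + matK + trnH-psbA vs the
hotspot candidates) on length, variable/informative sites and pi.

# Trees

`pDistance()` (p-distance, pairwise deletion) and `indelDistance()`
(normalized Hamming on the binary indel characters) feed
`neighborJoining()`, which delegates the agglomeration to `ape::nj` and
clamps negative branch lengths to zero with a warning; tie-breaking among
equal Q-criterion pairs is therefore `ape`'s. Bootstrap support resamples
alignment columns with replacement under a fixed seed and reports the
fraction of replicate trees containing each bipartition of the base tree.
ML and BI inference are not reimplemented: `exportAlignment()` writes
relaxed PHYLIP or NEXUS for the external programs, and `sameTopology()`
checks topology classes (e.g. an expected ingroup arrangement) on whatever
tree comes back.

# The simulator: what it emulates, and what it does not

`simParams()` defaults describe a typical medicinal-Asteraceae-scale
plastome data set, the regime in which the analysis rules above are
defined:

| parameter | default | why |
|---|---|---|
| regions | LSC 84 kb, IR 25 kb ×2, SSC 18.7 kb | typical ~153 kb plastome proportions |
| tree | six-taxon ingroup, mean pairwise distance ≈ 0.00106 | congeneric chloroplast divergence is of order 10⁻³ |
| regionRateFactors | LSC 1.3, IR 0.3, SSC 1.8 | the IR evolves several-fold slower than single-copy DNA, SSC fastest — the ordering seen in plastome diversity tables |
| hotspot | 2.2 kb at the LSC tail, ×6.5 | one localized divergence hotspot, peak-to-mean ratio as observed for top windows |
| SSR tracts | 45/genome, 71% mononucleotide, 99% of monos A/T | plastome SSR composition is strongly A/T-mono biased |
| slippage | 0.067 per tract per branch, ±1 unit, 55:45 expansion bias | single-unit slippage dominates observed SSR-related indels |
| non-SSR indels | 8.8×10⁻⁵ per site per branch, geometric sizes (mode 1 bp), 1% long tail 0.4–1 kb | yields ~120 events per six-taxon set, ~25% SSR-related, with a rare large deletion |
| kappa | 2 | transitions about twice as likely as each transversion |

The simulator evolves the true alignment directly: every indel inserts or
gaps columns as it happens, so no external aligner is in the loop and the
event list *is* the alignment's ground truth. Substitutions in IRb are
mirrored (complemented) into IRa, keeping the inverted repeat byte-exact
in every descendant. The ancestor's background is scrubbed of accidental
tandem runs (by an independent regex pass) before tracts are planted with
pinned flanks, so the planted catalogue is exactly what a perfect scanner
should report on the ancestor.

Deliberate simplifications — and hence what passing tests do *not* show
about real data:

* SSR tracts and indels are excluded from the IR (and the four bases
  pairing across region boundaries are held fixed) so the IR mirror and
  the simulated region lengths stay exact. Real plastomes have some IR
  SSRs and IR boundary shifts; the detector handles them, but the
  simulator does not exercise them.
* No compound/interrupted SSR structure, no codon model, no
  recombination, no IR expansion/contraction events.
* Slippage moves one unit at a time; real tracts occasionally jump.
* The guide tree is fixed and correct; alignment error — the major
  real-world nuisance for indel calling — is absent by construction, so
  caller recall on truth alignments is an upper bound.

# Numerical and testing choices

* All coordinates are 1-based closed (`IRanges` convention) in R objects
  and reports; 0-based half-open appears only in BED output.
* Every stochastic computation funnels through one integer seed;
  simulation, bootstrap and pipeline reruns are byte-reproducible.
* The test suite validates each operation against an independent oracle
  (brute-force tandem-run enumeration for the scanner, per-column
  recounts for sites and pi, constructed circles for the structure layer,
  additive matrices for NJ, and the simulator's truth tables for the
  caller). Property checks run at compact problem sizes — 2 kb sequences
  for the scanner oracle, ~31 kb six-taxon genomes for cross-module
  checks, three full ~153 kb simulations plus fifty compact replicates
  for the recovery suite — chosen to keep the whole suite fast while
  exercising the same rates and rules as the full-scale run.
* The acceptance script (`scripts/acceptance.R`) re-runs the full-scale
  simulation and pipeline from scratch at the caller's seed and reports
  the headline quantities it computes; nothing in it is precomputed.

# Known limitations

* The exact-pair IR definition cannot represent slightly asymmetric IR
  copies (see above).
* GenBank parsing covers the location grammar organelle records use
  (`a..b`, `complement`, `join`, partial markers); deeply nested
  locations (`order(...)`, remote references) are rejected with a parse
  error.
* The indel caller requires a trustworthy multiple alignment; it does not
  realign, and alignment artefacts will surface as spurious events.
* Distance trees are a deliberate desk-scale stand-in for ML/BI; support
  values from `bootstrapSupport()` are bootstrap proportions on NJ, not
  posterior probabilities.
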