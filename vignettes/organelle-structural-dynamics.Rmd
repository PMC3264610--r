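---
title: "Structural dynamics of plant organellar genomes with OrganelleDynamics"
author: "OrganelleDynamics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural dynamics of plant organellar genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrganelleDynamics)
```

# Scope and model

Plant mitochondrial genomes are conventionally assembled and deposited
as a single circular *master circle* (MC), but in vivo they are
populations of molecules: recombination across repeated sequences
interconverts the MC with *isomeric* single circles (same content,
rearranged order/orientation) and, across direct repeats, excises
*subgenomic* circles. Chloroplast genomes, by contrast, are
structurally conservative, with a quadripartite architecture of two
inverted repeats (IRa/IRb) separating a large and a small single-copy
region (LSC/SSC), and they continuously donate sequence to the
mitochondrial compartment (such insertions are called *mtpt*).
OrganelleDynamics implements this whole analysis circle: repeat
discovery, recombination modelling, quadripartite detection, mtpt
detection and ageing, tRNA provenance, and codon decodability.

All coordinates are 1-based and inclusive, and circular molecules use
modular arithmetic: an interval with `start > end` wraps the origin.
Two length conventions coexist for arcs, because published segment
tables print `end - start` (one less than the inclusive base count);
`arcLength()` exposes both, and `decomposeSegments()` reports both per
segment. Under the inclusive convention, segment lengths plus twice the
repeat lengths tile the circle exactly — this conservation is asserted
on every decomposition.

# Maximal repeat discovery

`findMaximalRepeats()` reports every maximal exact two-copy repeat of
at least `min_length` bp (default 50, the conventional cutoff for
recombinationally relevant organellar repeats), in forward (F: the two
copies read identically) and palindromic (P: the second copy is the
reverse complement of the first) orientation. *Maximal* means
extendable in neither direction without a mismatch. The search seeds on
exact words of `min(min_length, 32)` bp shared between the genome and
(for P) its reverse complement, extends every seed diagonal to
maximality with circular indexing, and de-duplicates runs; the doubled
coordinate space means repeats crossing the origin are found without
special cases. The trivial whole-circle self-match and pairs whose two
copies overlap each other are excluded. Correctness is defined by an
exhaustive diagonal-scan oracle (every diagonal and anti-diagonal of
the circular sequence, maximal runs read off a run-length encoding)
that the test suite runs against the finder on more than fifty random
and planted genomes of up to 20 kb.

Each pair carries the closed-form expectation
`E = orientations × N² × (1/4)^L` as a significance annotation. This
is a documented simple expectation for chance maximal pairs in a
uniform random sequence, not a reimplementation of any published
repeat-finder statistic; published E-values from such tools are not
reproducible from the simple formula (a 101 bp pair in a 510 kb genome
evaluates to ~8×10⁻⁵⁰ under it), which is why the package filters
repeats by length only and never by E-value — downstream structural
results are insensitive to the formula.

# Recombination: segments, isomers, subgenomic circles

Given a set of repeat pairs (the recombinationally *active* subset is a
user input: activity is established by physical evidence such as
mate-pair support, not by sequence alone), `decomposeSegments()` cuts
the circle at the repeat copies and labels the inter-repeat segments A,
B, … from the lowest-coordinate segment start. `buildMasterState()`
arranges copies and segments into a cyclic signed unit list — the
`MoleculeState` — with all units on the + strand except the second copy
of each palindromic pair.

A repeat pair is *inverted* in a state when its copies carry opposite
signs, *direct* when they agree; prior inversions can flip either
status. `recombine()` implements one event:

* inverted pair → one product: the arc strictly between the two copies
  is reversed and strand-flipped (the repeat copies persist at the
  junctions, as the repeat is physically retained). The two possible
  arcs give the same molecule up to a whole-molecule flip; the
  implementation computes both and asserts their canonical keys agree
  rather than assuming it.
* direct pair → two products: the excised circles, each retaining one
  repeat copy.

Molecule identity is decided by `canonicalKey()`: the lexicographic
minimum over all rotations of the unit string and of the flipped,
order-reversed unit string. `enumerateIsomers()` runs a breadth-first
closure, applying every available inversion to every reached
single-circle state until no new canonical form appears; excision
products are recorded but not expanded (subgenomic circles are reported
separately and never counted as isomers, and reintegration of excised
circles is out of scope). Closure to fixpoint matters: some reachable
isomers require two or more successive inversions. For the
three-active-pair mitochondrial configuration bundled with the package
(two palindromic pairs of 1,474 and 843 bp and one forward pair of 222
bp on a 510,519 bp circle), the closure yields exactly four isomers
besides the MC, with the direct 222 bp pair contributing the excision
route.

`moleculeGeneReport()` translates a molecule into per-gene exon strand
patterns ("+"/"−" per exon in exon order), flagging cross-strand
(trans-splicing) genes and exons stranded on absent segments. Exons
must lie wholly inside one segment (or one repeat copy); an exon
spanning a cut point is a hard error naming the exon. Exons placed
inside repeat copies are reported with the strand of that repeat unit
in the current state — exact for the first copy; ambiguous placements
between identical copies after rearrangement are not resolved.

# Quadripartite detection

`detectQuadripartite()` defines IRa/IRb as the longest palindromic
maximal repeat pair of at least `min_ir` bp (default 1,000), reusing
the repeat finder, and assigns the longer inter-IR arc to LSC, the
shorter to SSC; IRa is the copy following the LSC. IRs are therefore
required to be exact reverse complements — the common case for
plastomes, and the choice that keeps the detection oracle exact;
genomes whose IRs differ by a few substitutions are outside the default
model. Equal-length competing candidate pairs raise an error demanding
a manual choice rather than guessing. Region fractions are reported per
single IR copy (one IR's length over the genome length), the convention
used in genome reports. The conservation `2·IR + LSC + SSC = N` is
asserted on every map. `junctionFeatures()` reports features
containing or abutting each of the four junctions.

# Plastid-derived sequence (mtpt) detection

`findCpDerived()` aligns the mitochondrial genome against the
chloroplast genome of the same species with the package's own
seed-and-extend local aligner and keeps alignments passing all of:
identity ≥ 80%, E-value ≤ 10⁻⁵, length ≥ 50 bp (the conventional
thresholds, which are also the package defaults in
`alignmentParams()`). The aligner:

1. seeds on exact 8-mers on both strands and clusters seeds per
   diagonal with a 150 bp gap tolerance (substitution divergence keeps
   homologous seeds on a single diagonal; the default simulators are
   substitution-only, and indel-rich homology would fragment across
   diagonals — a documented limitation of the default engine);
2. screens each cluster by raw ungapped identity over a window extended
   40 bp beyond the cluster, discarding chance seed clusters (their
   identity is diluted toward the 25% background) at threshold 0.45;
3. refines survivors by affine-gap local alignment
   (match +2 / mismatch −3, gap open 5 / extend 2) with a 50 bp margin;
4. end-trims the refined alignment until each end opens with a dense
   match window (≥ 5 matches in 8 columns), so boundaries track the
   homologous block instead of lucky flank columns — a bounded amount
   of boundary noise (occasionally ~10 bp on one end) survives any such
   rule, which is why the tests state boundary accuracy as a
   distributional claim and recall/precision by overlap;
5. resolves overlapping mt-side hits greedily by score, then length,
   then leftmost position. Hit counts on real genomes depend on this
   merge rule, which is why count-type comparisons across aligners
   deserve a few percent of slack.

E-values use a Karlin–Altschul-style formula with fixed ungapped
nucleotide parameters (λ = 0.625, K = 0.41) and the two genome lengths;
with the identity and length thresholds in force the E-value cutoff is
never the binding constraint. Per-hit GC is computed on the mt-side
sequence, N bases excluded.

`classifyAge()` calls a hit *old* if its mt-side sequence aligns to at
least one other species' mitochondrial genome at the same
identity/E-value thresholds covering ≥ 50% of the hit, and *new*
otherwise — homology in another mitochondrial lineage implies the
transfer predates the species split, absence suggests a recent event.
An empty panel leaves hits unclassified. `regionOfOrigin()` assigns
each hit to LSC, SSC or IR by the midpoint of its chloroplast-side
interval. `summarizeTransfer()` aggregates counts, total bp, genome
fraction, and length-weighted GC per age class.

`pearsonR()` and `welchT()` wrap the standard sample correlation and
Welch two-sample test (the tests cross-check both against the closed
formulas). On the bundled comparative GC table of eleven species, both
published correlation coefficients reproduce as Pearson *r* over the
eight species that carry new insertions: r(Cp-GC, New-GC) = 0.69 and
r(Mt-GC, Old-GC) = 0.64 at two decimals. Two choices deserve note,
both made because they reproduce the printed values: the quantities are
reported as *r* although the source labels them "r²" (the squared
reading reproduces neither number), and the old-insertion correlation
is computed over the new-insertion-bearing subset — including the two
lower plants, whose ancient insertions have extreme GC, flips the sign.

`classifyTrnas()` applies the same thresholds (with coverage relative
to the mt tRNA) to call each mitochondrial tRNA cp-derived or native;
tRNA-length sequences skip the seeding stage and are aligned directly.

# Codon usage and wobble decodability

`codonUsage()` counts frame-0 codons across a CDS set and reports
stop-codon usage over terminal codons only; internal stops warn (in
organellar genes they often flag RNA-editing sites) but still count.
`decodableCodons()` computes the set of sense codons readable by a
tRNA gene set under a configurable wobble model, `wobbleRules()`:

* **strict** — classical wobble at anticodon position 34: G34 reads
  C/U, U34 reads A/G, C34 reads G, A34 reads U;
* **superwobble** — additionally, U34 reads all four third positions in
  four-codon family boxes (boxes whose four codons are synonymous);
* **two_of_three** — additionally, in family boxes served by no U34
  isoacceptor, any isoacceptor of the box reads all four third
  positions (the first two codon positions suffice).

The lysidine special case (modified C34 in the isoleucine CAU tRNA
reading AUA, not AUG) is on by default and keyed to the trnX-NNN gene
naming. The three policies are nested, and the tests assert this
monotonicity on random anticodon subsets. Under the default
(two_of_three + lysidine) rules the bundled 27-gene chloroplast tRNA
set decodes exactly 61 sense codons — i.e. the full sense-codon
complement. The two-out-of-three component is load-bearing in exactly
two boxes of that set (ACN, which has only a G34 threonine tRNA, and
CGN, which has only an A34 arginine tRNA); no published wobble
convention accompanies the claim this reproduces, so the rule set above
is this package's declared model, configurable and logged rather than
hidden.

# Simulators and what passing tests mean

The generators produce every fixture from a seed, restoring the global
RNG state afterwards:

* `simulateRepeatGenome()` — i.i.d. background at a target GC (default
  0.43, typical of seed-plant mitochondrial genomes) with repeats
  planted by copy or reverse-complement copy. Flanking bases are
  adjusted so each planted pair is *exactly* maximal at its planted
  length, making truth tables exact oracles.
* `simulateQuadripartiteGenome()` — LSC + IRa + SSC + revcomp(IRa)
  around a circle at GC 0.37 (typical plastome), IR boundaries pinned
  non-extendable the same way.
* `simulateTransferPair()` — a quadripartite cp-like genome and an
  mt-like background; cp fragments are copied in, point-mutated to an
  exact Hamming identity (`mutateToIdentity()`: exactly
  `round((1−identity)·L)` substitutions, never base-to-itself, no
  indels — so planted identity is exact and recall/precision checks are
  deterministic), and separated by ≥ 200 bp so hits map one-to-one onto
  plants. The truth table records, per fragment, the planted intervals,
  identity, GC, cp region, and the length of the unmutated terminal
  runs (only fragments with intact ends have recoverable boundaries).
* `simulateTrnaSet()` — cp tRNA genes, verbatim-or-mutated copies in
  the mt set, plus unrelated native tRNAs.

The simulators emulate the statistical structure the analyses assume —
uniform background composition, substitution-only divergence, exactly
maximal planted repeats — and none of the things real organellar
genomes add: compositional heterogeneity, low-complexity and tandem
repeats, indel divergence, nested or overlapping transfers. Passing the
planted-recovery suites therefore demonstrates algorithmic correctness
under the declared model, not field performance on arbitrary genomes;
the accession-dependent checks in the test suite (quadripartite
dimensions, mtpt totals and stop-codon usage of the deposited Boea
records) are the bridge to real data and require the user to supply the
GenBank records locally, as they are too large to ship as plain-text
package fixtures.

Problem sizes in the test suite were chosen so the whole suite runs in
a few minutes on one core: oracle-checked genomes of 0.8–12 kb (the
exhaustive oracle is quadratic), twenty transfer scenarios on 40–60 kb
mt backgrounds, and the full-size 510,519 bp coordinate-level
decomposition (which needs no sequence at all).

# Numerical and design choices

* GC content excludes N from numerator and denominator; an all-N
  sequence has undefined (NA) GC.
* Ties in repeat sorting break by `start1`; overlapping-hit resolution
  breaks by score, then length, then leftmost.
* Features wrapping the origin are stored as single `start > end` rows
  rather than split; writers (GFF3/BED) split them at the boundary, and
  the GenBank reader merges a two-part origin-abutting `join()` into
  one wrapped row, so split and wrapped encodings round-trip.
* `decomposeSegments()` skips zero-length gaps between abutting repeat
  copies; labels follow coordinate order of the remaining segments.
* The 14-pair published repeat table ships as data
  (`boeaMtRepeats()`), with the three recombination-active pairs
  flagged; `boeaRecombinationPairs()` is the canonical input for the
  master-circle analyses. Published E-values in that table are carried
  as annotations, never recomputed or filtered on.
* `runPipeline()` validates its whole configuration before any stage
  runs, stamps every output with the package version, a configuration
  hash and the seed, and produces byte-identical outputs for identical
  configuration and inputs.

# Known limitations

* The repeat finder treats N as unmatched during extension but does not
  excise N-containing seed words; genomes with long N runs should be
  masked first.
* The mtpt aligner's diagonal clustering assumes substitution-dominated
  divergence; use the refinement-stage gapped alignment (which does
  handle indels) only after seeding succeeds. Heavily indel-diverged
  transfers below ~100 bp can escape seeding.
* Detected insertion boundaries carry a few bp of noise where planted
  (or real) homology ends are themselves degenerate; GC and length
  statistics are robust to this, single-hit boundary coordinates are
  not.
* Isomer enumeration treats molecules as unit lists, not sequences:
  two distinct repeat pairs of identical length are distinguished by
  position, but sequence-identical repeat families with more than two
  copies are modelled as independent pairs.
* tRNA classification considers only same-species cp-vs-mt homology;
  horizontal transfer between species and nuclear copies are out of
  scope.
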