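---
title: "Methods: comparative small RNA analysis with sRNAbud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative small RNA analysis with sRNAbud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAbud)
```

sRNAbud implements the comparative small RNA sequencing analysis used to
contrast two plant libraries — the motivating case is perfect versus
imperfect (pistil-aborting) flower buds of Japanese apricot, sequenced on an
early short-read platform — as a set of testable modules: read cleaning,
tag collapsing, annotation, hairpin-based novel miRNA discovery,
differential expression by an exact count test, and miRNA target scanning.
A synthetic-data generator with complete ground truth stands in for the
unavailable raw libraries, so every stage is verifiable end to end.

## Read cleaning

A raw read is `insert + 3' adapter (+ filler)` at a fixed read length
(36 nt in the simulated platform).  Cleaning assigns every read to exactly
one category, checked in a fixed precedence that mirrors the usual cleaning
ledger: low quality → 3' adapter null → 5' adapter contaminant → insert
null → shorter than 18 nt → poly(A) → clean.  Operational definitions the
upstream description leaves open were fixed as follows and are
configurable:

* **High quality** — no `N`, and fewer than 10% of bases below Phred 20.
  This is conventional small RNA practice; the threshold matters little
  because adapter location dominates the outcome.
* **Adapter search** — exact match of the first 8 nt of the 3' adapter,
  rightmost occurrence.  Rightmost is the safe choice under adapter
  read-through: a spurious 8-mer inside the insert cannot shadow the true
  adapter start.  A read without the 8-mer is "3' adapter null"; an empty
  trimmed insert is "insert null".
* **Poly(A)** — a trimmed insert with at least 80% A, the signature of
  oligo-dT artifacts.
* Inserts longer than `max_len` carry no usable small RNA and are folded
  into "3' adapter null".

Clean inserts of 18–30 nt are collapsed into unique tags with per-library
counts; the clean-read totals become the normalization denominators N1 and
N2.

## Annotation

Tags are classified by first match in the precedence rRNA → snRNA →
snoRNA → tRNA → mature miRNA → unannotated.  ncRNA classes match by
substring containment in either strand of any class reference, because
reads from structural RNAs are degradation fragments; mature miRNAs match
only by exact full-length identity, the "perfectly matched" convention for
calling conserved miRNAs.  Family member counting strips `-3p`/`-5p` arm
suffixes first: the two arms of one precursor are one member.

## Hairpin discovery

Unannotated tags with at least `min_mature_count` reads (default 5, about
the smallest mature counts reported for credible novel miRNAs) are mapped
to the genome by exact full-length matching on both strands; tags hitting
more than 20 loci are dropped as repeats.  Around each locus two flanking
windows are excised (20 nt upstream + flank downstream, and the reverse) at
several flank extents — 30, 80, 150, 250 nt, shortest first.  Scanning
extents matters: a genuine hairpin can be masked in a long window when the
minimum-energy structure pairs its stem with flanking sequence, and trying
the short excision first recovers it.  The 250 nt ceiling keeps precursors
up to a few hundred nt reachable.

Each window is folded by the package's minimum-free-energy engine and the
candidate is accepted only if all of the following hold:

1. the mapped tag (putative mature) sits wholly on one arm of the stem,
   outside the terminal loop;
2. the star sequence implied by a duplex with 2-nt 3' overhangs on both
   strands has at least one sequenced read — star evidence is the
   operational signature of genuine Dicer processing;
3. the duplex has at most 4 unpaired mature positions and no asymmetric
   bulge over 2 nt (the conventional plant-miRNA duplex criteria);
4. the window folds at or below −18 kcal/mol under the in-package model;
5. the precursor trimmed to the minimal hairpin spanning the duplex is at
   least 50 nt.

The star span is located from the fold's pairing partners of the mature
ends, extrapolating across locally unpaired positions; rejected candidates
carry machine-readable reasons.  Accepted loci that overlap on the same
strand are clustered (a hairpin supported by both its mature and star tags
is reported once, keeping the highest-count tag as mature).  Identical
matures at distinct loci remain distinct candidates.

## The folding engine

Energies come from a reduced nearest-neighbor model: Turner-style stacking
energies for the 36 ordered pair-type combinations (Watson–Crick plus G:U
wobble), hairpin loops of at least 3 nt penalized `5.0 + 0.15(s−3)`
kcal/mol, interior/bulge loops `2.0 + 0.35s` (capped at 30 unpaired
bases), and an affine multiloop cost `3.4 + 0.4·branches + 0.1·unpaired`.
The minimum-energy nested structure is found by a Zuker-style dynamic
program over integer centi-kcal energies with a deterministic traceback
(candidates re-examined in a fixed order), so results are exactly
reproducible.  An exhaustive-enumeration oracle scores every nested
structure by loop decomposition and shares only the parameter tables with
the dynamic program; the two agree exactly on every sequence short enough
to enumerate (property-tested at up to 22 nt).

Two points deserve emphasis.  First, absolute energies are specific to this
model: the −18 kcal/mol acceptance gate is applied under it and is
configurable; energies from other folding programs are comparable only
qualitatively.  Second, the familiar mirror symmetry — a sequence and its
reverse complement folding to mirror structures of equal energy — holds
exactly only when G:U wobble is disabled (`allow_gu = FALSE`), because the
reverse complement of a G·U pair is A·C, which does not pair.  The test
suite checks the symmetry in the Watson–Crick sector.

## Differential expression

For each miRNA with raw counts `x`, `y` and clean-read totals N1, N2:

* normalized expression = `count / total × 10⁶` (reads per million);
  tables report 2 decimals, internal arithmetic is full precision — the
  reported fold-changes are reproducible only from unrounded normalized
  values;
* a normalized value of exactly 0 is revised to 0.01; a pair with both
  values below 1 is excluded as too lowly expressed;
* fold-change = `log2(imperfect / perfect)`;
* significance comes from the Audic–Claverie exact test on the raw integer
  counts: conditional on `x`, the count in the other library follows
  `p(γ|x) = r^γ (x+γ)! / (x! γ! (1+r)^{x+γ+1})` with `r = N2/N1`; the
  two-sided p-value doubles the smaller of the inclusive lower and upper
  tails.  Raw counts, not normalized values, enter the factorials: the
  formula requires integers.  All terms are evaluated through `lgamma` in
  log space and the upper tail as `1 − Σ_{γ<y}` with compensated summation.

The conditioning library is arbitrary, and the inclusive-tail convention
makes the two conditioning orientations differ by the order of the
boundary point mass.  `ac_pvalue` therefore reports the average of the two
orientations, which is exactly invariant under swapping the libraries;
both raw orientations remain available via the `orientation` argument.
Under a simulated null the empirical type-I error at α = 0.05 sits slightly
below nominal (the test is conservative because both tails include the
observed count).

A record is called differential when the linear fold-change exceeds 1.5 in
either direction and p < 0.05 (`**` below 0.01).  Whether "1.5-fold"
bounds the linear ratio or |log2 fold-change| is ambiguous in the
original description; the linear ratio is the default and both readings
are exposed.  No multiple-testing correction is applied, matching the
original analysis.

## Target scanning

Differential miRNAs are scanned against transcripts by ungapped sliding
windows compared to the miRNA's reverse complement.  Per position
(position 1 = miRNA 5' end): Watson–Crick 0, G:U wobble 0.5, mismatch 1.0,
penalties doubled in the seed-proximal core (positions 2–13).  A hit needs
at most 3 mismatches ("fewer than four") and penalty at most 4.0.  G:U
pairs are tallied separately from mismatches by default
(`gu_as_mismatch` flips this, an ambiguity the original screen leaves
open).  Gapped alignment is out of the default path because the original
screen was a mismatch-count filter.

## The synthetic study

`simulation_spec()` defaults define the emulated study: two libraries of
10⁵ fixed-length 36-nt reads with 3' adapter read-through; 61 planted
known mature miRNAs in 24 families (member counts 8/6/5 for the three
largest, geometric rank-abundance floored at 5 reads per 10⁵), three of
them at a planted 3-fold differential and two condition-specific; five
novel hairpins with star reads at 2% of mature abundance; an
rRNA/tRNA/snRNA/snoRNA fragment background at 12.6% of reads; contaminant
classes at the per-mille rates of a well-behaved run (0.24% adapter null,
0.16% 5' contaminants, 0.22% too-short, 0.03% each insert-null and
poly(A)); and condition-specific insert-length distributions peaking at
21 and 24 nt, the two canonical plant small RNA classes.  Planted
abundances are expected reads per 10⁵ and scale with depth.

Planted hairpins are perfect inverted repeats with a 12-nt loop and two
controlled mutations on the star side of the duplex.  The mutations play
two roles: real precursors are imperfect, and a perfect stem would make
the mature an exact inverted repeat mapping to both strands at once.  Each
design is self-checked — the bare precursor must fold back to the intended
duplex and pass the acceptance gates with its designed star — and redrawn
until it does, so planted truth is recoverable by construction.  Whenever
a planted mature draws at least one read, at least one star read
accompanies it, keeping hairpin truth recoverable at shallow depths.

Background inserts span 18–28 nt rather than the full 18–30 nt window: at
read length 36 with an 8-nt adapter-seed requirement, a 29–30-nt insert
leaves too little adapter to detect, and keeping inserts at most 28 nt
makes every cleaning category unambiguous so the ledger equals the truth
table exactly.  All random sequences avoid the 8-nt adapter seeds for the
same reason.

What the generator does **not** emulate: sequencing errors beyond the
optional degraded-quality mode, isomiR/length heterogeneity around planted
matures, true ncRNA secondary structure, repeat-rich genomes, and real
miRNA sequence composition.  Passing tests therefore demonstrate
correctness of the pipeline's logic under clean, unambiguous conditions,
not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* Folding uses integer centi-kcal energies; ties in the traceback resolve
  by a fixed candidate order, so outputs are byte-stable across runs.
* Table values round 2 dp half away from zero (`round_half_up`), isolating
  binary-representation edge cases from reported numbers.
* `ac_pvalue(0, 0, N, N) = 1`; with unequal totals the value is
  `< 1` because the lower tail at zero is the point mass `1/(1+r)`.
* Empty inputs: zero-depth simulation warns and emits empty libraries;
  an empty read set yields an all-zero ledger; an empty reference set
  warns and leaves tags unannotated; rejection of a hairpin candidate is a
  result with reasons, never an error.
* Coordinates are 0-based half-open internally; reports print 1-based
  inclusive `scaffold:start:end:strand`.

## Problem sizes in the test suite

The suite validates the folding engine against exhaustive enumeration on
200 random sequences of 15–22 nt, the count test against direct tail
summation on 500 random count/total tuples plus 1,000 null simulations,
the target scanner against a naive all-window oracle on 50 synthetic
transcripts, and the full pipeline on simulated studies of 10⁵ reads per
library (with smaller 1.5–2×10⁴-read studies for module-level checks).
These sizes give stable statistical assertions (3-sigma binomial bands,
type-I error within [0.03, 0.07]) while keeping the whole suite under a
minute of compute.

## Known limitations

* The folding model is a reduced nearest-neighbor parameterization:
  adequate for ranking hairpin candidates and fully oracle-checkable, but
  not a substitute for full Turner-parameter folding when absolute
  energies matter.
* Trans-species mapping (reads from one species on a relative's genome) is
  modeled as exact matching; a mismatch-tolerant mode exists but is off by
  default.
* The Audic–Claverie test assumes Poisson sampling of counts; it has no
  overdispersion term, so biological replicates (absent in the emulated
  design) would require a different model.
* Printed p-values in the original differential table are not reproducible
  from any consistent reading of the published formula (normalized values
  inside factorials); the package reproduces the normalization and
  fold-change arithmetic exactly and treats the test through its defined
  structural properties instead.
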