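---
title: "Detecting internal complementary base-pairing sequences in circRNAs"
author: "icbpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal complementary base-pairing sequences in circRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbpscan)
```

## The problem

Circular RNAs (circRNAs) are covalently closed loops produced by
backsplicing; they have no 5' or 3' end and no poly-A tail. A circRNA is
usually drawn as an open ring, but whenever two disjoint stretches of the
same molecule are exact reverse complements of each other, the ring can
fold back on itself and form an internal duplex. We call such a pair of
stretches an *internal complementary base-pairing sequence* (ICBPS): two
disjoint arms, each read 5'→3', one the exact antiparallel Watson–Crick
complement of the other. Internal duplexes are of interest because a
"closed" duplexed region can bury miRNA recognition elements (MREs) or an
open reading frame (ORF), changing what the molecule can sponge or
translate, and because extremely long circRNAs (el-circRNAs, here defined
strictly as > 5,000 nt) carry many such regions.

`icbpscan` finds every *maximal* ICBPS pair in a circRNA, summarises each
molecule by a small set of statistics, intersects arms with annotation
intervals on circular coordinates, aggregates cohort-level distributions
and correlations, and generates synthetic cohorts with planted ground
truth so that the whole pipeline can be validated without any database
download.

## Definitions and per-circRNA statistics

For one circRNA of total length `circLen` (nt), scanned at a minimum arm
length `min_len`:

* **maximal pair** — a pair of disjoint arms, exact reverse complements,
  not extendable at either end *in the same pairing register* without
  breaking the match or the disjointness. Maximal pairs are the unit that
  is counted; sub-pairs contained in a maximal pair of the same register
  are never reported.
* **nPairs** — number of maximal pairs with arm length at or above the
  reporting threshold (default 20 nt; candidates are detected from 10 nt).
* **maxLen / medianLen** — maximum / median arm length over those pairs.
  The median of an even number of pairs is the arithmetic mean of the two
  central values (reported to 1 decimal; the convention is free because
  only binned medians are ever compared).
* **complementary ratio** —
  `CR = 2 * maxLen / circLen * 100%`, the percentage of the circle
  occupied by the longest duplex (both arms). `CR = 0` exactly when no
  pair passes the threshold, and `CR = 100` when the two arms of the
  longest pair tile the whole circle. Reported to 2 decimals.
* **el-circRNA** — `circLen > 5000`, strict inequality.
* **pattern flags** — `multi_partner`: some arm serves two or more
  distinct partners (one segment intersects an arm of another pair while
  the two partner arms do not intersect each other); this captures the
  shared-arm topology even when, after canonical ordering, the shared
  segment is the upstream arm of one pair and the downstream arm of the
  other. `overlapping_complements`: any two pairs have intersecting arms
  at all. A 1-nt intersection counts, and intersection is evaluated on the
  circle.

## The scanner

Complementarity is strict antiparallel Watson–Crick (A:T/U, G:C). There is
no G·U wobble — a wobble pair would not be *completely* complementary —
and no mismatch or bulge tolerance: matching is purely lexical, not
thermodynamic. U is normalized to T on input so DNA- and RNA-alphabet
records behave identically; positions holding N never participate in any
pair.

`find_icbps_pointer()` implements a seed-and-extend version of the classic
two-pointer window search. One pointer anchors the start of a query
window, the second marks its end, starting at `min_len`. The window is
looked up (via a k-mer hash) among the reverse-complement k-mers of the
sequence; every disjoint occurrence fixes a *pairing register* (the
anti-diagonal `q + p + L`), and the window is grown to its maximal extent
in that register — the end pointer advances as long as the next base still
pairs and the arms stay disjoint, then the start pointer retreats
likewise. Each maximal pair is discovered once per anchor inside its arms;
duplicates are collapsed, and pairs are reported in canonical orientation
(upstream arm first; ties are impossible because arms are disjoint),
sorted by arm starts.

Two readings of the classical two-pointer description deserve a note:

* *Per-anchor growth.* Growing a single longest window per anchor would
  silently miss maximal pairs whose register is shadowed by a longer
  window at the same anchor. The scanner therefore grows the window
  separately in every register in which the anchor window has a partner;
  this is what makes "every maximal pair is returned exactly once"
  provable, and it is the property the brute-force oracle checks.
* *Partner position.* Whether the partner must lie strictly downstream of
  the query (which would explain a stop rule at `2 * min_len` from the
  end) or anywhere in the molecule makes no difference to the output: arms
  are disjoint and pairs are canonicalized with the upstream arm first, so
  both readings produce the same pair set. No switch is exposed for it.

**Circular mode.** The default scan is linear on the given linearization,
which matches how backsplice-junction sequences are usually analysed. A
circle has no ends, though, so junction-crossing duplexes are chemically
possible: with `wrap = TRUE` the same machinery runs on the concatenated
sequence (anchors and partner representatives taken from the middle copy
of a triplication, so every circular window is contiguous), disjointness
is evaluated on the circle, and rotational duplicates are removed.
Coordinates of wrapping arms are reported with `end > circLen` plus a wrap
flag. In wrap mode the reported pair set is invariant under rotating the
linearization point, up to the corresponding coordinate shift.

**Degenerate repeats.** Self-complementary microsatellites (e.g. poly-AT)
legitimately produce very many overlapping maximal pairs; in fully
self-complementary circular registers the maximal splits are the
half-circle partitions whose two residual gaps are both shorter than 2 nt.
Both the scanner and the oracle enumerate these correctly, but a
per-record cap (`max_pairs`, default 10,000) aborts with a clear error
rather than letting a pathological record run away.

**The oracle.** `find_icbps_bruteforce()` is an independent quadratic
implementation used for validation: it materialises the full pairing
matrix `M[i, j]` ("position j carries the base that pairs with position
i") and decomposes it along anti-diagonals, where maximal runs of matches
map onto each other under the mirror `i -> d - i`. A pair of distinct
mirror runs is one maximal pair; a self-mirrored (near-palindromic) run
contributes its two halves, abutting at the centre. The test suite checks
set-equality of the two implementations on hundreds of random and
periodic sequences in both modes.

## Overlap with annotations

Annotations (MREs, ORFs, arbitrary region labels) are supplied as interval
files — the package deliberately does not re-implement miRNA target
prediction or coding-potential scoring, which are established external
tools; their outputs are consumed as intervals. A circRNA *overlaps* a
kind when any arm of any reported pair intersects any annotation of that
kind by at least 1 nt (the most permissive reading; no minimum overlap is
imposed). Overlap is evaluated between annotations and ICBPS *arms*, not
the whole molecule — the statistic is about duplexes burying sites.
Per-circRNA flags drive the cohort percentages, and
`n_overlap_events` counts every intersecting (arm, annotation)
combination. All interval algebra is circular: intervals may cross the
junction (`end > circLen`) and intersection is invariant under joint
rotation.

On disk, annotation files are BED-like and 0-based half-open (standard
6-column BED is also accepted, with the kind in the name field); in
memory, everything is 1-based inclusive, the R/Bioconductor convention.
Pairs and profiles tables are 1-based inclusive both in memory and on
disk.

## Cohort statistics

`summarize_cohort()` assembles the classic cohort panels: histograms of
maxLen (over circRNAs with maxLen ≥ 10 nt), of pair count and of CR, with
explicit under-/overflow bins so counts always conserve mass (last bin
closed, all others left-closed right-open); Pearson correlations of pair
count and of maxLen against circRNA length; and the fraction of circRNAs
carrying at least one reported pair. Following the corresponding figure
captions literally, the length cap (default 10,000 nt) applies to the
pair-count correlation only, the maxLen correlation is unrestricted.
Whether correlations use all circRNAs or only those that carry pairs is
ambiguous in the source material; the default is the with-pairs subset
(`with_pairs_only = TRUE`), switchable. p-values are two-sided from the
t-distribution with n − 2 df; no multiple-testing correction is applied
(none is applied in the analyses this mirrors). Correlations are refused,
with a warning, below n = 3 or on constant input. Default bin edges mirror
the usual figure granularity (maxLen in 5-nt steps from 10; CR in 5-point
steps) and are configurable, since exact published edges are not
available.

## The synthetic generator

`generate_cohort()` draws i.i.d. random backbones (default 50% GC —
complementary-match base rates depend strongly on composition, so GC is a
spec parameter) with lengths either fixed or log-uniform over a range,
optionally forcing a fraction of records to el-circRNA length, and plants:

* A/A′ pairs — one arm and one reverse-complement partner, at random
  disjoint positions or at an exact separation;
* B/B′/B″ topologies — one arm with ≥ 2 disjoint partners (each
  arm–partner combination is one ground-truth pair, sharing the arm);
* MRE/ORF-like intervals — the first interval of each kind intersects a
  planted arm with the plan's stated probability and is otherwise kept
  clear of all arms, so the realized per-record overlap status is exactly
  one Bernoulli draw; ORF lengths are multiples of 3, at least 60 nt,
  MREs 7–22 nt.

Planted arm sequences are drawn free of internal repeated or
self-complementary k-mers so partner copies cannot interact, and
successive plantings avoid each other's intervals. A **cleanliness check**
then rejects and resamples any record in which the set of complementary
matches of length ≥ `clean_min_len` differs from the planted truth: below
2,000 nt the brute-force oracle provides an exact verdict; above, a shared
reverse-complement k-mer screen is used (conservative: it cannot miss an
exact match of length ≥ k, and it additionally verifies every planted
duplex is intact). Cleanliness must be requested at a scale the backbone
can satisfy: the expected number of chance decamer matches grows with the
squared length (≈ 17 in a 6-kb random sequence), so demanding a 6-kb
record clean at k = 10 would reject essentially every realization. For
el-circRNA-scale constructs the check is therefore run at the 20-nt
reporting threshold — chance ≥ 20-nt matches are vanishingly rare — which
is exactly what profile-level assertions need. Cohorts are deterministic
functions of (spec, seed), and generation restores the caller's RNG
state.

What the generator emulates is the *statistical skeleton* of a circRNA
cohort: lengths, planted exact duplexes of known size and topology, and
annotation intervals with a controlled arm-overlap rate. What it does not
emulate: exon structure and splicing biogenesis, the empirical length and
composition biases of real databases, imperfect (bulged, wobbled)
duplexes, and thermodynamic stability. Passing the planted-recovery and
overlap-calibration tests therefore demonstrates algorithmic correctness
on known truth, not biological realism of any particular cohort.

## Numerical and design choices

* Coordinates: 1-based inclusive everywhere in R, 0-based half-open only
  in BED-like files (converted at the boundary); wrap encoded as
  `end > circLen`.
* CR uses the maxLen among pairs at or above the reporting threshold, so
  CR is consistent with the reported pair set and is 0 exactly when
  nothing is reported.
* `report_threshold >= min_len` is enforced; records shorter than
  `2 * min_len` are profiled with zero pairs after a warning, records
  failing alphabet normalization are skipped with a warning and counted.
* The scanner reports only maximal pairs; a "report non-maximal pairs"
  switch would have no coherent semantics under bidirectional maximal
  extension and is not offered.
* Determinism: identical inputs and configuration give identical outputs,
  including file outputs; no timestamps enter data files.

## Problem sizes used by the test suite

The suite validates oracle equivalence on 100+ random circRNAs of
100–300 nt (GC 0.3–0.7, `min_len` 4–10, both modes), planted recovery on
50 records of 500 nt, pattern classification on 50 records of 600 nt,
rotation invariance on 20 records of 300 nt, overlap calibration on
3 × 500 records of 300 nt, and the el-circRNA worked example at 6,071 nt —
sizes chosen so the whole suite runs in a few minutes while every code
path, including the quadratic oracle, is exercised.

## Limitations

* Lexical matching only: no folding energies, no secondary-structure
  prediction, no imperfect duplexes. A reported ICBPS is a *candidate*
  duplex; whether it actually forms in vivo depends on thermodynamics and
  context the package does not model.
* The brute-force oracle is quadratic in memory and is intended for
  records up to ~2,000 nt.
* The "open/close" dynamics of duplexed circRNAs (m6A regulation, RBP
  binding, degradation) are a biological hypothesis with no computable
  model here; the package quantifies sequence-level potential only.
* Database-scale published counts depend on the database version and on
  external MRE/ORF predictors and are not reproduced; the pipeline
  validates the computations on synthetic truth instead.
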