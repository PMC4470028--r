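---
title: "Grading p53 response elements: the model behind p53scan"
author: "p53scan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading p53 response elements: the model behind p53scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53scan)
```

## The biological model

p53 binds DNA as a tetramer — a dimer of dimers — with each monomer
contacting a 5 nt quarter site. The canonical response element (RE) is
two copies of the palindromic decamer `RRRCWWGYYY` (R = A/G, W = A/T,
Y = C/T), i.e. four quarter sites, optionally separated by a spacer of
0–13 bp between the half sites. Transactivation assays across large
collections of RE variants support a set of qualitative regularities
that similarity-percent or additive matrix scores do not capture:

* mismatches in the `CWWG` core are far more damaging than peripheral
  ones;
* mismatches in the two **internal** quarter sites (those flanking the
  junction between half sites, where the two dimers cooperate) hurt more
  than the same mismatches in the external quarters;
* several mismatches **grouped in one quarter site** (knocking out one
  monomer contact) cost less than the same mismatches scattered across
  quarters;
* a spacer longer than 2 nt breaks inter-dimer cooperation and severely
  reduces activity regardless of the rest of the site;
* an `AT` at the center of a `CWWG` core (A then T, strictly) is a
  positive feature, especially for non-canonical sites;
* a lone half site, or a three-quarter (**3Q**) site — three consecutive
  quarter sites, which can sit on either end of the full consensus — can
  still confer measurable, low-level responsiveness.

`p53scan` turns these regularities into a deterministic grading system
with five levels: grade 5 (highly functional) down to grade 1 (unlikely
functional), plus "no grade" for windows that merely resemble an RE.
The grade estimates transactivation potential, not consensus similarity.

## The penalty system

Every decamer position carries a mismatch label by distance from the
core: `A` for the invariant C and G of `CWWG` (positions 4 and 7), `B`
for the central `WW` (5 and 6), `C` for positions 3 and 8, `D` for the
outermost 1, 2, 9 and 10. For a spacer-free candidate site the total
penalty is

```
S = sum over mismatches of  weight(label) x m(quarter)
  + scatterSurcharge x max(0, nQuartersHit - 1)
  + spacerPenalty(spacer)
  - atBonus x (number of cores that are exactly "AT")
S = max(0, S)
```

where `m(quarter)` is 1 for external quarters, the internal-quarter
multiplier for Q2/Q3 of a full site, and additionally the 3Q multiplier
for internal quarters of 3Q sites. Two hard rules are checked before the
thresholds: more than three mismatches spread over three or more quarter
sites give **no grade**, and a spacer-free site whose only violations
are at most two label-D mismatches with all cores `AT` is grade **5**
outright. The thresholded grade is finally clamped by the long-spacer
cap (grade <= 2 whenever the spacer exceeds 2 nt) and by the class
ceiling (full 5, 3Q 3, half 2).

### Default magnitudes

The directional structure above is established experimentally; the exact
magnitudes are this package's calibration, shipped as a single
overridable YAML table (`inst/extdata/default_rules.yaml`):

| parameter | default | rationale |
|---|---|---|
| label weights A/B/C/D | 4 / 3 / 2 / 1 | strict ordering core -> periphery |
| internal-quarter multiplier | 1.5 | internal mismatches dominate equal-label external ones |
| extra 3Q internal multiplier | 1.25 | internal mismatches hit 3Q sites harder than full sites |
| scatter surcharge | 4 per extra quarter | see below |
| AT-core bonus | 1 (full) / 2 (3Q, half) | AT matters most for non-canonical sites |
| spacer penalties | 0, 2, 3, then 8 for 3-13 nt | 1-2 nt already costly; >2 nt breaks cooperation |
| grade thresholds | S = 0 -> 5; <=2 -> 4; <=5 -> 3; <=9 -> 2; <=14 -> 1; else none | ties resolve to the better grade |
| class ceilings | full 5, 3Q 3, half 2 | half sites are at best weakly functional |

The scatter surcharge deserves a note. With a multiplicative internal
penalty, a surcharge of 2 would make two core-adjacent mismatches
*grouped in an internal quarter* (1.5 x (4+3) = 10.5) cost more than the
same labels *scattered over the two external quarters* (4 + 3 + 2 = 9.5)
— inverting the grouped-versus-scattered regularity exactly where it
matters most. The default of 4 is the smallest integer surcharge that
preserves `grouped >= scattered` for every label multiset, quarter
assignment and site class (worst case: `{A,B}` grouped internally, 10.5,
versus scattered externally, 11); we verified this by enumeration over
all label multisets up to quarter capacity.

Penalties are sums of integers and the binary-exact factors 1.5 and
1.875, so grading is deterministic bit for bit; thresholds compare with
`<=`, resolving ties toward the better grade.

### Decisions where the evidence is open

* **"External positions" in the grade-5 exception** are taken to be the
  label-D positions (1, 2, 9, 10 of each decamer).
* **The AT bonus is strict**: only `A` then `T` qualifies; `TA`, `AA`,
  `TT` do not.
* **3Q sites accept no spacer**; a spaced 3Q has no experimental
  support and the search space would balloon.
* **The 3Q ceiling is 3** (configurable): perfect-AT 3Q sites grade
  above 2, but never compete with good full sites.
* **Half sites with a label-A or -B mismatch are not reported** at all
  (configurable): a half site with a damaged core is indistinguishable
  from background and would dominate output volume.

## The scanner

`scanSequence()` evaluates every window of every class: full sites at
each spacer 0–13, both 3Q arrangements, and half sites. Windows
containing any non-A/C/G/T character are skipped (the rules are defined
over ACGT only; treating N as a mismatch would invent evidence), and
soft-masked lowercase is uppercased.

The degenerate consensus is reverse-complement symmetric position by
position: the label map of `RRRCWWGYYY` is palindromic, internal
quarters map onto internal quarters, `AT` cores onto `AT` cores, and
the two 3Q arrangements onto each other. Consequently every
reverse-strand match coincides with a forward-strand match over the
identical interval with identical penalty, and the scanner enumerates
the forward strand only, reporting all calls on `+` — mathematically
identical to scanning both strands and collapsing each palindromic twin
pair.

Overlap resolution proceeds in three steps: identical-interval records
collapse to the best-scoring one; among mutually overlapping same-class
calls a greedy pass keeps the best by grade, then lowest penalty, then
smallest spacer, then leftmost start; and 3Q/half calls wholly contained
in a **strictly stronger** full-site call are suppressed as partial views
of it. Strictness matters: any perfect 3Q extends into some gradeable
full-site window (the added quarter's mismatches are confined to one
quarter, which never triggers the no-grade rule), so suppressing at
equal grade would make the scanner structurally unable to report 3Q
sites at all. A non-canonical site graded at least as high as its
full-site extension is an interpretation in its own right and is kept.

Coordinates are 1-based inclusive (`GRanges` convention) in memory and
in the TSV output; BED output is 0-based half-open as the format
requires.

## Null models and enrichment

Two sequence null models are implemented. **Local permutation**
shuffles bases within consecutive bins of 500 nt, preserving each bin's
base multiset exactly and hence the local GC structure — the right null
for promoter windows, whose GC content rises sharply near the TSS.
**GC-matched random sequence** draws i.i.d. bases at a fixed GC fraction
(default 0.44, the bulk human value) — the right null for comparisons
against arbitrary genomic region sets. Defaults are 10 replicate null
sets per analysis.

`enrichmentVsNull()` reports, per grade, the fold enrichment of RE
frequency over the null and a one-sided exact binomial tail probability.
The number of trials is defined as the number of **candidate windows**
evaluated by the scan (all classes, spacers and arrangements, N-free),
one total per scan shared across grades; counts are pooled over null
replicates rather than averaged, which is stabler at the low counts
typical of the high grades. A grade with zero null counts falls back to
a 0.5 pseudocount and is flagged in the result rather than silently
producing infinities. On data generated by the null model itself the
pipeline is calibrated: per-grade observed counts stay inside the
central binomial band of the pooled null frequency (the test suite
checks this end to end).

## Metaprofiles

`tssMetaprofile()` anchors each RE at its interval midpoint (no anchor
point is dictated by the model; the midpoint is the symmetric choice),
computes its position relative to the TSS of its window — windows from
`extractWindows()` are strand-oriented so upstream is always negative —
and histograms positions in 100 nt bins over `[-flank, +flank]`. The
overall histogram is normalized to a probability distribution (mass sums
to 1 under any bin width); per-grade curves use cumulative thresholds
(grade >= g) and are each normalized as their own density, so curve
shapes are comparable across grades with very different abundances.

## PWM comparison

`pfmToPwm()` converts a position frequency matrix into log2
probability-ratio weights using a multinomial model with a Dirichlet
conjugate prior: posterior `p(b, i) = (count + prior x background_b) /
(total + prior)`, entry `log2(p / background_b)`. Background defaults
to uniform and prior strength to 1 — neither is dictated by the data,
both are configurable, and the transform is cross-checked in the test
suite against the Biostrings reference implementation. Match scores are
normalized to `[0, 1]` by the column-extreme sums, so the column argmax
sequence scores exactly 1 and the argmin exactly 0. Sub-width sites
(3Q, half) are scored at their best alignment inside the matrix with
uncovered columns contributing zero (background): a partial site
therefore cannot reach 1 even when it matches its columns perfectly,
which reproduces the structural over-penalization of 3Q sites by
full-width matrices that motivates rule-based scoring in the first
place.

## The synthetic fixture generator

`buildFixture()` emulates the input geometry of a promoter-window
analysis: a set of windows (default 10 windows of 20 kb, i.e. ±10 kb
around a central TSS) of i.i.d. background at GC 0.44, optionally with a
piecewise-linear GC ramp toward the TSS (a test device for the
GC-confounding analyses, not a claim about real promoter composition),
into which `sampleREWithGrade()` plants sites of requested class and
grade by rejection sampling — every returned site verifiably re-grades
to its target. Planted placements are additionally verified against the
scanner in their local sequence context: background bases can extend a
planted site into an equally strong full-site call or spell an
overlapping equally good site, in which case the placement is re-drawn,
so the truth table is recoverable ground truth by construction.
Background collisions elsewhere in the windows are left untouched
(sanitizing them would distort composition); recovery checks match on
truth coordinates.

What the generator does **not** emulate: real promoter k-mer structure,
repeats, chromatin accessibility, or clustering of REs. Passing
planted-recovery and calibration tests therefore demonstrates the
correctness of the scanning and statistics machinery, not predictive
performance on real genomes.

## Validation scales

The shipped validation uses desk-scale problem sizes chosen to give the
statistics room without waste: oracle equivalence against brute-force
enumeration on 100 random 2 kb sequences (about 3.4 million candidate
windows); rule-direction properties on 1000 sampled sites each;
null-model calibration on 12 windows of 2 kb with 10 replicates;
planted enrichment recovery at 2x and 16x on 30-window fixtures. The
genome-scale analyses (whole-promoter maps, distal DNase enhancer
scans) are supported as inputs through `scanFasta()`,
`extractWindows()` and `mergeAndFilterDistal()` but are not part of the
test suite.

## Known limitations

* The default rule magnitudes reproduce every directional and
  categorical regularity above, but they are a reconstruction — tools
  trained on the full original transactivation compendium will differ
  in individual penalties, so grades should be compared within a rule
  table, not across tools.
* Interactions between nearby REs (clusters of half sites, full + 3Q
  composites) are not modeled; each call is scored in isolation.
* The binomial model treats candidate windows as independent trials;
  overlapping windows are positively correlated, so p-values at very
  high hit densities are anti-conservative. Fold enrichments are
  unaffected.
* Grading is defined over ACGT only; IUPAC ambiguity codes other than N
  are treated like N (window skipped).
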