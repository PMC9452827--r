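---
title: "Triage of exonic variants for splicing disruption: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of exonic variants for splicing disruption: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
library(dplyr)
```

## The problem

Exonic single-nucleotide variants can damage pre-mRNA splicing in two broad
ways: by weakening the donor (5'ss) or acceptor (3'ss) consensus that the
spliceosome recognises at the exon boundary, or by rearranging the exonic
splicing enhancer (ESE) and silencer (ESS) motifs through which SR proteins
and hnRNPs tune exon recognition. Either mechanism can cause the exon to be
skipped from the mature transcript, with consequences — in-frame internal
deletion or frameshift plus premature termination — that have nothing to do
with the amino-acid change the variant was originally annotated with.

`spliceshift` implements the desk half of a screen-then-validate workflow:
map catalogue variants onto transcripts, score the two disruption
mechanisms, filter to candidates, predict the protein consequence of the
skip, and quantify the exon-trap minigene readout used for validation.

## Coordinate model

Everything lives in CDS ("c.") coordinates: 1-based, closed intervals, with
c.1 the A of the start codon. Genomic coordinates, strand, and non-SNV
variants are deliberately out of scope — candidate tables in this field are
published in c. space, and a transcript-relative frame keeps the arithmetic
exact. Models may be *partial*: only the exons under study need spans.
Contiguity is enforced whenever two consecutively numbered exons are both
present, which turns the published annotations into a consistency check
rather than an assumption.

The signed within-exon location follows the reporting convention of
candidate tables: `offset5 = c_pos − c_start + 1`,
`offset3 = c_end − c_pos + 1` (so `offset5 + offset3 = length + 1`), and
the reported value is the smaller distance, positive from the 5' end,
negative from the 3' end, with ties reported as positive. A variant at the
last base of an exon is `−1`; "within 4 bases of the exon end" counts the
boundary base as distance 1.

`build_model_from_anchors()` inverts this: each annotated variant (exon
number, exon length, signed location) pins down its exon's span uniquely,
and disagreeing anchors raise an error naming both rows. The packaged
candidate fixture rebuilds this way into models whose re-located variants
reproduce every published location.

## Splice-site scoring

Two model kinds cover the common publication formats:

* **PWM (frequency matrix + background)**: score = per-position
  `sum(log2(w/b))`. Windows default to 3 exonic + 6 intronic nt for donors
  and 20 intronic + 3 exonic for acceptors, the conventions of the widely
  used scoring services; both are configurable. A zero weight at an
  observed base yields `-Inf`, which is the correct limit for a
  position treated as invariant.
* **k-mer score table**: an explicit window → score map, the distribution
  form of maximum-entropy models. Unknown windows are an error, not a
  default, because a silent 0 would masquerade as a real score.

The quantity reported for a variant is `100·(mut − wt)/wt`, rounded
half-away-from-zero to 2 decimal places; `delta < 0` flags potential site
loss. The percent change is undefined at `wt = 0` and errors rather than
returning an arbitrary value. Scores printed by external services (neural
network or maximum-entropy web tools whose internals are not
re-implemented here) can be supplied directly to `score_delta()`; the
package's own scorers exist for synthetic and user-supplied models.

## Motif deltas

A hit is a `(offset, motif)` pair. Because an SNV can only change windows
that overlap it, `motif_delta()` restricts the comparison to
variant-overlapping hits: hits present in wild type and absent in the
mutant are *broken*, the converse *gained*. When a substitution converts
one set member into another, that is one broken plus one gained hit — the
hit-list diff, not a net membership count. Overlapping occurrences of the
same motif count separately, and a motif present in two sets counts once
per set. The minimal complete window for a k-mer set is the variant
± (k − 1) nt, clipped at the exon; larger windows change nothing because
non-overlapping hits cancel.

No published ESE/ESS matrices are bundled (the service used for the
original annotations is proprietary); the packaged candidate table carries
its printed counts as trusted annotations, and the scanner serves synthetic
and user-supplied motif sets.

## The candidate filter

A variant is selected when **either**

1. `min(offset5, offset3) <= 4` (boundary proximity), or
2. `ese_broken + ess_gained > 5` (regulatory disruption, strict
   inequality).

The strictness of criterion 2 matters: a variant with a disruption sum of
exactly 5 at distance 4 is selected by proximity alone, and a sum-5 variant
deep in the exon is not selected. Both thresholds are `triage_params()`
arguments; the defaults reproduce the published screen, where all 14
candidates pass — 6 by proximity only, 8 by regulatory disruption only.
Decisions are monotone: moving a variant closer to a boundary or breaking
more elements can never deselect it. First/last-exon variants can be
dropped up front (`exclude_terminal = TRUE`) since an exon-trap construct
cannot assay them.

Only the two printed count types enter criterion 2; gained enhancers and
broken silencers are reported by `motif_delta()` but deliberately not
counted, matching the published rule.

## Skipping consequences

For a skipped exon of length L:

* `frame_preserved ⇔ L mod 3 = 0`; then `aa_lost = L/3` and the affected
  codon range is `ceiling(c_start/3) … ceiling(c_end/3)` — first and last
  codon *touched*. This convention reports the published ranges even when
  the exon starts mid-codon (the 129-nt exon starting at c.101 prints
  codons 34–77). The hybrid codon formed at a non-aligned in-frame
  junction is not translated (it would need flanking exon sequence);
  `aa_lost` is the deleted-codon-equivalent count.
* Otherwise the frame shifts from the anchor codon
  `A = ceiling(c_start/3)`. With full CDS sequence the first in-frame
  TAA/TAG/TGA at or after A is located and annotated `p.XaaA Yaafs*K`
  with `K = termination − A` — the anchor keeps its amino acid when the
  shift begins inside it, so this matches HGVS counting where the first
  *changed* residue is position 1. Without sequence, the consequence is
  reported frame-only with termination honestly `NA` rather than guessed.
  A shifted tail with no stop sets a `runs_through` flag.

## Minigene quantification

Exon-trap products are `backbone + L` (inclusion) and `backbone`
(exclusion), with the 263-bp backbone as default. Densitometric exclusion
is `100·lower/(lower + upper)`, scale-invariant and undefined only when
both bands are zero. Group comparison is an unpaired pooled-variance
(Student's) two-sample t-test, two-sided — pooled rather than Welch
because that is the named test in this assay literature and replicate
numbers are tiny (n = 3 by default). Degenerate inputs use explicit
conventions: both groups constant and equal gives t = 0, p = 1; constant
but different gives p = 0.

Classification: **complete** skipping when the inclusion band is
undetected in the mutant (mean share of lane intensity below a 1%
detection fraction, configurable — densitometry itself, e.g. gel-image
processing, is out of scope and intensities arrive as numbers);
**partial** when both products appear and mutant exclusion is
significantly higher at α = 0.05; **none** otherwise. Note the measured
exclusion percentages of a real assay are wet-lab outcomes; the packaged
table of published percentages exists for formatting and plotting, not as
something the package can predict.

## Synthetic data and what it shows

`make_transcript()` builds contiguous, sequence-bearing transcripts with
motifs planted verbatim (collisions are errors, compatible overlaps
allowed) and synthetic intron flanks of selectable consensus strength for
junction-window scoring. `make_variant_cases()` draws random SNVs and
records ground truth *constructively*: the boundary distance from the
chosen position, motif breaks/gains by direct substring enumeration (a
separate code path from the scanner under test), and frame arithmetic from
exon lengths. `make_assay_replicates()` adds clipped Gaussian noise to a
true exclusion percentage; its default of 3 replicates mirrors the assay
design, and a noise SD of a few percentage points is typical of gel
densitometry.

The recovery tests run the real pipeline over these cases and demand exact
(100%) agreement with the constructed labels — over 1,000 cases in the
acceptance suite, on a transcript whose exon lengths echo the assayed
exons (140/111/129/87/152/108 nt) and with dense 60+60 hexamer alphabets
so motif-change events are common. What this shows: the mapping, scanning,
filtering and frame arithmetic are mutually consistent and match
independent enumeration. What it does not show: performance on real human
sequence composition, real motif databases, or real splicing outcomes —
the filter's biological sensitivity/specificity is a property of the
published screen, not of this implementation.

Problem sizes throughout the test suite (hundreds of property cases,
1,000 recovery cases, 10^4 replicates for the noise-model check) were
chosen so the whole suite runs in about a minute on a laptop core while
still exercising every branch.

## Numerical and design choices

* Rounding of reported percentages is half-away-from-zero at 2 d.p.,
  chosen to reproduce printed values exactly (R's `round()` half-to-even
  would not).
* Ties in the signed location report the 5' distance; verified against
  every published row.
* Two printed inclusion sizes (for the 140-nt and 108-nt exon constructs)
  disagree with backbone + length arithmetic by 2 and 44 bp; the tests
  pin the seven consistent sizes and flag these two as caption
  discrepancies instead of silently reconciling them.
* Two printed positive acceptor-site percent changes have no underlying
  scores published, so their inputs are unrecoverable; they ride along in
  the fixture but are excluded from numeric checks.
* The filter accepts externally supplied counts or live scanner output;
  the provenance difference is visible in the input table the caller
  passes, not hidden.

## Limitations

* Exonic SNVs only: no intronic offsets, indels, multi-transcript genes or
  genomic coordinates.
* No branch-point or intronic regulatory scoring; no RNA secondary
  structure; no NMD modelling.
* External predictors' internal models are not reproduced; where only
  their printed outputs exist, those are inputs.
* Protein-domain annotation of deleted ranges (which transmembrane helix
  is lost) is descriptive text from protein databases, outside the
  package's scope.
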