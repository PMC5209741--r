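---
title: "Screening cloned ITS sequences for pseudogenes and recombinants"
author: "ITSscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cloned ITS sequences for pseudogenes and recombinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ITSscreen)
```

## The problem

The nuclear ribosomal DNA cistron (18S--ITS1--5.8S--ITS2--26S) occurs in
hundreds to thousands of tandem copies per genome. Concerted evolution
normally homogenises these repeats, which is what makes the internal
transcribed spacer (ITS) usable as a phylogenetic marker. When concerted
evolution is incomplete -- under hybridization, polyploidy, or simply slow
homogenisation -- an individual carries divergent paralogs side by side:
functional copies, decaying pseudogenes, and occasionally chimeric copies
produced by recombination (natural or PCR-mediated). Cloned ITS amplicons
sample this hidden variation one repeat at a time, and before any
phylogenetic use the clones must be sorted into functional copies,
pseudogenes, and recombinants.

ITSscreen implements that triage as a reproducible pipeline. A pseudogene is
recognised by relaxed constraint: elevated substitution rate, reduced GC
content (methylation-driven C&rarr;T and G&rarr;A deamination), lesions in
the conserved angiosperm 5.8S motifs, and loss of the conserved 5.8S
secondary-structure helices. A recombinant is recognised by a sharp
discontinuity in its similarity to two candidate parents, formalised here as
a maximum chi-squared (MaxChi) breakpoint test.

## Region delimitation

`delimitRegions()` places the ITS1 / 5.8S / ITS2 boundaries by local
alignment of three anchors (reference 5.8S, 18S tail, 26S head) against each
clone, scored +1 match / -1 mismatch / -2 per gap position. The 5.8S
interval is the aligned span of the reference 5.8S; the spacers are what
lies between the anchors. Two guards make this robust on decayed copies:

* the 5.8S anchor must reach 50% identity over its aligned span **and**
  contribute at least 25 matching bases -- a short spurious local hit
  cannot delimit a sequence, while a pseudogene 5.8S with a sizeable
  deletion still can;
* a flank anchor is accepted only at &ge; 70% identity over &ge; 60% of its
  length and on the correct side of the 5.8S span; otherwise the region is
  extended to the sequence end and a truncation flag is set.

With the prescribed gap penalty the local alignment will not bridge
deletions whose cost exceeds the flanking match gain (roughly &ge; 50 bp
inside the 5.8S), so for such extreme copies the recorded 5.8S span covers
only the longer retained segment; the motif scanner still reports the
missing motifs through its own global alignment. Coordinates are 1-based
inclusive internally (the Bioconductor convention); the partition TSV is
written 0-based half-open (BED convention) and printed reports are 1-based.

## The three evidence streams

**GC flags.** `gcContent()` is plain (G+C)/(A+C+G+T) with ambiguity codes
excluded on both sides. "Significantly lower GC than co-sample clones" is
operationalised in `flagLowGC()` as *median minus delta*: the baseline for a
region is the median GC of the co-sample clones whose motifs and helices are
clean (two passes, so decayed copies do not drag the baseline down), and a
clone is flagged when it falls more than `deltaPP` (default 2 percentage
points) below it. Samples with fewer than three clones fall back to the
global clean median. The default of 2 pp was chosen as roughly four times
the within-class GC standard deviation produced by functional-copy drift at
realistic clone divergence, so flags essentially never fire on functional
copies while decayed copies (which in published evidence tables sit 5-20 pp
low) are caught.

**Motifs.** The three conserved angiosperm 5.8S motifs are
M1 = `CGATGAAGAACGTAGC`, M2 = `GAATTGCAGAATCC`, M3 = `TTTGAACGCA`. A clone
5.8S containing the exact motif anywhere is conserved, irrespective of
context. Otherwise the clone is globally aligned to the reference 5.8S and
the motif window is the alignment image of the motif's reference span:
substitutions are reported 1-based within the motif ("nt-7,12"), positions
falling on clone gaps are missing ("missing 4-16", "all missing"). Anchoring
the window on the reference span avoids spurious distant matches in heavily
decayed copies. Ambiguity codes count as mismatches (conservative and
deterministic).

**Helices.** Foldability of helices B4-B8 is tested as a deterministic
base-pairing feasibility check at the published forced positions
(B4: 45/105/3, B5: 48/61/3, B6: 69/96/3, B7: 110/118/3,
B8: 119/142/4 + 126/135/3, in reference 5.8S coordinates; block (i, j, k)
forces i..i+k-1 to pair with j..j-k+1). A helix is foldable ("X") iff every
forced pair maps through the alignment to two non-gap clone bases forming a
Watson-Crick or G·U pair. The diagnostic question is binary -- can the
conserved stem form at all -- so no thermodynamic energy model is needed,
and the check is exactly reproducible. Ambiguity codes never pair. Below
40% alignment identity the pattern is reported all "-" with a warning flag
(in practice that identity is only reached by non-5.8S input).

**Verdict.** `classifyClones()` ORs the three streams: one GC region flag,
one non-conserved motif, or one unfoldable helix makes a pseudogene, and
`reasons` records each trigger. The OR-with-minimum-1 default follows the
observation that published evidence tables contain GC-only pseudogenes
(conserved motifs, all helices foldable, low GC); `minCriteria` can raise
the bar. The verdict is monotone by construction: additional lesions can
only add reasons.

## Diversity statistics

`countSiteClasses()` counts variable columns (&ge; 2 distinct unambiguous
bases) and parsimony-informative columns (&ge; 2 bases each in &ge; 2
sequences); percentages print to one decimal. `pairwiseDiversity()` returns
k (mean pairwise differences) and Pi (per-site); the default *complete
deletion* policy drops every column containing a gap or ambiguity, the
common default of desk tools for this statistic, and makes
Pi = k / lengthUsed an exact identity (asserted to 1e-12 in the tests);
pairwise deletion is available by argument. Ambiguity codes are always
treated as missing, never as partial matches. `classContrast()` computes
both statistics per region and per class (F/P), the layout of the published
functional-versus-pseudogene diversity tables. `simpleIndelCode()` converts
each distinct gap (start, end) into one presence/absence character, with
gaps that contain or overlap (but do not equal) a character's span scored
"?"; an exclusion mask for ambiguously aligned regions is the user's
responsibility, as automatic detection is out of scope.

## Recombination scan

For a child and two candidate parents, the informative sites are the
columns where the parents differ and the child matches exactly one of them.
`maxChiBreakpoint()` slides a split over the informative-site sequence and
scores each with the chi-squared of the 2x2 table (left/right half-window x
matched parent); with equal half-windows of w sites this collapses to
`2w(a-b)^2 / ((a+b)(2w-a-b))`. Significance comes from permuting the
match labels (1000 by default), with the conservative (1+c)/(1+P)
estimator; the breakpoint estimate is the alignment column midway between
the informative sites flanking the best split.

Two parameters deserve a note:

* the similarity-profile window (30 bp) and the MaxChi half-window are
  different quantities; the latter is measured in informative sites
  (default 10 per side, clipped to half the informative-site count).
  A small half-window keeps candidate splits covering the whole alignment
  and the breakpoint localisable; larger windows trade localisation for
  power.
* fewer than 8 informative sites is reported as "insufficient signal"
  rather than tested.

`scanRecombinants()` applies this per clone: candidate parents are the
other distinct clones, ranked by identity to the child (ties by ID), pairs
enumerated deterministically and capped (default 200). The observed MaxChi
statistic is computed for every pair, and the permutation test is spent on
the single best-statistic pair per child -- permuting every pair would
multiply runtime by the pair cap for no change in the selected report.
Bonferroni correction across children is applied and both raw and corrected
p-values are reported. Natural and PCR-mediated recombination are not
distinguishable from sequence alone and no such field is reported.

**Null calibration.** The permutation null is checked against triplets in
which the child is an independent sister lineage of the two candidate
parents -- the situation a clean clone actually faces in a scan, under
which the informative-site labels are exchangeable. (A child cloned
directly from one parent is a degenerate null: nearly every informative
site matches that parent, the statistic is permutation-invariant, and the
p-value is identically 1; it can never produce false positives, but it is
useless for calibration.) On 200 such triplets the rejection rate at
alpha = 0.05 is about 0.02-0.05 -- slightly conservative, as expected from
the discrete statistic and the permutation estimator.

## The synthetic generator

`simulateCloneSet()` generates what the screen assumes real cloned data
look like; its defaults are the package's reference study conditions, not
tuning knobs.

* **Unit**: `makeReferenceUnit()` builds an 18S-tail(25) + ITS1(230) +
  5.8S(160) + ITS2(210) + 26S-head(25) unit; the 5.8S carries exact
  M1/M2/M3 at offsets 6/76/145 with every forced pair Watson-Crick by
  construction and GC nudged into 54-56%; spacers sit at ~62% GC. These
  match the length and composition ranges of functional plant ITS units.
* **Lineages**: each sample ancestor diverges from the root at
  `lineageRate` (0.03/site; spacer scale for congeneric species), with the
  5.8S at a tenth of that and motif/forced-pair sites fully protected --
  the purifying-selection assumption the screen itself rests on, and the
  reason functional 5.8S diversity is an order of magnitude below spacer
  diversity.
* **Clones**: functional copies add `baseRate` (0.005/site) on
  unconstrained sites. Pseudogenes mutate at 5x that rate over *all* sites
  with a CpG/GpC deamination bias (`cpgTransitionBias` = 0.8 of in-context
  substitutions are C&rarr;T/G&rarr;A), so GC strictly decreases in
  expectation; with probability 0.4 each they additionally receive an
  explicit motif lesion and a forced-pair disruption (recorded
  position-by-position in the truth table so classifier reasons can be
  checked criterion-by-criterion); deletions arrive as Poisson(0.2) per
  clone with 1 + Geometric (mean 8 bp) lengths, plus an optional large
  50-140 bp deletion mode (off by default). Deletions only, no insertions:
  every reported length variant in decayed plant ITS copies of this kind is
  a deletion, and it lets the generator emit the *exact* alignment (gaps at
  deleted ancestral positions) without an external aligner.
* **Recombinants** (5% of clones) splice two sample ancestors at a
  uniform breakpoint in the interior, recorded in the truth table.
* Class counts are deterministic (`round(n * fraction)`), the seed is
  mandatory, and identical seeds give byte-identical FASTA/TSV output.

What the generator does **not** emulate: alignment error (its alignment is
exact by construction), insertions and microsatellite slippage, within-array
gene conversion, PCR chimeras with more than one crossover, and base-calling
noise. Passing the recovery tests therefore demonstrates that the screening
logic is correct under the decay model, not that real data of any particular
taxon will be this clean; on real clones the alignment and reference choice
dominate the error budget.

## Numerical and design choices

* Reporting precision follows the published table conventions: GC to two
  decimals, site-class percentages to one decimal.
* All alignments (anchors, 5.8S mapping) use match +1 / mismatch -1 over
  the full IUPAC alphabet, so ambiguity codes never score as matches.
* Ties in the MaxChi split profile resolve to the leftmost maximizing
  split; parent-pair ranking ties resolve by clone ID -- all outputs are
  deterministic at fixed seed.
* Degenerate inputs are statuses, not crashes: absent motifs, unfoldable
  patterns, "insufficient signal" triplets, NA diversity cells for
  single-member classes.
* Problem sizes used by the test-suite and acceptance computations --
  ten 100-clone runs for classifier recovery, 50 planted chimeras, 200
  null triplets, 50 oracle alignments up to 20 x 500 -- were chosen as the
  smallest sets at which the binomial noise of the measured rates is well
  inside the asserted margins.

## Known limitations

* The packaged reference set is synthetic. It is constraint-satisfying by
  construction and ideal for validating the machinery, but real studies
  must supply a published functional reference of the study group, and
  boundary placement on real data may differ by a few bp from any
  particular published delimitation.
* The GC flag is a within-sample contrast; a sample consisting *entirely*
  of uniformly decayed copies yields no flag (the motif/helix streams still
  fire).
* MaxChi assumes one crossover per child; mosaic chimeras are out of
  scope, as is any phylogenetic-incongruence recombination test.
* The helix check is feasibility, not stability: a helix of marginal free
  energy that can still pair its forced positions counts as foldable.
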