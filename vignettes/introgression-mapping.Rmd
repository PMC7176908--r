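---
title: "Mapping a binary trait locus from backcross introgressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a binary trait locus from backcross introgressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

A qualitative trait — here, whether a barley line is amenable to
*Agrobacterium*-mediated transformation — segregates in a population built
by repeatedly backcrossing a donor line into a recurrent (recalcitrant)
cultivar. After a few backcrosses each line carries only one or two short
donor chromosome segments in an otherwise recurrent genome. If the trait is
controlled by a single donor locus, the segment containing it must be
present in every line showing the trait and absent from every line that
does not. `introscan` turns that logic into a tested pipeline:

1. **Triage** the SNP-array panel against the two parents, keeping only
   markers with opposite homozygous parental calls.
2. **Encode** progeny calls as graphical genotypes: `A` (recurrent
   homozygote), `B` (donor homozygote), `H` (heterozygote).
3. **Call segments**: maximal runs of donor-carrying calls per sample.
4. **Contrast**: find marker runs whose donor state co-segregates
   perfectly with the phenotype, and delimit the minimal region from the
   boundary recombinants.
5. **Annotate**: intersect the candidate interval with a GFF3/BED gene
   annotation.

Because the procedure is exact set logic on a binary trait, there is no
QTL model, no LOD score and no multiple-testing correction; the
permutation check offered in the test-suite is diagnostic only.

## Marker triage

With two inbred parents assayed on a fixed array, markers fall into five
categories, applied in this precedence order: monomorphic (both parents
the same homozygote), single-parent (a call for only one parent; markers
with no parental call at all are folded into this "insufficient parental
information" class with a warning), unmapped (no position on the physical
map), parent-heterozygous, and retained. Only the partition sums are
observable downstream, so the precedence choice is a documented
convention rather than a scientific claim. Retained markers are the only
ones that can distinguish parental origin, and all later stages operate on
them in physical-map order. Coordinates are 1-based inclusive bp
throughout; conversion to BED's 0-based half-open convention happens only
in the BED reader/writer.

## Segments and interruption tolerance

A donor segment is a maximal run of `B`/`H` calls along a chromosome.
Missing calls are absence of evidence: they never interrupt a run and
never support one. A recurrent-homozygous call breaks a run — unless it is
an *isolated* interruption: `max_interruptions` (default 0) is the longest
gap of consecutive `A` calls a segment may absorb, and a run may absorb
any number of such isolated gaps. We chose gap-length rather than a total
per-segment budget deliberately: isolated discordant calls are the
signature of independent genotyping errors, and their number grows with
segment length while their gap length does not. With per-call error rate
`e` and `n` samples, the chance that two erroneous `A` calls land on
*adjacent* markers (defeating tolerance 1) is of order `(e/2)^2` per
marker pair, which is negligible at array error rates, whereas two
isolated errors anywhere in a long segment are common enough to matter.

Segment bounds are reported at the supporting markers (inner bounds);
reasoning about flanking recombination lives in the contrast stage, which
reports outer bounds as well.

## Phenotype contrast and minimal-region delimitation

A marker is **concordant** when every non-missing call in the
transformable class carries donor material (`B` or `H`; heterozygotes are
accepted because observed carrier lines may be heterozygous across the
region — a strict homozygous mode is available for recessive traits) and
every non-missing call in the non-transformable class is `A`. Classes with
more than `max_missing_fraction` (default 0.1) missing calls make the
marker **non-evaluable**, which is reported distinctly from
**discordant**: insufficient evidence must not be allowed either to break
a candidate run or to support one. The default of 0.1 reflects typical
array no-call rates; raising it trades robustness of runs against the
risk of resting a candidate on very few calls.

Candidate regions are maximal runs of concordant markers (non-evaluable
markers pass through; discordant markers break), ranked by
concordant-marker count and then physical span. The top region is then
refined: each transformable sample's donor span overlapping the region is
computed with `call_segments`, and the **inner bounds** are the
intersection of those spans — so the samples with the shortest donor
contributions, the boundary recombinants, define the region and are named
in the output. The **outer bounds** are the nearest markers beyond the
inner bounds at which any transformable sample shows an `A` call (or the
chromosome's terminal markers). Both intervals are always reported: the
concordant markers define the smaller span, the flanks define the larger
one, and published region sizes may follow either convention, so gene
counting defaults to the outer interval while both are written out.

Degenerate inputs are handled explicitly: a class with no samples is an
error; a single transformable / single non-transformable pair is accepted
as a documented limit case; an empty span intersection (impossible unless
concordance was computed on different data) is an error rather than a
silent empty region.

## The simulator

The synthetic-data module exists so that every stage can be validated
against known truth, and its defaults emulate the study design the
pipeline was built for:

* **Genome**: 7 chromosomes of 600 Mbp, 600 cM genetic length in total,
  with linear bp-to-cM scaling per chromosome. These are deliberately
  coarse stand-ins for the barley physical map — sufficient for interval
  recovery, not for modelling recombination-rate heterogeneity.
* **Meiosis**: Haldane model — Poisson crossover counts with mean
  `length_cM/100`, uniform positions, no interference, no obligate
  chiasma. The no-interference choice is the simplest standard model and
  is adequate for testing interval recovery; it slightly inflates the
  frequency of close double crossovers relative to real meiosis.
* **Breeding scheme**: donor x recurrent cross, `n_backcrosses` rounds of
  backcrossing (default 1 for simulation studies; the motivating program
  ran BC1–BC4), then screened selfing generations. The phenotypic screen
  at the 5H proxy locus operates only at selfing rounds (F2 onward,
  mirroring visual screening of F2 grains): homozygous-donor plants always
  pass, heterozygotes pass with probability
  `selection_misclassification_rate` (default 0.1 — the screen is known to
  be imperfect, and selected lines heterozygous at the proxy locus are
  observed), homozygous-recurrent plants never pass. A lineage whose
  screen rejects every candidate grain is restarted; if restarts are
  exhausted an explicit extinct-lineage error names the generation.
* **Trait**: dominant by default — one donor allele at the causal 2H locus
  makes a line transformable. Lines, not embryos, carry the phenotype;
  per-embryo stochasticity appears only in assay counts, as
  `Binomial(n_embryos, te_if_carrier)` with defaults of 50 embryos and a
  13% per-embryo success probability for carriers.
* **Array panel**: the default category counts reproduce a 44,040-marker
  panel with 31,925 monomorphic, 2,535 single-parent, 45 unmapped and 79
  parent-heterozygous markers, leaving 9,456 informative. Genotyping noise
  is per-call: corruption to a uniformly chosen different token with
  `genotyping_error_rate`, then no-calls with `missing_rate` (both default
  0; mapping simulations use 0.5% error to probe robustness).

What the simulator does **not** model: recombination interference and
hot/cold spots, segregation distortion away from the selected locus,
marker clustering along the physical map, intensity-level array artefacts
(error is i.i.d. per call), and any embryo-level biology. Passing tests
therefore show that the set logic, bookkeeping and noise tolerance of the
pipeline are correct under the stated statistical model — not that real
barley data meet that model.

## Problem sizes and numerical choices

Validation uses study-scale defaults chosen to mirror the motivating
design while staying comfortably reproducible on a laptop: mapping
simulations breed lines until at least 10 transformable and 3
non-transformable exist, genotype them at 500 markers per chromosome, and
repeat over 50 seeded studies; backcross-genetics checks use 500 lines
per generation; oracle-equivalence checks run 1,000 random rows.
Stochastic checks compare sample means to expectations within three
standard errors. All randomness flows from explicit seeds; identical
configuration plus seed gives bit-identical populations, matrices and
reports (timestamps aside).

Two open choices were resolved as follows. Whether "polymorphic"
additionally required a progeny call-rate filter is unknowable from the
published accounting, so no progeny-based filter is applied — triage uses
parental calls and map placement only. And because it is equally unstated
whether published region sizes are measured flank-to-flank or
marker-to-marker, both intervals are always emitted rather than guessing.

## Limitations

* The contrast rule is exact co-segregation; a single misphenotyped line
  destroys the true region. The interruption and missingness tolerances
  guard against genotyping noise, not phenotyping error.
* With very few non-transformable lines, long runs elsewhere in the
  genome can be concordant by chance; ranking by marker count mitigates
  but does not eliminate this, which is why the boundary samples and
  marker lists are reported for inspection.
* Candidate-gene counts depend on the annotation supplied; the package
  treats gene identifiers and confidence labels as opaque.
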