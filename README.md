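# introscan

Introgression mapping of binary traits in backcross populations.

`introscan` is for geneticists who have bred a trait from a donor line
into a recurrent cultivar by repeated backcrossing, genotyped the lines on
a biallelic SNP array, and want to know **which donor segment carries the
trait**. The motivating use case is mapping a barley transformability
locus: after backcrossing a transformable mutant into a recalcitrant
elite cultivar, each line retains only one or two donor segments, and the
causal segment is the one present in every transformable line and absent
from every non-transformable one.

## The method

For retained markers (opposite homozygous parental calls), progeny calls
are encoded as graphical genotypes `A`/`B`/`H` (recurrent homozygote /
donor homozygote / heterozygote). A marker is *concordant* when

* every non-missing call in the trait-positive class is `B` or `H`
  (dominance-compatible; a strict homozygous mode covers recessive
  traits), and
* every non-missing call in the trait-negative class is `A`, and
* each class has at most a fraction `max_missing_fraction` of missing
  calls (otherwise the marker is *non-evaluable*, which neither breaks
  nor supports a run).

Maximal runs of concordant markers are candidate regions, ranked by
marker count. The top region is refined by interval intersection: with
donor-carrying spans `[s_i, e_i]` over the trait-positive samples `i`,
the inner bounds are `[max_i s_i, min_i e_i]` — the boundary recombinants
attaining them are reported — and the outer bounds are the nearest
flanking markers at which any trait-positive sample is `A`. Genes are
then counted in the interval from a GFF3/BED annotation.

A meiosis-level simulator (Poisson crossovers, mean `length_cM / 100`,
uniform positions; screened backcross pedigrees; five-category array
panels with per-call noise) generates populations with known truth, so
the whole pipeline is validated end to end without any external data.

## Worked example

```r
library(introscan)

# a complete simulated study: breeding, genotyping, phenotypes, truth
study <- simulate_mapping_study(seed = 7)
table(study$phenotypes$class)
#> non_transformable     transformable
#>                12                10

res <- map_study_locus(study)
res$top
#> <candidate_region> chr2H inner [400,453,059, 483,849,501]
#>                          outer [397,715,071, 488,606,177] (79 markers)
res$top$boundary_samples
#> $left:  "BC1F2-014"   $right: "BC1F2-012"
round(study$truth$causal$bp)   # the planted locus...
#> 455000000
res$contains_causal            # ...lies inside the reported outer interval
#> TRUE
```

The candidate region sits on the causal chromosome; the two boundary
samples are the recombinant lines whose introgression ends delimit it.
Marker triage of a full-size array panel and the transformation-efficiency
statistic work the same way:

```r
map   <- build_map(barley_chromosomes(), 6300, seed = 1)
panel <- build_marker_panel(panel_config(), map, seed = 2)
triage_panel(panel)$report
#> Marker triage: 44040 markers evaluated
#>   monomorphic    31925
#>   single_parent   2535
#>   unmapped          45
#>   parent_het        79
#>   retained        9456

compute_te(200, 26)   # % embryos yielding >= 1 transgenic plant
#> 13
```

A subcommand CLI wrapping these functions ships in
`inst/cli/introscan.R` (`simulate`, `triage`, `encode`, `segments`,
`map-locus`, `annotate`, `assay-stats`, `pipeline`), e.g.

```sh
Rscript inst/cli/introscan.R pipeline \
  --genotypes raw.tsv --map map.tsv --parents Optic,M1460 \
  --phenotypes phenotypes.tsv --genes genes.gff3 --out results/
```

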