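---
title: "Methods: SNP filtering, parentage and clone identification for exome-capture GBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP filtering, parentage and clone identification for exome-capture GBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpanel)
```

## The problem

Conifer breeding programmes increasingly genotype trees with exome-capture
genotyping-by-sequencing (GBS): 120-bp probes enrich sequencing libraries
for exonic fragments, reads are aligned and variant-called, and the result
is a VCF with per-sample, per-allele read depths at hundreds of thousands
of candidate SNPs. Before those genotypes can drive pedigree
reconstruction, clone identification or genomic selection, three problems
must be solved:

1. **Quality control.** Sequencing error, low read depth and probes that
   co-capture paralogous loci all masquerade as polymorphism. Conifers
   offer a unique control: the megagametophyte, a haploid maternal seed
   tissue. A haploid sample that appears heterozygous is a direct flag for
   paralog co-capture or artifact.
2. **Marker selection.** Parentage analysis wants a small panel of common,
   independent, well-behaved markers, not the full rare-variant-skewed SNP
   set.
3. **Relationship analysis.** Trio parentage by exclusion counting, and
   clone (ramet) identity by pairwise genotype mismatch, with an honest
   account of how panel size and missing data erode both.

`radpanel` implements this pipeline end-to-end, driven by a synthetic-data
generator that emulates the study design the analyses assume, so every
stage is testable without access to sequencing data.

## Data model

Tabular data are tibbles throughout (sample sheets, panels, reports, pair
tables). The two large grids are matrix-backed S3 containers with tidy
accessors (`as_tibble()`, `tidy()`):

* `variant_table` — per-site metadata (probe, gene, alleles, site quality)
  plus an integer array of per-sample per-allele read depths (`AD`). The
  VCF `QUAL` column stands in for the genotyping provider's proprietary
  quality score.
* `genotype_matrix` — called genotypes as unordered allele multisets
  (phase is never represented): two allele-index matrices plus a per-sample
  ploidy vector. Haploids carry a single allele.

VCF input is parsed with `vcfR`; output is written by the package (plain
text, `AD:DP` FORMAT, `PROBE`/`GENE` INFO keys) and round-trips exactly.

## Genotype calling

`call_genotypes()` applies the depth-and-ratio rules of the final
filtering pipeline:

* total depth `< 10` (configurable): the data point is missing;
* haploid samples: the single deepest allele (lowest allele index on a
  tie);
* diploid samples: heterozygous for the two deepest alleles when the
  minor-read ratio `d2 / (d1 + d2)` is at least 0.1.

The treatment of a *failed* heterozygote (minor reads present but below
ratio) is genuinely ambiguous: the minor observation can be read as
sequencing error to be corrected, or as grounds to distrust the data
point altogether. Both behaviours are exposed:
`low_ratio_action = "demote"` calls homozygous-major (our calling
default); `"missing"` discards the point (what the final pipeline's allele-ratio
filter stage, `filter_final_49k()`, uses).
A pure homozygote (zero minor reads, ratio 0) is never discarded — removing
every homozygous data point cannot be the intent of a `< 0.1` ratio rule.
All thresholds are strict: a value exactly at a `< T` threshold survives.

## The two filtering pipelines

`filter_pilot_80k()` removes, in printed order: probes heterozygous in
more than 5% of megagametophytes; SNPs with site quality `< 10`; SNPs with
mean depth `< 5`; SNPs with more than two observed alleles; SNPs whose
population-mean alt/(ref+alt) read ratio falls outside `[0.1, 0.9]` (that
mean is an allele-frequency estimate, so the stage removes near-fixed
sites).

`filter_final_49k()` reorders the logic so that *data quality is
established before biological filters run*: mean depth `< 10` first; then
extra (2nd/3rd) alternate alleles are dropped when no individual reads
them above depth 10 (the SNP is reclassified biallelic) while SNPs with a
deeper extra allele are routed to a separate true-triallelic table; then
the two per-data-point stages (depth, allele ratio); then probe-level
haploid heterozygosity, monomorphism over all non-missing calls, and a
MAF ≥ 0.03 floor over the unrelated reference cohort. An extra allele at
depth exactly 10 is covered by neither printed inequality ("< 10" drop,
"> 10" true triallelic); it is dropped, the conservative reading.

Two reporting conventions: the report keeps
a raw `None` row ahead of the filter stages, and because the per-point
stages change data points rather than site counts, the report tracks both
(`n_snps` and `n_data_points`). Haploid heterozygosity is defined on the
pre-call depth vector — at least two alleles with at least two reads
each — because single-read alternate observations are overwhelmingly
sequencing error at these error rates.

## Marker selection for pedigree reconstruction

`select_pedigree_snps()` applies, in order: call rate `> 0.75`, observed
MAF in `[0.35, 0.5]`, a Hardy–Weinberg chi-square goodness-of-fit p-value
`> 0.10`, then greedy pruning so every retained pair has squared genotypic
correlation `r² < 0.02` (composite LD measured as the squared Pearson
correlation of 0/1/2 dosage vectors over pairwise-complete individuals).

The HWE statistic is computed by hand with one degree of freedom (three
genotype classes, minus one, minus the estimated allele frequency) and no
continuity correction; `stats::chisq.test` cannot express the
estimated-parameter df reduction.

Two numerical choices deserve note:

* **Pruning order.** Several pruning orders satisfy the pairwise bound.
  We iterate candidates by descending call rate and discard any
  SNP correlated at `r² ≥ 0.02` with an already-kept SNP: deterministic,
  and it favours complete data.
* **LD cohort.** Call rate, MAF and HWE use the unrelated reference
  cohort, but `r²` uses *all* diploid samples. At `n ≈ 135` the bound
  `r² < 0.02` sits inside the null sampling distribution of `r²` between
  unlinked SNPs (`E[r²] ≈ 1/n`; about 10% of unlinked pairs exceed 0.02),
  so pruning on the cohort alone saturates the pool at a few dozen SNPs
  regardless of how many markers qualify. With the full sample set the
  null exceedance collapses and pruning removes only genuinely correlated
  pairs. Note that strong family structure in a small simulated study
  re-inflates null `r²`; the desk-scale experiments in this package
  therefore draw their random panels from the marginal-criteria pool
  (sites are simulated unlinked, so there is nothing real for the LD stage
  to remove there).

`random_panels()` draws seeded, uniform, without-replacement panels
(default 60 panels of 110 SNPs — enough markers to tolerate missing data);
`truncate_panels()` keeps each panel's first *k* SNPs so reduced panels
are nested by construction.

## Exclusion-analysis parentage

For a candidate parent pair, the compatible offspring genotypes are the
unordered sums of one gamete from each parent — at most 4 ordered gamete
combinations (het × het). A panel SNP where all three genotypes are
non-missing and the offspring genotype is not in the compatible set is an
*exclusion*; SNPs with any missing genotype are skipped and do not count
as comparable. The candidate pair with the fewest exclusions is the
assignment; raw counts are ranked (a rate mode would matter only when
comparable counts differ sharply between pairs, which the dropped-sample
floor already guards against). Ties are reported as ambiguous, never
silently broken. Self-pairs are optional and off by default.

Internally, exclusion counts over all `C(117, 2)` candidate pairs are
accumulated with gamete-possibility indicator matrices and BLAS
`tcrossprod` — for each offspring-dosage class `o ∈ {0, 1, 2}` the count
of compatible SNPs between candidates `a` and `b` is a sum of inner
products of "can transmit ref" / "can transmit alt" indicators — with a
per-prefix-block accumulation so all truncation sizes of a panel cost one
pass. The slow per-trio path (`trio_exclusions()`, multiallelic-safe) is
the reference implementation and the two are cross-checked in the tests.

`reduction_experiment()` tallies, per panel and truncation size, unique
correct assignments (`true`), unique wrong ones (`false`), ties
(`ambiguous`), and offspring dropped because their own non-missing calls
fall below a floor (default half the panel size), mirroring how a
low-call-rate individual is excluded rather than misassigned.

## Clone identification

`pairwise_mismatch()` compares unordered genotype multisets: a SNP is
comparable when both calls are non-missing, and any difference (including
het vs either homozygote) is one mismatch — no allele-sharing partial
credit. Pairs with fewer than 80 of 110 comparable SNPs are excluded; for
other panel sizes the floor scales proportionally. Pairs are classified
from the sample sheet as ramet / full-sib / parent-offspring / unrelated;
pairs in any other relationship (half-sibs, cross-family comparisons) are
labelled `other` and excluded from the four printed classes.

For each panel the *gap statistic* is the minimum full-sib mismatch
percentage minus the maximum ramet percentage; a larger gap discriminates
clones from their closest relatives more safely. `rank_panels_by_gap()`
reports this gap (plus the parent-offspring and unrelated analogues) for
every panel, sorted.

Under Hardy–Weinberg proportions at alternate-allele frequency `p`, two
unrelated individuals mismatch at a SNP with probability
`1 − (p²)² − (2pq)² − (q²)²`; the tests check simulated unrelated pairs
against this closed form, and check the kinship ordering of class means
(ramet < full-sib < unrelated, parent-offspring < unrelated).

## The synthetic-data generator

`simulate_study()` emulates the study design the analyses assume:

* **135 unrelated founders** drawn under Hardy–Weinberg proportions at
  per-site frequencies from a configurable MAF spectrum. The default is
  `0.5 × Beta(0.05, 3)`, which puts ~93–94% of sites below MAF 0.03 — the
  heavily rare-variant-skewed spectrum exome capture discovers in this
  population. A uniform option serves the panel-selection experiments.
* **Two full-sib families** (82 and 93 offspring by default, the two
  mapping populations) by Mendelian segregation, sites unlinked
  (recombination maps are out of scope).
* **104 haploid megagametophytes**, one uniformly drawn maternal gamete
  each.
* **Ramet copies** (default: 2 extra copies of each family parent) that
  share the source's true genotype exactly; only depth and error are
  re-rendered.
* **Read rendering**: total depth per data point is negative binomial with
  mean 60X and dispersion `size = 5` (overdispersion consistent with a
  reported 6X–204X range around a median of 66X); each read draws an
  allele from the true genotype and substitutes to another listed allele
  with probability 0.002 (sequencing chemistries report 0.11–0.28%);
  probes flagged paralogous (5%) mix half their read mass from a duplicated
  latent locus with its own fixed genotype, which is what makes haploids
  look heterozygous; a small fraction of sites (2%) list a spurious third
  allele reachable by error. Missingness arises *only* through the depth
  threshold at calling time; the characteristic depth-vs-missingness curve
  of real GBS data is consistent with that mechanism, but it is an
  assumption.

What the generator deliberately does not emulate: linkage and
recombination, selfing and inbreeding, batch effects, index hopping,
reference-bias in alignment, and locus-specific capture efficiency.
Passing tests therefore demonstrate correctness of the algorithms under
the stated generative model, not robustness to every artifact of real
exome-capture data.

`perturb_genotypes()` adds call-level genotype error and missingness for
robustness experiments, bypassing the read model.

## Problem sizes and determinism

The packaged experiments run at desk scale: 2,000 simulated sites for the
filtering study and a 704-site, 135-founder, 2 × 90-offspring study for
the parentage and clone analyses (60 panels of 110 SNPs, truncations
110…50), sizes chosen so the full suite and the acceptance script complete
in minutes on one CPU while keeping every Monte-Carlo check comfortably
inside its 3-standard-error band. All randomness flows from explicit
seeds: a `sim_config` seed fixes the whole study, `random_panels()` takes
its own seed, and identical seeds reproduce outputs byte-for-byte
(asserted in the tests). R's Mersenne-Twister default RNG is used
throughout.

## Known limitations

* The proprietary site-quality score of the original genotyping provider
  is not re-derived; the VCF `QUAL` column is its documented stand-in.
* Linkage analysis (marker clustering into linkage groups) is out of
  scope; simulated sites are unlinked.
* The exclusion engine's fast path assumes biallelic sites (which the
  final pipeline guarantees); multiallelic genotypes are handled only by
  the per-trio reference path.
* With two large full-sib families and 135 founders, composite-LD pruning
  at `r² < 0.02` is noise-limited (see above); pool sizes at this scale
  are not comparable to those attainable from a large, diverse genotyped
  population.
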