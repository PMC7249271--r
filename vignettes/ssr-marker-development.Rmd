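---
title: "Microsatellite marker development from genome-skim assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite marker development from genome-skim assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrskim)
```

## The problem

Population-genetic work on non-model plants still leans heavily on
microsatellites (simple sequence repeats, SSRs): co-dominant, cheap to score,
and informative at fine geographic scales.  Developing them from scratch is
where the effort goes.  Genome skimming — shallow shotgun sequencing of a few
individuals, assembled into fragmentary contigs — yields more than enough
sequence to mine thousands of candidate repeats, design primers around them,
and even pre-screen which candidates are likely to be polymorphic *before*
ordering a single oligo, by comparing the assemblies of the skimmed
individuals in silico.

`ssrskim` implements that desk half of the marker-development pipeline as
composable, testable functions, plus the population-genetic panel used to
characterise the markers once genotyped: allele counts, private alleles,
observed heterozygosity ($H_o$), unbiased expected heterozygosity ($H_s$),
exact Hardy–Weinberg tests, and the pairwise index of association with a
permutation null.

## Repeat detection

`scan_sequence()` finds every **maximal perfect run** of a di-, tri- or
tetranucleotide motif.  Maximal means one more full motif copy in either
direction breaks perfection; perfect means no interruptions, the only model
under which "this individual carries two more repeat units than the
reference" is a well-defined statement, which the downstream polymorphism
screen depends on.  Runs are attributed to their shortest period — an
$(AT)_6$ tract is a dinucleotide locus, never $(ATAT)_3$ — and split at
ambiguous bases.

Motifs are named by a canonical class representative: the lexicographically
smallest string among all rotations of the motif and of its reverse
complement (`canonical_motif()`), so $(AG)_5$ read on either strand, in any
frame, is one locus class.  Default minimum run length is 4 repeats for
every class.  This is the same threshold the retention filter applies later
(and marker panels routinely contain 4-repeat loci), so detection must admit
them; it is configurable per class.

The scanner is validated against a brute-force oracle that simply tries
every motif of every class at every position with regular expressions; the
two agree exactly on seeded 5-kb contigs.

## Primer design and the retention filter

Around each repeat, every primer window of 18–27 nt in a 150-bp flank is
enumerated and scored, and left/right windows are paired combinatorially
(`design_primer_pairs()`).  Scoring:

* **Melting temperature** by nearest-neighbor thermodynamics with the
  unified dinucleotide parameter set, duplex-initiation terms and the
  entropy salt correction $0.368\,(N-1)\ln[\mathrm{Na}^+]$, at 50 nM total
  primer.  The default effective monovalent concentration is 200 mM — PCR
  annealing buffer, i.e. ~50 mM K$^+$ plus the stabilising effect of
  ~1.5 mM Mg$^{2+}$ — which places typical 50%-GC 20-mers near 60 °C.  At a
  naive 50 mM the same primers sit near 54 °C and a 60 °C-centred penalty
  would reject everything; the defaults are chosen so the scale on which
  penalties are computed is the scale at which primers actually anneal.
  The implementation agrees with an independent implementation of the same
  published parameter table to 10^-6^ °C.
* **Per-primer penalty**: $w_{tm}\,|T_m - 60| + w_{len}\,|L - 20| +
  w_{gc}\max(0, |gc - 0.5| - 0.1)$ with weights 1/°C, 1/nt and 10 — zero at
  the optimum, strictly increasing in each deviation (a primer3-like shape).
* **Pair penalty**: the two primer penalties plus $0.5\,|\Delta T_m|$ per
  °C of melting-temperature mismatch.

`filter_pairs()` then applies the published retention rule verbatim: pair
penalty < 1.7, each primer penalty < 0.8, $|\Delta T_m|$ < 2 °C, both
primer 3′ ends **more than** 20 bp from the repeat, and product size within
89–301 bp.  The penalty, temperature and distance bounds are strict, as
printed; the product-size interval is read as closed — the source does not
say, and an amplifiable 89-bp product is an odd thing to exclude on a
boundary technicality.  Because penalty models differ between designers, the
package pins the *filter logic* in its tests, not absolute penalty values;
the weights are configurable and documented.

`design_markers()` keeps the single lowest-penalty surviving pair per locus
(ties: smaller product, then leftmost).  When two repeat regions end up
sharing one amplicon, both loci keep the pair and are suffixed `a`/`b` in
coordinate order — compound loci are treated as independent markers, which
is also how they behave at the genotyping bench.

## In-silico polymorphism screening

For each marker and each skimmed individual, `screen_markers()`:

1. finds the best local alignment of the individual's contigs to the
   marker's reference contig (Smith–Waterman, match +1, mismatch −1, gap
   open −2, extend −1, both strands, score floor 30; one best hit per
   individual, ties by score then subject coordinate);
2. anchors the two 20-bp reference flanks adjacent to the repeat inside the
   individual's contig, allowing ≤ 2 substitutions per flank — tolerant of
   skim-level sequencing error while keeping the repeat boundaries
   unambiguous — and counts the maximal perfect motif run between the
   anchors (`count_repeats()`);
3. applies the retention rules (`classify_marker()`): calls with ≥ 5
   alignment mismatches are invalid; markers with reference repeat count
   < 4 are dropped; a marker is `POLYMORPHIC` the moment one valid call
   differs from the reference repeat count, `MONOMORPHIC` when all valid
   calls agree with it, `INSUFFICIENT` when no valid call remains.

Gaps inside the repeat region are deliberately *not* counted as mismatches
for the validity rule: an indel there is precisely a repeat-count change,
the signal being screened for.  Heterozygous assemblies that produce two
contig haplotypes per individual are not modelled — the first-best hit
stands for the individual.

## The diversity panel

All statistics work from a tidy genotype table (two integer allele columns
per locus, alleles as fragment sizes in bp, missing calls fully missing):

* $H_o$: fraction of non-missing individuals with two different alleles.
* $H_s = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$: the small-sample
  unbiased gene diversity.  This exact form is forced by arithmetic: an
  all-heterozygous biallelic locus in 23 individuals must print 0.511 and
  the 22-of-23 configuration 0.510, which the variant subtracting an
  $H_o$ term does not reproduce.  Note the estimator attains 1.0 exactly
  when all $2n$ allele copies differ.
* Private alleles: an allele counted for a population iff it occurs in no
  other population; undefined (NA, with a warning) for a single population.
* Hardy–Weinberg: biallelic loci get the exact conditional test — the
  distribution of the heterozygote count given allele counts is enumerated
  in full, and the two-sided p-value sums all outcomes no more probable
  than the observed one (probability ordering, the standard convention;
  stated here so reimplementers can match).  Loci with more alleles get a
  Monte-Carlo permutation of the $2n$ allele copies (default 999 reps, +1
  correction so $p > 0$).  Monomorphic loci return exactly 1.
* Index of association: per individual pair, $d_j \in \{0,1,2\}$ counts
  allele differences at locus $j$; $I_a = V_O/V_E - 1$ with
  $V_O = \mathrm{var}(d_a + d_b)$, $V_E = \mathrm{var}(d_a) +
  \mathrm{var}(d_b)$, and $\bar r_d$ is the correlation of $d_a$ with
  $d_b$.  The permutation null shuffles one locus's genotypes across
  individuals.  Duplicated loci give $\bar r_d = 1$ by construction — a
  useful positive control and, with `paralogy_flag()`, part of the
  diagnostic story below.

Missing data are handled by per-locus pairwise deletion — each cell of the
panel reports its own $n$ — matching how such panels quote per-cell sample
sizes.  `diversity_table()` adds pooled `"All"` rows; whether those pool the
individuals or average the populations is genuinely ambiguous in published
panels, so both are offered (`all_method = "pooled"`/`"mean"`, default
pooled).  Summary rows use the sample SD ($n-1$).

**Paralogy.**  In a genus with ancient whole-genome duplication, a "locus"
can be two diverged paralogs co-amplifying.  The fingerprint is a locus
where essentially every individual is the *same* heterozygote.
`paralogy_flag()` flags loci with $H_o = 1$ and one identical heterozygous
genotype in ≥ 95% of non-missing individuals; flagged loci are annotated,
never removed, because the right treatment (re-scoring, exclusion,
duplicate-aware models) is a judgement call for the analyst.

## Simulators, and what passing tests mean

Every input the pipeline consumes can be generated with known truth
(`simulate_reference()`, `simulate_individuals()`,
`simulate_genotype_matrix()`), all pure functions of `(config, seed)`.
Defaults mirror the targeted study design: 50 contigs with one planted
repeat each, seven skim individuals with repeat-count shifts drawn from
$\{-1{:}0.2,\ 0{:}0.5,\ +1{:}0.2,\ +2{:}0.1\}$, and six populations of
23–30 diploids at 1.23% missingness under strong selfing.  Genotypes use
the inbreeding-coefficient model — heterozygosity $2pq(1-F)$ at a biallelic
locus — the simplest structure that reproduces panels dominated by $H_o$
values of 0 and 1; it was chosen over explicit selfing pedigrees, which add
machinery without adding tested behaviour.  The single base flanking each
planted repeat is constrained so the planted run cannot extend, keeping the
truth table exact; spurious background repeats are allowed and make
detector *precision* (as opposed to recall) a measured, not asserted,
quantity.

The simulators emulate substitution noise and repeat-length mutation; they
do not emulate assembly error, chimeric contigs, allelic dropout, or
electrophoretic size binning.  Tests passing on simulated data therefore
demonstrate the algorithms are correct under their stated model, not that
wet-lab genotyping artefacts are handled.

### Numerical and calibration choices

* Exact-test calibration is checked on 500 null loci of 100 diploids at
  $p = 0.5$: large $n$ keeps the conditional distribution dense enough that
  the discrete test's rejection rate sits near the nominal 0.05 (its exact
  null rejection rate at this design is 0.045), inside binomial 99% bounds.
  At skim-study sample sizes (20–30) the exact test is visibly
  conservative, as all discrete exact tests are.
* Association calibration uses two independent loci in 200 individuals,
  50 replicates, 199 permutations each — sizes at which $\bar r_d$'s null
  spread is well under the 0.15 acceptance radius while the whole suite
  stays inside a few minutes on one CPU.
* Parameter recovery (allele frequencies to ±0.05, $H_s$ to ±0.03 of
  $2pq$ at $n = 500$, $F = 0$) is asserted on estimates averaged over five
  replicate simulations: at $n = 500$ the worst-case standard error of
  $\hat H_s$ is ~0.015, so a single-draw ±0.03 band would fail a correct
  implementation in roughly one seed in five, while the replicate-averaged
  band is ~4 standard errors wide.
* Ties in probability orderings are absorbed with a $10^{-10}$ relative
  tolerance so floating-point noise cannot flip a p-value across an
  enumeration boundary.
* Degenerate inputs: empty FASTA, half-missing genotype calls, non-integer
  alleles, loci with < 40 bp flanks, groups with $n = 0$, monomorphic loci
  in association tests — each has a defined, tested behaviour (error,
  warning-plus-empty, or NA) documented on the function.

### Problem sizes used by the test suite

Oracle equivalence runs on 100 seeded 5-kb contigs; primer enumeration is
checked exhaustively on a 300-bp fixture (~0.8M pairs); screening loops use
8–12 contigs of 500–600 bp across 4–7 individuals; the statistical
calibrations use the sizes above.  These were chosen as the smallest sizes
at which each property is actually informative.

## Known limitations

* Perfect repeats only; compound-with-interruption and imperfect repeat
  models are out of scope (penta-/hexanucleotide classes are accepted by
  the canonicaliser but untested).
* No hairpin/dimer thermodynamics or multiplex-compatibility scoring in
  primer design; absolute penalties from other designers are not
  reproducible and not attempted.
* The screen genotypes assemblies, not reads; within-individual
  heterozygosity at a marker is invisible to it.
* No $F_{ST}$/AMOVA/clustering, no null-allele estimation, and p-values
  are reported raw, without multiple-testing correction across loci.
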