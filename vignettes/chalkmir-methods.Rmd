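---
title: "chalkmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chalkmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`chalkmir` re-implements a small RNA-seq analysis of the developing rice
grain (caryopsis) under high daytime temperature (HDT) stress versus
control (CDT), across multiple genotypes differing in grain chalkiness.
The pipeline has four statistical/algorithmic cores:

1. **Novel MIRNA discovery.** Reads are mapped to a genome (ungapped,
   at most one mismatch, both strands), merged into candidate loci by a
   deterministic gap-merge caller, and candidates overlapping known
   MIRNA annotations are removed. Each remaining candidate's precursor
   window is folded, the miRNA\* of its most abundant read is derived
   from the structure with 2-nt 3' overhangs, and the mature/star
   duplex must show at most 5 mismatched positions and at most 3
   asymmetric-bulge nucleotides.
2. **Processing precision.** For each candidate and library, the
   fraction of hairpin-overlapping reads matching the mature, the star,
   or their 1-nt end variants. Matures of 20–22 nt require a ratio of
   at least 0.75; 23–24 nt matures require 0.90. A candidate needs at
   least 10 exact mature reads *and* the ratio threshold in the same
   library, in at least 4 libraries.
3. **Quantification.** Unique reads are attributed to a mature/star
   catalog by best hit (no gaps, at most 1 mismatch, at most a 1-nt
   extension/truncation at each end), each read counted once with its
   full multiplicity; counts are normalized to counts per million
   clean reads (CPM), using the total clean library size.
4. **Differential expression.** A common negative-binomial dispersion
   is estimated by conditional maximum likelihood; per-genotype
   HDT-vs-CDT contrasts use the conditional exact test; the
   genotype-by-treatment interaction uses an NB log-linear model with a
   likelihood-ratio test (1 df); regulated sets are compared across
   genotypes (shared in all, chalk-group-exclusive, genotype-specific).
   Significance is raw p < 0.05, no multiple-testing adjustment, which
   is the convention of the analysis being reproduced; a BH column can
   be added by users from the returned p-values.

Supporting arithmetic (percent trait change under stress, Pearson
correlation with the `cor.test` t-distribution convention, and qPCR
2^-ddCT relative expression) is in the `pheno_qpcr` functions.

## The synthetic world

Real sRNA data for this design is not desk-scale reproducible, so the
package carries a first-class generator whose defaults *are* the
emulated study design:

* 5 genotypes × (CDT, HDT) × 3 replicates = 30 libraries;
* 30 planted MIRNA hairpins in a 200-kb random genome (GC 0.44);
* mature lengths peaked at 21 nt with a secondary 24-nt class;
* per-locus, per-library counts NB with mean 200 and dispersion
  `phi = 0.1` (`var = mu + phi mu^2`), multiplied by a log-normal
  library-size factor (`sdlog = 0.2`) and, under HDT, the locus's
  planted fold change;
* dicing precision 0.95: the complement of reads have each end shifted
  independently by ±1 nt (±2-nt shifts at one tenth that rate);
* 20 background clusters tiling 24-nt-biased reads uniformly over
  280-bp intervals — siRNA-like true negatives for the precision
  filter.

Planted hairpins have fully paired stems with 2-nt flanks on each arm,
an 8–12-nt loop, and mature/star duplexes with 2-nt 3' overhangs by
construction. Three G:U wobble pairs are planted in each stem: wobbles
keep the duplex fully paired (G:U is paired in all scoring here) but
break the exact reverse-complement palindromy of a pure Watson–Crick
stem, which would otherwise let every arm read cross-map antisense to
the opposite arm and duplicate each locus on the other strand — an
artifact real stems do not show. Hairpins are re-sampled until they
pass the package's own duplex criteria, closing the loop between
generator and discovery filters.

What the generator does **not** emulate: sequencing error, adapter
contamination, quality-score structure, multi-mapping repeat families,
expression heterogeneity across loci, and isomiR distributions beyond
the two-end shift model. A green end-to-end test therefore establishes
that the pipeline's filters recover planted signal and reject uniform
siRNA-like background at realistic depths — not that they would
reproduce any particular study's locus list on real tissue.

## Numerical and design choices

* **Coordinates.** Internally 1-based inclusive — the IRanges
  convention used by every container in the R genomics stack — and
  1-based inclusive GFF3 on disk. Converters to 0-based half-open
  (`gff_to_zero_based()`) are provided and involution-tested.
* **Folding.** The built-in folder is a base-pair-maximizing Nussinov
  dynamic program (Watson–Crick + G:U, minimum loop 3 nt,
  pseudoknot-free, deterministic outer-first traceback), implemented in
  C++. It is a stand-in for a thermodynamic folder: the annotation
  criteria tested here depend on the duplex pairing pattern, not free
  energies. Structures from any external folder can be supplied as
  `.dbn` files wherever a structure argument is accepted.
* **Duplex defect counting.** A duplex alignment column that is not a
  base pair counts as one mismatched position; an interior loop with
  `gA` and `gB` unpaired nucleotides on the two strands contributes
  `max(gA, gB)` mismatched positions, of which `|gA - gB|` are
  asymmetric-bulge nucleotides. The terminal 2-nt 3' overhangs are
  outside the scored region. This column-wise convention is the only
  one that is simultaneously symmetric in (mature, star), guarantees
  `asym <= mismatches`, and can realize all the boundary cases the
  criteria distinguish (counting nucleotides on both strands forces
  `mismatches - asym` to be even, which cannot separate a (6,3) from a
  (5,3) case). The two caps are applied conjunctively (<=5 AND <=3);
  the literal "or" reading — which would accept a 10-mismatch duplex
  with 3 bulges — is available via `literal_or = TRUE`.
* **Star derivation.** The star spans the partners of the mature
  shifted to give both strands 2-nt 3' overhangs
  (`star_start = pt[mature_end - 2]`, `star_end = pt[mature_start] + 2`
  on a paired stem, with nearest-paired-position fallback across
  bulges). On a perfect stem the derivation is an involution.
* **Mapping.** The production route hashes genome substrings per read
  length and looks up each read and its single-substitution variants;
  a sliding-window scan route exists for small genomes and
  verification, and both are checked against a Biostrings
  pattern-matching oracle in the tests. Exact hits suppress 1-mismatch
  hits per read; multi-mapping reads contribute their full count to
  every best-hit location (the common sRNA practice; fractional
  weighting was considered and left out as no test depends on it).
* **Exact test.** Counts are equalized to the geometric-mean library
  size as continuous pseudo-counts; group sums are rounded for the
  conditional test. Conditioned on the total, the NB conditional
  distribution is free of the mean, so the two-sided p-value is the
  sum of outcome probabilities no larger than the observed one (with a
  1e-10 relative tie tolerance). `phi = 0` reduces to the
  conditional-binomial (Poisson) limit. This equalization is simpler
  than the reference package's quantile adjustment, so p-values on
  real data approximate rather than duplicate it. log2 fold changes
  use a prior count of 0.5 on the rescaled per-library means
  (configurable).
* **Dispersion.** Common dispersion only, by conditional maximum
  likelihood summed over features and groups, optimized on the log
  scale over [1e-6, 5]; boundary optima report the Poisson limit. No
  tagwise/trended shrinkage — the simplest model consistent with the
  analysis reproduced.
* **Interaction.** NB log-linear model (`~ genotype * condition`,
  offset log clean size, fixed common dispersion) fitted by IRLS;
  LRT against the no-interaction model on 1 df. Rows that fail to
  converge within 50 iterations report `NA`. The GLM-LRT form was
  chosen over a pairwise contrast of exact tests because the
  interaction is a contrast of contrasts, which the exact test does
  not condition on; this is labeled, not asserted, as the original
  analysis' parameterization.
* **Attribution ties.** Best hit minimizes (mismatches, total end
  offset) lexicographically; remaining ties go to the
  lexicographically smallest entry name, making attribution
  independent of catalog input order. A read is never split across
  entries. The per-library >=10-mature-read support is per-library by
  default (`pooled_support = TRUE` pools it), since the source
  protocol does not state which was used.
* **Degenerate inputs.** Empty pileups give an undefined ratio and an
  automatic fail; all-zero features give p = 1 and log2FC = 0;
  all-zero matrices give dispersion 0 with a warning; zero clean sizes
  are an error for CPM.

## Known limitations

* The folder maximizes pairs, not stability: on random background
  sequence it finds dense pairings, so the duplex criteria alone do
  not separate MIRNAs from siRNA clusters — the precision filter does
  (by design, mirroring the annotation practice this package encodes).
* The exact test's rounding of equalized group sums introduces
  discreteness for very low counts.
* The gap-merge cluster caller is a stand-in; loci from any external
  caller can be supplied via GFF3.
* Reported log2FCs on real data will approximate, not duplicate, the
  reference count-model package's values (different normalization
  internals); the package's own tests validate against enumeration and
  simulation oracles instead.
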