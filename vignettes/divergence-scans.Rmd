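---
title: "Qst–Fst divergence scans: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qst–Fst divergence scans: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmetab)
```

`popmetab` asks two coupled questions about a crop that moved through
evolutionary stages — wild ancestral, intermediate/feralized, cultivated:
which genomic regions differentiated beyond neutral expectation between
consecutive stages, and which metabolites diverged more than those neutral
markers allow. This vignette is the package's own account of the models it
fits, the knobs that matter, what the synthetic cohorts do and do not
emulate, and the numerical conventions adopted where the method leaves room.

## Genotype model and diversity statistics

Genotypes are haploid: the species is selfing, accessions are treated as
single sequences, and homozygous diploid VCF calls collapse to the same
representation. Heterozygous calls are rejected by default
(`read_vcf_genotypes(..., het = "error")`) because every statistic below
assumes one allele per accession per site; an explicit `het = "major"`
escape hatch recodes them to the site's major allele with a warning.

For a group of $n$ sequences over $L$ analysed SNP sites:

* nucleotide diversity $\pi = \sum_{i<j} d_{ij} / \binom{n}{2} L$ with
  $d_{ij}$ the count of mismatching sites for pair $(i,j)$;
* Watterson's estimator $\theta_W = S / (a_n L)$, $S$ the number of sites
  segregating in the group and $a_n = \sum_{i=1}^{n-1} 1/i$;
* MAF, the per-site frequency of the least frequent **observed** allele
  (0 for sites monomorphic within the group);
* PIC $= 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ over the group's
  allele frequencies.

Both $\pi$ and $\theta_W$ are normalized per analysed SNP site, not per
genome base pair: a filtered SNP panel retains no information about
invariant sites, and the magnitudes this produces (roughly 0.1–0.35 per
site in realistic panels) are only comparable between groups analysed over
the same site set.

## Per-SNP AMOVA Fst and the permutation neutrality filter

For a pair of groups, each polymorphic SNP gets a one-level analysis of
molecular variance on 0/1 allele-mismatch distances. With group sizes
$n_1, n_2$, $N = n_1 + n_2$, the sums of squared distances reduce to allele
counts, and the expected-mean-square estimators give
$\hat\sigma_W^2 = \mathrm{SSD}_W / (N - 2)$ and
$\hat\sigma_B^2 = (\mathrm{MS}_B - \hat\sigma_W^2) / n_0$ with
$n_0 = N - (n_1^2 + n_2^2)/N$ for two groups. Then
$F_{st} = \sigma_B^2 / \sigma_T^2$. Conventions:

* sites monomorphic across the analysed pair are excluded up front;
* a negative $\hat\sigma_B^2$ is truncated to 0 *before* the ratio; a site
  with zero truncated total variance gets $F_{st} = 0$;
* per-SNP distances are haplotype mismatches (the haploid formulation);
  no diploid Weir–Cockerham estimator is provided;
* the multi-locus stage-level Fst (`global_fst`) sums **untruncated**
  components over loci and forms one ratio. Per-locus truncation plus
  ratio-saturation make the arithmetic mean of per-SNP Fst a biased summary;
  the component-sum ratio is the standard multi-locus estimator and is what
  the analytical island-model expectation (`expected_amova_fst()`) predicts.

The neutrality filter permutes accessions across the two groups. One shared
block of `n_perm` permutations (default 20,000) is applied to all SNPs: the
null — exchangeable group labels — is identical for every SNP, and sharing
the block makes the scan tractable at full permutation counts. Per SNP,
$p = (1 + \#\{F_{st}^{perm} \ge F_{st}^{obs}\}) / (n_{perm} + 1)$; the
add-one rule keeps $p > 0$ at finite permutation counts. SNPs with
$p < \alpha$ (default 0.01) are discarded as selection outliers; the
smallest discarded observed Fst is reported as the implied cutoff. No
multiple-testing correction is applied across SNPs — the scan is a filter,
not an inference, and correcting would keep more near-outlier SNPs in the
"neutral" set rather than fewer. The "Fst value of a neutral SNP" used
downstream is operationalized as the **mean** per-SNP Fst over the neutral
set (`neutral_fst_reference()`), with a quantile option; a single neutral
SNP would be underdetermined.

Sliding-window Fst uses the same 0-based half-open window grid as the
similarity scan (below); window means are plain averages over member SNPs,
empty windows are omitted, and sweep windows are those at or above the
empirical `quantile` (default 0.95, i.e. top 5%) of window means, computed
with linear interpolation between order statistics (R's default type-7
quantile; the method's convention is not otherwise pinned down, and ties are
flagged inclusively with $\ge$).

## Gene pools and genomic similarity

A group's gene pool takes, at every site, the majority allele within the
group — minority variants are treated as errors, never replaced by the
reference base — with exact ties broken by a seeded uniform draw so pools
are reproducible. Similarity between two pools in a window is the fraction
of sites with identical consensus alleles. Windows span 150 kb, step 75 kb,
are anchored at position 0 of each chromosome (the method does not describe
edge handling; the final partial window is kept if it passes the SNP
filter), windows with $\le 10$ SNPs are removed (strictly: only
$\ge 11$-SNP windows survive) and windows with similarity $\ge 0.95$ are
retained. The three pairwise comparisons share one grid, so retained windows
partition into the 7 cells of a Venn diagram keyed by
chromosome:start:end; because a window retained in two comparisons is one
genomic region but two (window, comparison) pairs, both totals —
per-comparison sums and merged distinct coordinates — are reported.

## Qst estimation and the divergence call

Metabolite abundances are log2-converted (a hard domain error on
non-positive values) and replicates are averaged per accession before any
variance decomposition; the within-group component is therefore the
between-accession variance of accession means, not the replicate-level
variance. This choice is switch-free by design: the replicate layer measures
technical noise, which belongs in neither $\sigma_B^2$ nor the denominator
of Qst. The decomposition is method-of-moments on the one-way layout
(pooled within-group variance; $\hat\sigma_B^2 = \max(0, (\mathrm{MS}_B -
\mathrm{MS}_W)/n_0)$ with the standard unbalanced $n_0$), which reproduces
the mixed-model answer for balanced designs without an iterative fitter —
the test suite cross-checks one instance against an `lme4` REML fit. Then

$$Q_{st} = \frac{\sigma_B^2}{\sigma_B^2 + 2\sigma_W^2},$$

undefined (NA) when both components are zero.

The 99% CI comes from a stratified bootstrap: accessions are resampled with
replacement within each group — replicates travel with their accession —
and Qst is recomputed per resample; percentile bounds at $(1-\ell)/2$ and
$1-(1-\ell)/2$. Percentile intervals can exclude the point estimate under
skew; that is expected behaviour, not a bug. Undefined resamples are
skipped and counted. A metabolite is **divergent** iff its whole interval
exceeds the neutral reference: `ci_lo > reference`, strictly — an interval
touching the reference is not called. No multiple-testing correction is
applied across metabolites, matching the screen's design.

## What the synthetic cohorts emulate

The generator's defaults are the package's reference study conditions:
three groups labelled Wb-NE / Wb-T / Cb-C with 7/9/9 accessions (a 25-
accession "pure" panel), 5000 SNPs over 7 chromosomes of 5 Mb, and
metabolites in 3 replicates per accession.

* **Genotypes** follow a Balding–Nichols island model: ancestral frequency
  $p \sim U(0.05, 0.95)$ (the support avoids monomorphic draws, mirroring a
  post-filter SNP panel), group frequency
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, Bernoulli accession alleles, no
  missing calls. The per-group drift defaults $F = (0.10, 0.18, 0.30)$ were
  chosen once, from the closed-form AMOVA expectation, to give pairwise
  stage Fst of 0.142 (Wb-NE vs Wb-T) and 0.240 (Wb-T vs Cb-C) — the two
  differentiation levels the analysis is designed around — and
  simultaneously a decreasing diversity gradient across the three groups.
* **Metabolites**: per metabolite, a baseline $\mu \sim N(10, 1)$ on the
  log2 scale, group effects, accession noise $N(0, \sigma_W^2)$ and
  replicate noise at 5% of $\sigma_W^2$ (technical variance is not
  separable from biological variance in the motivating design, so it is
  kept small and configurable). Group effects are drawn Gaussian and then
  **standardized so the realized between-group variance component equals
  $\sigma_B^2$ exactly**. With only two or three groups, leaving the
  realized component random would give it chi-square noise on one degree of
  freedom, and the recorded "true Qst" would describe the average draw
  rather than the cohort actually emitted; standardizing makes the ground
  truth exact per metabolite, which is what parameter-recovery testing
  needs. By default 30% of metabolites are divergent with $\sigma_B^2 = 2,
  \sigma_W^2 = 1$ (true Qst 0.5).
* **Btr loci**: diagnostic indel records (1-bp `GC`→`G`, 11-bp
  `GGCAACGTCTTC`→`G`) planted per a genotype plan, placed by default on
  chromosome 3H (the true genomic coordinates are configuration inputs, not
  constants of the package).

What the cohorts deliberately do **not** emulate: linkage disequilibrium
and recombination maps (sites are independent), demographic history
(bottlenecks, migration, admixture), genotyping error or missingness,
metabolite-metabolite correlation, and non-Gaussian abundance distributions.
Passing tests on these cohorts therefore validate the estimators and their
calibration under the assumed variance structure — they do not certify
behaviour under LD, admixture or heavy-tailed metabolomes.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; VCF positions
  (1-based) and GFF3 intervals (1-based inclusive) are converted at the I/O
  boundary, and BED output is native 0-based half-open.
* A single master seed fans out to per-stage child seeds (`fan_seeds()`),
  so each stage is independently reproducible and reordering stages does
  not change results.
* Degenerate cases have pinned conventions: Fst of a site with zero total
  variance is 0; Qst with both components zero is NA and excluded from
  calls; a Welch comparison of two zero-variance samples with equal means
  returns $t = 0, p = 1$; gene-pool ties are seeded random; haplotype
  labels are assigned by descending carrier count, ties and unobserved
  haplotypes in lexicographic order, and the full 2^k table is always
  emitted so labels are auditable.
* Problem sizes in the shipped tests and the acceptance script are scaled
  to desk size as the package's own test design: 2000-SNP null panels with
  2000 permutations, 500 metabolites per Qst truth level, 500 bootstrap
  resamples for the specificity study. The method's full-scale defaults
  (20,000 permutations, 1000 resamples) remain the function defaults.

## Known limitations

* Only two-group (pairwise) AMOVA is implemented; hierarchical designs
  (regions within groups) are out of scope.
* The haploid mismatch formulation means diploid outbred data are not
  supported beyond the homozygous-call path.
* The permutation filter controls the per-SNP type-I rate, not FDR; the
  neutral set is a filter output and inherits the add-one resolution floor
  of $1/(n_{perm}+1)$.
* Bootstrap CIs are percentile, not BCa; at 7–9 accessions per group they
  under-cover slightly, which makes the divergence call conservative in the
  direction of fewer false positives.
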