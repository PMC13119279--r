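---
title: "Methods: diversity statistics and core-collection construction in germcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics and core-collection construction in germcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`germcore` reconstructs, as a tested and reusable pipeline, the standard
workflow for characterising a resequenced crop germplasm panel and
distilling it into a core collection. This vignette records the models,
the conventions chosen where the field's tooling is ambiguous, and what
the synthetic-data tests do and do not establish.

## Data model and filtering

The panel is held as a `geno_panel`: an accessions × sites matrix of
ALT-allele dosages (0/1/2, `NA` for missing), a per-site variant table
carrying the six GATK hard-filter annotations, and a named vector of
chromosome lengths. Only biallelic SNPs with GT calls are retained from a
VCF; multiallelic and non-SNP records are counted and skipped, and
half-calls are treated as missing (the upstream convention for unphased
diploid panels; phase is never used).

Hard filtering removes a site when **any** rule fails — QUAL < 20,
QD < 2.0, MQ < 40.0, FS > 60.0, SOR > 4.0, MQRankSum < −12.5,
ReadPosRankSum < −8.0 — and a site *missing* an annotation passes that
sub-filter, matching GATK practice: rank-sum annotations are undefined at
sites without both REF and ALT reads, and discarding such sites would
bias the panel toward heterozygote-rich regions. The MQRankSum cutoff is
−12.5 (the widely used default) even though source material sometimes
prints the sign-less "12.5"; the threshold object exposes it for callers
who want the literal value. MAF filtering is inclusive (MAF ≥ 0.1 keeps
the site) and uses the minor allele regardless of REF/ALT labelling.

LD pruning follows the PLINK `--indep-pairwise w s r²` semantics: windows
of `w` SNPs advancing by `s`, pairs scanned in index order, and the
*later* site of any pair with dosage-correlation r² > 0.2 removed. Two
choices are deliberate: r² is the squared Pearson correlation of dosages
over pairwise-complete observations (composite LD — genotypes are
unphased, so haplotype-EM r² is not identifiable without phasing), and
the later-site tie-break makes the scan deterministic. The test suite
checks the implementation against a brute-force O(w²) oracle and verifies
idempotence (pruning its own output is the identity).

## Diversity statistics

Per site with ALT frequency `p` over `n` called diploids:

* observed heterozygosity `Ho` = heterozygote fraction;
* expected heterozygosity `HE = 2p(1−p)` with **no** finite-sample
  correction;
* PIC (Botstein) `= 1 − p² − q² − 2p²q²`;
* nucleotide diversity contribution `(2n/(2n−1)) · 2p(1−p)`, summed and
  divided by the **total genome length** `L` (monomorphic positions count
  in the denominator — this is why π is per-bp and orders of magnitude
  smaller than HE).

`FIS = 1 − mean(Ho)/mean(HE)` is the ratio-of-means form: applied to a
published Ho/HE pair (0.2896, 0.3165) it returns 0.0850 at four decimals,
which is how diversity tables in the germplasm literature are computed.
Per-population rows count `num_snps` over sites polymorphic *within* the
population but average the statistics over all sites with data, and the
pooled `ALL` row is the **unweighted arithmetic mean** of the population
rows (verified in the acceptance tests against a published seven-value
mean). Both conventions are the ones that reproduce published tables;
they are surfaced rather than hidden because other tools average
differently.

Trait descriptives use the sample (n−1) standard deviation and
`CV% = 100·sd/mean`. The Shannon index H′ bins a trait into 10 classes —
below mean−2σ, eight half-σ classes, and at-or-above mean+2σ — and
returns −Σ pᵢ ln pᵢ over occupied classes. The 10-class half-σ grid is
the germplasm-literature convention; H′ is bounded by ln 10 ≈ 2.303 and
defined as 0 for a constant trait.

## Differentiation and gene flow

Pairwise Fst uses the Weir–Cockerham (1984) two-population variance
components `a` (among populations), `b` (among individuals) and `c`
(within individuals), computed per site from sample sizes, allele
frequencies and heterozygote proportions. Window values are
`Σa/Σ(a+b+c)` over 500-kb non-overlapping windows; the genome-wide
headline value is the same ratio over **all** sites (a ratio of sums,
hence invariant to window size — property-tested), with the unweighted
mean of window values also reported because published tables rarely say
which was used. Small negative estimates are a known signature of this
estimator at near-zero differentiation and are preserved, not clamped.

Gene flow is the island-model conversion `Nm = (1−Fst)/(4·Fst)`, applied
verbatim even to negative Fst (yielding large negative, uninterpretable
values that the report flags). At Fst = 0 the quantity is undefined and
reported missing. Published Nm values are typically computed from
*unrounded* Fst, so recomputing them from printed two-significant-digit
Fst reproduces only the best-separated pairs exactly; the acceptance
target uses the pair where the printed precision suffices.

## Structure

* **IBS distance**: 1 − mean shared-allele score, score
  `(2 − |gᵢ−gⱼ|)/2` per pairwise non-missing site.
* **Modified Rogers**: `sqrt(mean (gᵢ−gⱼ)²/4)`, the Euclidean-type
  metric conventional for core-subset optimisation.
* **Gower** (numeric traits): range-normalised mean absolute difference.
* **PCA**: dosages centred by 2p and scaled by `sqrt(2p(1−p))`, missing
  imputed to the site mean (zero after centring), eigendecomposition of
  the accession covariance — the standard GRM-PCA pipeline.
* **PCoA**: classical metric scaling; exact on Euclidean-embeddable
  matrices (tested to 1e−8) with only positive-eigenvalue axes kept.
* **NJ**: Saitou–Nei with the standard Q criterion. Two unstated details
  are fixed deterministically: Q ties break toward the lowest node-index
  pair (original leaf order first), and negative branch lengths are
  clamped to zero with the total clamped deficit recorded on the tree.
  NJ is exact on additive matrices and is tested against a
  least-squares topology-enumeration oracle up to six taxa.
* **Phenotype clustering**: traits standardised, Euclidean distance,
  Ward linkage (`ward.D2`); Ward is the default because the published
  workflows this mirrors cut compact trait clusters, but the linkage is
  an argument.
* **Kinship** is the Pearson correlation of accession dosage vectors;
  entries can be negative and the lowest relatedness bin absorbs them.
  Binning uses the conventional 0.125/0.25/0.5 cutpoints with the top
  cut inclusive in the penultimate bin.

## Core selection

Both tracks maximise the **average entry-to-nearest-entry (A-NE)**
distance — the mean over selected entries of the distance to the nearest
other selected entry — which directly penalises selecting near-duplicates.
The optimiser is a random-restart steepest-ascent swap search (replace
one selected entry by one unselected, take the best improving swap,
repeat to local optimality; several seeded restarts, patience-based early
stop). This stands in for the "mixed replica" metaheuristics of dedicated
core-selection software: the objective is identical, the search is
deterministic under a seed, and at toy sizes it provably attains the
exhaustive optimum (tested at n = 12, k = 4 against full enumeration).
Subset sizes are `floor(n × fraction)` with a floor of one — at n = 313
this gives 93 at 30% and 15 at 5%.

The genotype track optimises on Modified Rogers at gradient fractions
(default 0.05–0.30), then picks the fraction minimising the mean relative
absolute deviation of (Ho, HE, PIC) from the full panel, larger π
breaking ties. The phenotype track optimises on Gower distance and scores
candidates with:

* `MD%` / `VD%` — mean / variance difference. Two conventions exist in
  the literature and they disagree: *significance counting* (percentage
  of traits whose core-vs-full t or F test rejects at 0.05; multiples of
  25 with four traits) and *relative magnitude* (mean percent deviation
  of the core mean/variance). Published evaluations that report "MD 0%"
  alongside a VD that is not a multiple of 25 are only consistent with
  counting for MD and magnitude for VD, so the default convention is
  that mixture; both pure conventions are selectable and all four
  numbers are in the per-trait detail.
* `CR%` — mean ratio of core to full trait ranges; `VR%` — mean ratio of
  CVs. The selector maximises CR + VR subject to MD = 0.

Cores are merged as an order-stable set union with overlap accounting,
and the merged core is validated per trait by one-way ANOVA with Tukey
HSD, using N.S./*/**/*** notation at 0.05/0.01/0.001.

## Synthetic data: what it emulates, what it does not

The generator is a Balding–Nichols model: ancestral frequencies
Uniform(0.05, 0.95); population frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F), so the target Fst *is* the model
parameter — which makes estimator recovery directly testable (the WC
estimate on a simulated F = 0.05 panel with 2 × 50 accessions and 5000
SNPs falls in [0.04, 0.06]). Individuals are admixed through a Dirichlet
ancestry vector (concentration `alpha`; 0.1 by default — mostly pure
with visible admixture, matching a landrace panel), genotypes are
binomial in the individual frequency, and missing calls are masked at 2%.
Traits are multivariate Gaussian around cluster means with correlation
0.3 and per-trait means/sds on the scale of the four standard
architecture traits (branch and node counts, stem diameter in mm, plant
height in cm), giving CVs in the published 8–21% band. Defaults mirror
the motivating panel shape — 313 accessions, 7 populations (sizes chosen
once, consistent with the published per-group compositions), 8
chromosomes totalling ~450 Mb — with `n_snps` scaled to a desk-friendly
20,000; the test suite uses a 24 × 600 fixture for speed.

What a green test therefore establishes: the estimators recover the
parameters of an idealised, linkage-free, HWE-within-deme world, and the
combinatorial machinery (filters, pruning, distances, trees, subset
search) is exact or oracle-equivalent. What it does not: behaviour under
real LD structure, allele-frequency spectra shaped by selection or
bottlenecks, genotyping error that correlates with heterozygosity, or
trait architectures with genotype–environment interaction. Published
headline numbers that depend on the deposited resequencing data
(panel-wide SNP counts, the specific diversity table values) are not
reproducible at desk scale and are not claimed; only
printed-arithmetic-checkable quantities are asserted.

## Numerical and degenerate-input choices

* Report rounding is R's default (half-even) at print time; statistics
  are never rounded internally.
* All-missing sites error in `allele_stats`, are removed with a warning
  in `maf_filter`, and cannot reach downstream statistics.
* A population with fewer than two members is excluded from the
  diversity table with a warning; ANOVA requires two observations per
  group; `fis` and `nm_from_fst` return `NA` with a warning at zero
  denominators.
* Ts/Tv with zero transversions reports an infinite ratio with a
  warning rather than failing.
* Every stochastic entry point (`optimize_subset`,
  `gradient_core_search`, `select_pheno_core`, the generators, the
  pipeline) takes an explicit seed, default 313; the pipeline derives
  per-stage seeds from it, and two runs at the same seed are
  byte-identical (asserted in the acceptance suite).

## Known limitations

InDels appear only in count/density summaries; no ancestry-model fitting
(ADMIXTURE-style) or its cross-validation; no bootstrap support on NJ
trees; no haplotype-aware simulation or linkage-aware pruning beyond the
windowed r² rule; the phenotype-core candidate generator is A-NE on
Gower, one of several defensible choices for a sampler the source
workflows leave unspecified.
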