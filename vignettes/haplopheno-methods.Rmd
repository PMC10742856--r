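---
title: "Methods: candidate-gene haplo-pheno analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene haplo-pheno analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopheno)
```

## The problem

Haplotype-based breeding asks a narrow question of a diversity panel: for
each candidate gene already known or suspected to influence a trait, which
of the haplotypes segregating in the panel is the most favorable, and which
multi-gene haplotype combination should selection target? `haplopheno`
implements that workflow for fully inbred panels (selfing crops such as
rice): variant QC, multi-environment trait statistics, a kinship-corrected
association scan, haplotype group statistics, and a discriminating marker
panel for the superior haplotype group.

Inbreeding is what makes the haplotype step trivial and robust: a fully
homozygous accession carries one haplotype per gene, read directly off its
variant dosages, so no statistical phasing is involved.

## Pipeline and models

### Variant QC

Records are removed when `QUAL < 30`, `QD < 4.0`, `FS > 60.0` or
`MQ < 40.0` — strict inequalities, so boundary values survive. A record
missing one of those INFO annotations simply skips that criterion (the
count of skips is logged); dropping such records instead would silently
discard whole callsets produced without a given annotation. Multiallelic
records are dropped with a logged count; residual heterozygous calls in an
inbred panel are kept in the dosage matrix but excluded later at haplotype
calling.

### Variance components, heritability, BLUP

For each trait observed on `n` accessions in `e` environments with `r`
replicates, variance components come from the expected mean squares of the
two-way ANOVA. With `r = 1` (one pooled value per accession and year — the
default, matching trials that pool several plants per plot) the
genotype-by-environment interaction and the residual are confounded; the
estimator then reports `Vg = (MS_G - MS_GE)/e`, `Ve = MS_GE`, `Vge = 0`
and says so. Negative moment estimates are truncated at zero, the standard
convention. Broad-sense heritability is

    h2 = Vg / (Vg + Vge/e + Ve/(r*e)),

the reliability of an accession mean across the whole trial. BLUPs use the
balanced closed form: environments are removed as fixed effects by
centering, and accession means are shrunk toward the grand mean by exactly
`h2`. For accessions observed in fewer environments the shrinkage uses
their own environment count, which reproduces the Henderson
mixed-model-equation solution (verified in the tests against a direct MME
solve). General REML machinery would add nothing at this design size.

### Kinship and LD pruning

Kinship is the centered relatedness matrix `K = W W' / p` over
column-centered dosages with mean imputation of missing calls — the
standard estimator of mixed-model association tools. LD pruning follows
the sliding-window convention (window 100 variants, step 50, r² > 0.2;
within a violating pair the lower-MAF variant is removed, ties to the
later position). By default the pruned set feeds kinship while the scan
tests the full QC'd set; `assoc_on_pruned` flips that. Testing the full
set keeps every candidate site scoreable; building kinship from the pruned
set avoids letting one long gene dominate relatedness.

### The association scan

Per variant, the model is `y = 1*a + x*b + u + e` with
`u ~ N(0, s2*lambda*K)`. `K` is eigendecomposed once; in the rotated basis
the covariance is diagonal, so profiling the variance ratio `lambda` by
REML is a 1-D problem. A 61-point log10 grid over `[1e-5, 1e5]` brackets
the optimum and Brent refinement (`stats::optimize`) polishes it; the grid
pass is vectorized across variants. The Wald test uses a t reference with
`n - q` degrees of freedom, which reduces *exactly* to the OLS t-test when
`K` is the identity — the main correctness anchor for the scan. Variants
with minor allele frequency below 1% (or monomorphic) are skipped with a
reason rather than tested.

A variant is *associated* with a trait only when `p < 0.01` (strict) in
every dataset: each environment and the BLUPs. This consistency rule, not
multiple-testing correction, is the filter against environment-specific
flukes; an optional FDR column can be added downstream but plays no role
in the decision.

One operating characteristic worth knowing: in a candidate-gene panel the
kinship matrix is built from the very genes being tested, so a tested
variant's own direction in `K` carries a nonzero eigenvalue and part of
its signal is absorbed by the random effect. With ~40 genes the absorption
is mild; with very few genes it is severe. This is a property of the
method, not of the implementation, and the calibration experiments below
quantify it.

### Haplotype group statistics

Haplotypes are called per gene over its consistently associated variants;
any missing or heterozygous site makes that accession's haplotype missing
(conservative — no imputation). Labels are frequency-ranked (`H1` most
common, ties by lexicographic allele string). Groups with more than three
member accessions are analyzed (`min_count = 4`); a percent-based mode
(`>= 1%` of the panel) is provided because both conventions circulate.
Excluded accessions stay in the denominators of panel percentages, so the
percent column of all groups sums to at most 100 (equality only with no
missing assignments).

Group statistics run on BLUPs by default: two groups get a pooled-variance
Student's t (Welch behind a flag), three or more get Duncan's multiple
range test. Duncan critical ranges for a span of `p` sorted means use the
studentized range at protection level `alpha_p = 1 - (1 - alpha)^(p-1)`
with the harmonic mean of group sizes; the step-down recursion protects
pairs inside any homogeneous span, and the compact letter display is read
off the maximal non-significant ranges. Variance explained is the one-way
ANOVA eta-squared, `100 * SS_between / SS_total`, on the retained groups —
a deliberate, documented definition, since "percent of genetic variation
explained" is often left undefined in application papers. The superior
haplotype is the retained group with the most favorable mean for the
trait's breeding direction, ties to the larger group.

Combinations simply replace the per-gene label with the tuple of labels
across the associated genes (`HC1, HC2, ...`, frequency-ranked); rare
combinations are excluded by the same rule and all statistics apply
unchanged. Because combinations refine single-gene groupings, their
between-group sum of squares — hence eta-squared — can only grow, a
monotonicity the tests check.

### Marker panels

The discriminating panel for a target group is a set cover: each site
whose allele differs between the target and some other retained group
covers that group. Up to 15 candidate sites the minimal cover is found
exhaustively; beyond that a greedy cover (most new groups covered, ties to
the earlier genomic position) is used. The output is the site list with
diagnostic alleles — what an allele-specific PCR assay would interrogate;
primer design is out of scope. `genotype_panel()` calls an accession
`target` only when it is homozygous for every diagnostic allele, and
`inconclusive` on any missing or heterozygous panel site, so false
negatives on clean data are impossible by construction.

## The synthetic panel generator

No real panel ships with the package, so the generator is first-class,
tested code. It emulates a targeted-capture diversity panel: 180 fully
inbred accessions; 42 genes, each with a promoter (2 kb upstream,
strand-aware), UTRs, 2–3 exons and a CDS of valid length; 2–4 founder
haplotypes per gene copied whole into accessions (inbred lines are mosaics
of founder gene-haplotypes; recombination within a gene is rare enough to
ignore at this scale); three subpopulations whose founder frequencies are
Dirichlet perturbations of the panel-wide frequencies with concentration
`(1-F)/F` (a multi-allele Balding–Nichols analogue, `F = 0.15` by
default); and two trial years with one pooled value per accession-year.

Phenotypes follow `y = mu + g + h + E_j + (gE)_ij + eps`, where `h` is the
sum of planted haplotype effects and `g` is a background polygenic deviate
drawn with covariance proportional to the realized kinship of the genes
*not* causal for that trait. The restriction to non-causal genes is what
makes `g` a background term: drawing it from the full marker kinship would
place a random genetic effect directly on the causal haplotype contrast,
so the "planted" gap would no longer be the configured one and the
analytic eta-squared limit below would not hold. The confounding that the
mixed model must correct — population structure plus polygenic signal
spread over the other ~41 genes — is fully preserved, and the scan's
kinship matrix still contains the causal gene (as in real analyses), so
the test remains adversarial where it should be. Site-quality fields
are drawn from passing distributions with a configurable fraction planted
to fail each QC criterion. Defaults: 8 sites per gene (desk-scale; real
capture panels carry more, but extra sites within a gene are largely
redundant copies of the same founder contrast), four grain-morphology
traits with variances tuned to land broad-sense heritabilities around
0.80–0.94, and planted effects on the scale of published haplotype gaps
(tenths of mm for grain dimensions, 2.5–4 g for grain weight).

What the generator does *not* emulate: genotyping error inside retained
records, within-gene recombination, dominance or epistasis, multiallelic
sites, and genome-wide background loci outside the candidate genes. The
last one matters for interpretation: real panels have polygenic variance
only partially captured by candidate-gene kinship, so the scan's power on
real data should be somewhat *higher* than in these simulations.

## Calibration experiments

Three exported experiment functions define the package's operating
characteristics; the test suite asserts on them and
`scripts/acceptance.R` recomputes them from scratch
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`):

- `experiment_type1()`: null panels — no planted effects, independent
  accession-level noise — with subpopulation structure in the genotypes
  and one site per gene for near-independence; the per-dataset inclusion
  rate at `alpha = 0.01` must sit inside the binomial 95% interval over
  >= 10,000 variant-dataset tests (measured ~0.0102 over 28,600 tests).
  The function also offers the harder null in which the genetic term is
  drawn from the marker kinship itself (`background = "kinship"`); there
  the measured rate is ~0.0113, a mild inflation that reflects a real
  limitation — a kinship matrix built from a few hundred candidate-gene
  markers corrects population structure only partially. Panel-level
  clustering also makes that rate fluctuate more than binomially between
  runs.
- `experiment_recovery()`: 100 panels from `recovery_config()` — one
  causal gene among 42, two equifrequent founder haplotypes, planted gap
  equal to one phenotypic SD under `h2 = 0.85`. Fixing the background
  polygenic variance at 1, those constraints force gap
  `delta = sqrt(92/45)` and `Ve = 24/45`, and the population eta-squared
  of the causal split on accession means is `100*d^2/(d^2+4)` with
  `d^2 = 92/57`, i.e. 28.75%. The full pipeline must return the planted
  superior haplotype in at least 95 panels, with mean estimated R² within
  5 points of that limit.
- `experiment_h2()`: 50 panels with `Vg = 4` and `Ve` solved so the
  configured h² is 0.85; the moment-estimator mean must land within 0.08.

Numerical choices worth stating: kinship eigenvalues are floored at zero
(tiny negatives arise from rank deficiency); the REML search range for
`lambda` is `[1e-5, 1e5]` on a log grid, wide enough that the optimum is
interior in all calibration runs; `optimize()` tolerance is 1e-6 on the
log10 scale, far inside the 1% agreement required against a 10^4-point
reference grid; zero-variance degenerate cases in the group tests return
defined values (p = 1 for equal means) or flagged NAs rather than errors.

## Limitations

The closed-form BLUP assumes a balanced (or mildly unbalanced) two-way
design; heavily unbalanced multi-location trials need a general mixed
model. Duncan's test is liberal by construction — it is provided because
it is the field's convention for these tables, with the overall F and
pairwise t reported alongside. Eta-squared on BLUPs is an in-sample
quantity and modestly optimistic at small group counts. The consistency
rule's stringency grows with the number of environments; with many
environments a less brittle rule (e.g. BLUP-only with FDR) would be
preferable. Marker panels discriminate only against haplotype groups seen
in the training panel; a new haplotype in outside material can genotype as
`target` at the panel sites while differing elsewhere in the gene.
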