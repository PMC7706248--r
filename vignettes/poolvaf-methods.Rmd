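---
title: "Methods: pooled-amplicon VAF analysis with poolvaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-amplicon VAF analysis with poolvaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolvaf)
library(dplyr)
```

## The problem

Genebank accessions of outcrossing crops such as rye are heterogeneous:
a seed stock is a population, not a genotype, and alleles can segregate
within it at any frequency down to a single heterozygous plant. Genotyping
one seed per accession therefore misses most of the within-accession
variation. Deep pooled amplicon sequencing addresses this by pooling DNA
from many plants per accession (here 96 diploids, i.e. 192 chromosomes),
amplifying a panel of candidate-gene amplicons, and sequencing each pool to
thousands-fold coverage. The fraction of reads carrying an alternate allele
then estimates the **variant allele frequency (VAF)** of that allele within
the accession, with a design floor of one heterozygote per pool,
$\mathrm{VAF} = 1/192 \approx 0.0052$.

`poolvaf` implements the downstream analysis of such an experiment as a
tested, reusable pipeline: VAF estimation from read counts or VCF allele
depths, intersection of call sets from several variant callers, coding
effect classification, VAF-based population genetics (Nei distance,
neighbor joining, PCoA, private alleles), distribution comparison with a
two-part Wilcoxon test, VAF-to-genotype-score conversion, and CAPS
validation assay design. A synthetic-data module generates experiments
with the same statistical structure so every stage is testable without raw
sequencing data.

## The statistical core

### VAF from pooled read counts

For an accession with `depth_ref` reference and `depth_alt` alternate
reads at a site,

$$\widehat{\mathrm{VAF}} = \frac{d_{alt}}{d_{ref} + d_{alt}},$$

with zero total depth treated as missing, never as 0. Under the sampling
model (reads drawn binomially from the pool with symmetric per-base error
$e$), the estimator has expectation $f(1-e) + (1-f)e$, so its bias is
$e(1-2f) \le e$; with $e \le 0.002$ and deep coverage this is within the
$\pm 0.005$ recovery tolerance the test suite asserts.

### A binomial stand-in caller

The pipeline ingests external pooled-caller VCFs, but also provides
`call_pooled_variants()`: a site/accession is called when
$d_{alt} \ge$ `min_alt_reads` (default 20, the classic
"20 reads to support a 5% variant at 400x" depth rule) **and** an exact
one-sided binomial tail test rejects
$d_{alt} \sim \mathrm{Bin}(d, e)$ at level $\alpha$. The exact tail is
used rather than a normal approximation so small counts are correct. The
default $\alpha = 10^{-6}$ is deliberately small: a panel experiment
implicitly tests on the order of $10^5$ accession-by-position pairs, and a
per-test $10^{-6}$ keeps the expected number of error-driven calls near
zero, which matters because a single false carrier destroys a
private-allele classification.

### Multi-caller consensus

Variant callers disagree most at low frequency. `consensus_calls()`
normalises variant keys (shared affix trimming with position shift, so
indel representations from different callers match), intersects the key
sets, and keeps each caller's per-accession VAFs side by side — callers
agree on identity far more than on frequency. Consensus is intentionally
conservative: because the stricter emulated callers apply higher
alternate-read and frequency floors, the common set is depleted of the
lowest-VAF variants, which mirrors the behaviour observed when real
haplotype-based, frequentist and pooled callers are intersected.

### Nei's (1972) distance from VAF

Each variant is treated as a biallelic locus with alternate frequency $p$
(the pool VAF, 0 when not called) and reference frequency $q = 1-p$. For
accessions $X, Y$ over $L$ loci:

$$J_X = \tfrac1L \sum_\ell (p_{X\ell}^2 + q_{X\ell}^2), \quad
  J_{XY} = \tfrac1L \sum_\ell (p_{X\ell} p_{Y\ell} + q_{X\ell} q_{Y\ell}),
  \quad D = -\ln \frac{J_{XY}}{\sqrt{J_X J_Y}}.$$

$J_{XY} = 0$ (alleles disjoint at every locus) gives $D = \infty$: the
exact infinity is preserved in exported tables, and `cap_infinite()`
(default: 10 times the largest finite entry) must be applied before tree
building. Trees come from the standard Saitou–Nei agglomeration
(Studier–Keppler $Q$; `ape`'s implementation, with the two-taxon case
handled directly). Negative branch lengths are retained by default, with
an optional clamp, since different tree programs differ here. PCoA is
classical metric scaling (Gower double-centering + eigendecomposition via
`cmdscale`); coordinates are reported only on positive eigenvalues and
negative eigenvalues are reported but excluded.

### Two-part Wilcoxon test

Per-accession VAF vectors over the common-variant set are zero-inflated:
most accessions do not carry most variants. The two-part construction
(after Lachenbruch) combines

* $B$ — a pooled-variance two-proportion $z$ comparing the fractions of
  zeros, and
* $W$ — a tie-corrected, normal-standardised Wilcoxon rank-sum on the
  nonzero values,

into $X^2 = B^2 + W^2 \sim \chi^2_2$ under the null. When only one part is
computable (no zeros anywhere, or no nonzero values in one sample), $X^2$
is that part's square on 1 df — a choice this package fixes because the
underlying formulation leaves the degenerate cases open. When both parts
are degenerate, $p = 1$ with a flag. With no zeros the test provably
reduces to the plain tie-corrected rank-sum normal approximation
($\chi^2_1(z^2)$ equals the two-sided normal $p$), which the suite checks
to $10^{-6}$ against `wilcox.test`. Monte-Carlo calibration under a
zero-inflated null (40% zeros, $n = 300$ per sample) gives an empirical
size of about 0.051 at $\alpha = 0.05$ (10,000 replicates); the acceptance
check asserts the $[0.03, 0.07]$ band over 1,000 seeded replicates. Raw
per-pair decisions at $\alpha = 0.05$ form the binary significance matrix
(no multiplicity correction by default, matching common practice for this
display; a Bonferroni option exists). Hierarchical clustering treats that
0/1 matrix as a dissimilarity with complete linkage; flat clusters are cut
just below height 1, so accessions never declared different share a
cluster — the cut rule is a package decision, as published analyses rarely
state one.

### Genotype scores and threshold sensitivity

Treating a pool as if it were one diploid individual, VAF maps to a
0/1/2 score: $\mathrm{VAF} < L \to 0$, $\mathrm{VAF} \ge U \to 1$,
otherwise 2, with presets $(0.3, 0.7)$, $(0.4, 0.6)$, $(0.2, 0.8)$. The
textual rule that inspired this mapping leaves $\mathrm{VAF} = L$
unassigned; `poolvaf` defines $[L, U) \to 2$ so the mapping is total, and
documents the repair. Euclidean distances over score vectors feed NJ, and
Robinson–Foulds distances between the three preset trees quantify how
strongly the implied "genotype" depends on the thresholds — the package's
topology metric where published comparisons were visual.

### CAPS assays

`find_sites()` matches an IUPAC recognition pattern and its reverse
complement on the forward strand (deduplicating palindromes);
`site_change()` applies the alternate allele (indels shift downstream
coordinates; both alleles are re-scanned in full so sites created across
an edit are caught) and classifies gain/loss. Fragment boundaries are
placed at the first base of each site match: exact cut offsets differ per
enzyme and are irrelevant for telling alleles apart on a gel, so fragment
lengths are approximate to within the site length while always summing to
the allele length. Observed allele frequencies from individually
genotyped plants use
$(\mathrm{RefAlt} + 2\,\mathrm{AltAlt}) / (2n)$, reported at two decimals
by validation-table convention with full precision retained.

## The synthetic-data generator

`sim_config()` defaults encode the experiment the package targets: 95
accessions × 96 diploid plants, six ~600 bp amplicons, per-pool
depth log-normal with mean 13,948 truncated to [2,924, 30,275] (the
reported mean and ~10-fold range; the log-normal shape and its
$\sigma_{\log} = 0.45$ are a package choice, as only mean and range are
reported), one shared variant per 12 bp, and a symmetric per-base error
rate of 0.001 — a placeholder for unreported paired-end error profiles,
not a measured value.

Three allele classes are planted:

* **shared (common) variants** — carried by at least two accessions
  (site-specific carrier probability Beta(0.3, 1); singleton variants are
  the business of the private class), with carrier frequencies
  Beta(0.25, 4.75), concentrating mass at low VAF;
* **private alleles** — per accession, `floor(rate)` plus a Bernoulli
  remainder: wild 6, landrace 2, historic 0.8, modern 0.5 per accession
  (the reported five-to-seven / two / below-one gradient), with frequency
  Beta(1.2, 1.8) in wild material (mean ≈ 0.4) and Beta(0.35, 2.5)
  elsewhere (mean ≈ 0.12, median far lower — most non-wild private alleles
  are nearly invisible, as in real data);
* **hidden alleles** — exactly one heterozygous plant in one pool
  (frequency exactly $1/192$), Poisson with mean 2 per accession.

One accession (the first wild one by default) is made maximally diverged:
fixed for the alternate allele at 80% of shared sites, emulating a
distinct wild taxon scored against a cultivated reference. Within each
accession, plant genotypes follow Hardy–Weinberg proportions independently
per site (random mating, no linkage — a documented simplification), drawn
conditional on a carrier pool actually containing the allele; the stored
"true" pool frequency is the realised allele frequency of the sampled
plants, so `true_freq` equals mean dosage over `2n` exactly and hidden
alleles sit exactly at $1/192$. Read counts are
$\mathrm{Bin}(d, f(1-e) + (1-f)e)$ at log-normal depths; emulated caller
VCFs apply per-profile minimum alternate-read and minimum-frequency
thresholds (defaults 5/25/10 reads and 1/384, 1/128, 1/256) to one shared
count matrix, so the three call sets overlap but differ, most strongly at
low VAF.

What the generator does **not** emulate: read-level errors and qualities,
PCR amplification bias, linkage between sites, multi-allelic sites (the
analysis decomposes them, but the generator plants biallelic sites), and
caller-specific artefacts beyond thresholding. Passing tests therefore
demonstrate correctness of the analysis given the sampling model, not
robustness to every real-data pathology.

## Numerical and design choices

* Seeds: one master seed; per-stage substreams derived deterministically
  (`stage_seed()`), so stages re-run independently and the whole pipeline
  is bit-reproducible under a fixed seed.
* Missing VAF (zero depth) is `NA` at estimation, imputed 0 for distance
  and distribution analyses with a warning.
* Variant keys are normalised by suffix-then-prefix trimming (at least one
  base retained, position shifted); normalisation is idempotent.
* NJ ties are resolved by `ape`'s deterministic implementation; trees are
  reproducible.
* Variants spanning exon–intron boundaries classify as `intronic` with a
  warning; amplicons may truncate genes, handled via an explicit CDS
  phase.
* Effect classification covers SNVs (standard genetic code, strand-aware)
  and indels (frameshift/in-frame by length mod 3). Protein-level
  deleteriousness prediction needs external tools and databases; an
  externally produced `deleterious` flag is carried through summaries
  instead.
* Problem sizes in the test and acceptance runs: 12 accessions (4 wild /
  4 landrace / 4 modern), 3 amplicons, ~150 shared sites, 1,000
  Monte-Carlo replicates for test calibration — sizes chosen so planted
  structure is recoverable while a full run stays interactive.

## Known limitations

* The two-part test's binomial part uses a pooled-variance $z$ without
  continuity correction; at small $n$ or extreme zero fractions its size
  drifts above nominal (at $n = 300$, 40% zeros, the measured size is
  0.051).
* Nei's distance from VAF treats every variant as an independent biallelic
  locus and uncalled as frequency 0; linked sites or systematic caller
  dropout bias distances in ways the package does not model.
* With very few accessions per germplasm group, private-allele group
  contrasts are Poisson-noisy; group orderings from a dozen accessions
  should be read as demonstrations, not inference.
* CAPS fragment lengths are approximate to within the recognition-site
  length by construction; they distinguish alleles but are not gel-exact.
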