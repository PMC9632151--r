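---
title: "hervtools: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hervtools: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`hervtools` is a toolkit for locus-level analysis of expressed human
endogenous retroviruses (HERVs).  It does not run aligners or
assemblers: it consumes their output abstractions (per-sample
assembled-transcript alignments with support counts and identities,
re-mapping hits, genotype dosages, peak and methylation tracks) and
implements the decision logic around them — the part of such pipelines
that actually embodies scientific choices.  Internally every interval
is 0-based half-open; the GTF and VCF readers/writers convert at the
boundary and nowhere else, which eliminates off-by-one drift between
modules.

# Detection

A candidate transcript survives four gates, applied in order:

1. **Support/identity filter** — read-support count strictly greater
   than 5 and best-hit alignment identity at least 0.96.  The
   strict/non-strict mix is deliberate and is frozen in boundary tests
   (count 5 fails, identity 0.96 passes).  Identity is defined as
   matched / (matched + mismatched + inserted + deleted) aligned
   columns; the upstream spliced aligner's exact formula is not
   published, so this is a stated approximation.
2. **Recurrence/length merge** — same-strand transcripts whose exon
   chains share at least 1 bp are clustered by single linkage; the
   consensus chain is the union of member exons.  A cluster is kept if
   supported by at least `ceiling(0.5 × n)` of the body site's `n`
   samples and at least 200 bp long.  The recurrence denominator is the
   body-site sample count (the pipeline is run per site, and the
   published per-site locus sets imply per-site recurrence).  Single
   linkage over ≥ 1 bp overlap replaces a meta-assembler: what
   downstream stages need is exactly one consensus locus per overlapping
   cluster, and that contract is tested against a brute-force
   connected-components oracle.
3. **Unique re-mapping** — a merged locus is kept only if exactly one
   re-mapping hit passes the identity gate *and* no other hit lies
   within 0.01 identity of the best (a guard against score ties from
   floating-point noise), *and* the unique hit overlaps a HERV element.
4. **Expression call** — per body site, raw count > 5 and TPM ≥ 0.1 in
   at least 50 % of samples.

Each stage logs what it drops and why; the synthetic fixture plants ten
decoys that each violate exactly one gate, so a regression is
attributable to the responsible filter.

# Classification

*Location* uses gene-body (not exon-only) overlap: antisense HERVs
typically sit in introns of the opposite-strand gene, so exon-level
overlap would misclassify them as intergenic.  Priority is
`inserted` (same-strand overlap) over `antisense` over `intergenic`.
Unknown strand (`.`) never counts as same or opposite, and unstranded
loci are an error rather than a silent class.

*Origin* groups the overlapped HERV elements by provirus: elements from
two or more provirus groups make the locus `chimeric`; a single
provirus with 5′LTR, internal region, and 3′LTR all overlapped makes it
`full-length`; only-LTR overlap of a provirus group *without* any
internal-region annotation is `solo-LTR` (the genomic solo-LTR state,
approximated by annotation absence); everything else is `truncated` —
including a single LTR of a provirus that does have an internal region,
because that is partial overlap of an intact provirus, not a
recombined-out solo LTR.

*Full-length subtypes* are mutually exclusive with fixed priority
host-chimeric > upstream-TSS > 3′-readthrough > unit-length, because a
transcript can satisfy several geometric conditions at once and the
published subtype counts partition.  Upstream/downstream comparisons
are strand-aware: for a minus-strand locus, "upstream" is the larger
coordinate.  The class-assignment overlap threshold is ≥ 1 bp and
configurable; nothing in the source methods states a larger one.

# Expression

TPM is computed per column as `1e6 · (count/length) / Σ(count/length)`;
columns sum to 1e6 up to float tolerance and the transform is invariant
to scaling a sample's counts.  Sample distance is `1 − Spearman` on
`log2(TPM+1)` with average ranks; a constant profile has no defined
correlation, which is treated as 0 (distance 1) with a warning rather
than `NA` propagation.  The two-group DE contract is served by a
rank-sum reference engine (two-sided Wilcoxon on `log2(TPM+1)`, BH
across loci, mean-difference log2 fold change); the engine name is
recorded in every result row so a count-model engine can be swapped in
behind the same interface.  "Body site-specific" is read as exclusive
expression (expressed in exactly one site); "preferentially expressed"
is implemented literally as significant positive DE against every other
site where the locus is expressed.

# Genetics

**Presence-aware genotyping.** A zero count can mean the locus is
absent from that individual's genome.  Loci without a uniquely mapping
assembled contig in an individual are treated as missing (`NA`) for all
fits, and a test asserts that masking is exactly equivalent to removing
those individuals.

**Variant QC.** Keep missing < 5 %, MAF ≥ 1 %, HWE χ² (1 df) p ≥ 1e−6.
The source phrasing lists filters without directions that would be
genetically sensible read any other way; this reading is flagged as an
interpretation in the QC documentation.  The per-site filter
additionally requires ≥ 10 minor-allele carriers.

**Normalization.** TMM is implemented as originally published
(upper-quartile-closest reference, 30 %/5 % trimming of M and A,
precision-weighted mean of M, geometric-mean-1 rescaling); the test
suite checks it against an independent implementation to 1e−6 and
against closed forms (depth-only → all factors 1; constant M = m →
factor ratio 2^m).  The inverse normal transform is
`Φ⁻¹((rank − 0.5)/n)` with average ranks and preserved missing values.

**cis scan.** Variants within ± 1 Mb of the locus TSS.  Both the
inverse-normal expression and the dosage are residualized on the
covariates before taking the least-squares slope: residualizing only
the response (a common shortcut) leaves the slope unequal to the
multiple-regression coefficient whenever dosage correlates with a
covariate; residualizing both restores exact equivalence
(Frisch–Waugh) and the t test uses `n − n_cov − 2` df.  Hidden
expression factors are top principal components at the published
sample-size schedule (15/30/45/60 below 150 / below 250 / below 350 /
at least 350 samples) — a deterministic stand-in for latent-factor
methods that satisfies the same covariate contract.

**Permutations.** The per-locus statistic is the minimum nominal p over
cis variants (equivalently the maximum absolute partial correlation,
which is what is actually computed — one matrix product per locus).
Sample labels of the residualized expression are permuted; the
empirical p is the add-one rank `(1 + #{perm ≤ obs})/(1 + n_perm)`,
exact enumeration of all `n!` permutations below 9 samples.  Ties in
the statistic are counted as exceedances with a 1e−12 tolerance, which
makes the tiny-n enumeration agree bit-for-bit with an independent
oracle.  The add-one empirical p replaces a beta-tail approximation:
that approximation is an efficiency device, not part of the scientific
claim, and the empirical version is exact at the scale this package
targets.  eHERVs are called by BH on the empirical p at FDR ≤ 0.05
(BH replaces Storey q-values: deterministic, no density estimation).
The per-locus nominal threshold is the interpolated quantile of the
permutation min-p distribution at the target level.  Default
`n_perm = 1000` matches the power/calibration acceptance runs; the
file-based `qtl` pipeline stage defaults to 200 to keep the end-to-end
run fast — both are configuration fields.

**Enrichment.** Background variants are matched to targets by
chromosome, MAF quantile bin, and `log10(1 + TSS distance)` quantile
bin (20 bins each — unstated upstream; 20 gives ~5 %-wide bins, fine
enough to preserve the distributions, coarse enough not to starve the
pool), sampling without replacement with a logged nearest-bin fallback.
Per category the 2×2 table is tested two-sided (Fisher); the reported
odds ratio is the sample cross-product with 0.5 continuity correction
on zero cells, and the categories dropped upstream for low counts
(`ncRNA_splicing`, `splicing`, `stopgain`, `stoploss`) are removed
before testing.  GWAS hits are filtered at p < 5e−8 (strict) and
expanded by panel LD at r² > 0.8.

# Epigenetics

The TSS of a minus-strand locus is the last base of its span.  Peaks
count if they overlap the inclusive window `TSS ± 5 kb`; methylation is
the coverage-weighted mean beta over CpGs in the same window (weighted,
as is conventional for whole-genome bisulfite data; unweighted means
would let low-coverage CpGs dominate).  Expressed-vs-silent methylation
tests use TPM ≥ 0.1 vs TPM = 0, excluding the intermediate band —
the two published categories are non-exhaustive by construction.
Loci without any peak are removed per mark, not across marks (the
stricter reading would couple unrelated marks).

# Factors

Per-site sex and ethnicity effects delegate to the DE contract within
each site (sex-specific sites — ovary, prostate, testis, uterus,
vagina — excluded for sex by default); age uses per-site Pearson
correlation on `log2(TPM+1)` with ≥ 10 aged samples.  The global model
is `H_ijk = B_i + I_j + C_k + E_ijk` with body site fixed, individual
as a random intercept, and sex/ethnicity fixed or age as covariate,
fitted by maximum likelihood with `lme4`; the factor term is tested by
likelihood ratio against the nested model (the source does not state
its p-value method; the LRT is well defined and engine-independent),
screened at ≥ 6 body sites per locus ("more than five"), BH across
loci.  Singular fits are flagged in the output, never silently dropped.
Tests verify the model collapses to OLS when individual variance is
absent and that estimates are invariant to site relabeling and global
shifts.

# The synthetic world

The generator's defaults *are* the stated test conditions, not tuning
knobs: 12 planted loci (three per origin class; locations cycling
antisense/intergenic/inserted; the three purely geometric full-length
subtypes — the host-chimeric subtype is exercised in unit tests because
it requires a containing host transcript), 10 single-gate decoys, 8
samples per site with planted loci in 75 % of them (the first carrier
holds the full chain so the consensus union is exact), support count
20, identity 0.99 against gates of 5 and 0.96.  Counts are negative
binomial (size 10) around a base mean of 50 with planted site, sex
(δ = 1 log2), and age (0.02 log2/year) effects on the log scale.
Genotypes are Hardy–Weinberg draws; planted cis effects add
β × dosage (default β = 1, MAF 0.3) to a unit-normal expression value,
so effect recovery is interpretable in inverse-normal SD units.  Peaks
land near high-expression loci with probability 0.9 vs 0.1 background;
the planted methylation difference is +0.15.  Geometry is deterministic
given the configuration; all stochastic draws are seeded and restore
the caller's RNG state.

What the generator does *not* emulate — and therefore what a green test
does not establish: realistic repeat-family sequence homology and the
multi-mapping it induces (decoys violate one gate each by
construction), LD structure beyond independent variants, relatedness,
batch effects, or the empirical count distributions of real tissue
panels.  Green acceptance means the decision logic is faithful and
calibrated on data that satisfies its assumptions, not that the
thresholds are optimal for any particular cohort.

# Numerical conventions

Average ranks for ties everywhere (Spearman, rank-sum, inverse normal);
BH for every multiple-testing family; deterministic sign convention for
principal components (largest-|loading| positive); LD pruning drops the
later-positioned variant of a linked pair; merged loci are id-assigned
in genomic sort order so output is reproducible; degenerate inputs
(constant vectors, empty groups, singular designs) are logged and
skipped or flagged rather than silently coerced.

# Known limitations

The rank-sum DE engine has a p-value floor at small n (≈ 1.5e−4 at
10 vs 10), so single discoveries cannot clear BH over very large locus
panels — a count-model engine can be plugged into `pairwise_de`'s
contract where that matters.  Coding-potential calls, colocalization
posteriors, network modules, and the upstream aligners themselves are
out of scope by design.
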