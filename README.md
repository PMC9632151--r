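# hervtools

Locus-specific detection and association analysis of expressed human
endogenous retroviruses (HERVs).

Most of the human genome's retroviral remnants are transcriptionally
silent, but thousands of individual HERV loci produce RNA in normal
tissues.  Quantifying them is hard precisely because they are repeats:
family-level counting hides which genomic copy is transcribed, and
locus-level calling needs aggressive filtering to survive multi-mapping.
`hervtools` re-implements, as a tested and reusable R toolkit, the
decision logic of a locus-specific expressed-HERV pipeline and its
downstream association machinery:

* **Detection** — select HERV-informative reads (overlap a HERV element,
  touch no annotated exon), gate assembled-transcript alignments at
  support count > 5 and identity ≥ 96%, merge candidates recurring in
  ≥ 50% of a body site's samples with consensus length ≥ 200 bp, and
  keep only loci with a unique genomic re-mapping that overlaps a HERV
  element.  Expression calling requires raw count > 5 and TPM ≥ 0.1 in
  ≥ 50% of a site's samples.
* **Classification** — location (`antisense` / `intergenic` /
  `inserted`, by strand-aware gene-body overlap), origin (`solo-LTR` /
  `truncated` / `chimeric` / `full-length`, from the LTR–internal–LTR
  provirus structure of the overlapped elements), and the four
  full-length subtypes (`unit-length`, `upstream-TSS`,
  `3'-readthrough`, `host-chimeric`).
* **Expression** — TPM, 1 − Spearman sample distance with classical MDS,
  body-site specificity/ubiquity (≥ 40 sites), and a pluggable
  two-group DE contract (rank-sum reference engine).
* **Genetics** — presence-aware genotyping (loci without uniquely
  mapping assembled contigs become missing values), variant QC
  (missingness < 5 %, MAF ≥ 1 %, HWE p ≥ 1e−6), TMM scaling factors,
  rank-based inverse-normal transform, LD pruning and genotype PCs,
  cis-QTL scans in a ± 1 Mb TSS window with permutation-based empirical
  p-values (statistic: minimum nominal p over cis variants; add-one
  rank, exact enumeration at tiny n), eHERV calling at FDR ≤ 0.05, and
  matched-background Fisher enrichment (MAF / chromosome / TSS-distance
  matching, GWAS LD expansion at r² > 0.8).
* **Epigenetics** — histone peaks and coverage-weighted DNA methylation
  in ± 5 kb TSS windows, tested against expression (Wilcoxon, per-locus
  Pearson, BH).
* **Factors** — per-site sex/ethnicity DE and age correlation, plus the
  global linear mixed model `H_ijk = B_i + I_j + C_k + E_ijk`
  (body site fixed, individual random, sex/ethnicity fixed or age as
  covariate; likelihood-ratio tests via `lme4`).
* **Simulation** — a fully seeded generator for every input (annotation,
  transcripts, counts, genotypes, peaks, methylation, metadata) with
  machine-readable truth: 12 planted loci covering the full taxonomy and
  10 decoys that each violate exactly one detection gate.

## Worked example

Detect and classify the planted loci of the synthetic fixture:

```r
library(hervtools)
cfg <- sim_config(seed = 1)
ann <- simulate_annotation(cfg)
tx  <- simulate_transcripts(cfg, ann)
filt   <- filter_candidates(tx)                   # count > 5, identity >= 0.96
merged <- merge_candidates(filt, n_samples = 8)   # >= 50% recurrence, >= 200 bp
loci   <- assign_unique_locus(merged,
            simulate_remap_hits(merged, ann, cfg), ann$herv)
cl <- classify_loci(loci, ann$herv, ann$genes)
table(origin = cl$loci$origin, location = cl$loci$location)
```

```
             location
origin        antisense inserted intergenic
  chimeric            1        1          1
  full-length         0        0          3
  solo-LTR            1        1          1
  truncated           1        1          1
```

All 12 planted loci are recovered with exact labels; the 10 decoys are
eliminated at their planted gates (2 at the identity filter, 2 at the
count filter, 2 at the length gate, 2 at the recurrence gate, 2 at the
uniqueness check).

Map cis-ervQTLs on a seeded cohort with 3 planted effects
(β = 1 inverse-normal SD at MAF 0.3) among 7 null loci:

```r
gs <- simulate_genotypes(cfg <- sim_config(seed = 2),
                         n_individuals = 100, n_qtl = 3, n_null = 7,
                         n_cis = 25)
perm <- permutation_pass(gs$expr, gs$genotypes, NULL, gs$loci_tss,
                         n_perm = 1000, seed = 2)
call_ehervs(perm)[, c("locus_id", "best_variant", "beta", "p_perm",
                      "fdr", "is_eherv")]
```

```
      locus_id best_variant       beta      p_perm         fdr is_eherv
 HERV_00000001     var_1_13  0.9051897 0.000999001 0.003330003     TRUE
 HERV_00000002     var_2_13  0.9606365 0.000999001 0.003330003     TRUE
 HERV_00000003     var_3_13  1.3837832 0.000999001 0.003330003     TRUE
 HERV_00000004     var_4_10 -0.3681563 0.471528472 0.523920524    FALSE
 ...
```

The three planted loci are called eHERVs at the permutation floor
1/(1+1000), each at its true causal variant (`var_i_13`, the middle cis
variant), with effect estimates near the planted β = 1; the null loci
stay uncalled.

A complete file-based pipeline (simulate → detect → classify → quantify
→ qtl → epi → factors), with per-stage JSON manifests and deterministic
outputs, runs via:

```r
herv_run("all", run_config(out = "run1", seed = 5))
```

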