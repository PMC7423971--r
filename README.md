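# tcrlens

Case-control analysis of T cell receptor beta-chain (TCRβ) CDR3
repertoires, from raw reads to a cross-validated classifier — plus a
V(D)J recombination cohort simulator so every stage is testable without
access to patient sequencing data.

**Who it is for:** researchers comparing bulk TCRβ CDR3 amplicon
repertoires between a case group and a control group (for example an
autoimmune cohort vs healthy donors) who want a small, fully reproducible
pipeline with planted-truth validation.

## What it computes

A T cell clone is identified by its rearranged CDR3 junction: the
nucleotide stretch from the V segment's second conserved cysteine (2nd-CYS)
codon through the J segment's F/W codon of the FGXG motif, keyed as
(V gene, J gene, junction). Given per-sample FASTQ files and a germline
V/J reference, `tcrlens`:

* assigns germline V and J genes by Smith–Waterman local alignment
  (affine gaps; match +2, mismatch −2, gap open −4, extend −1) and
  extracts the junction between the anchors mapped through the alignment;
* builds clonotype tables (productive reads only: in frame, stop-free,
  C…F/W) and per-sample statistics — **D50** (the percentage of ranked
  unique clones whose cumulative reads reach 50% of the sample; lower =
  more clonally expanded), a four-bin clonal abundance partition
  (< 0.001%, 0.001–0.005%, > 0.005% below the top 100, top 100 clones),
  CDR3 length, amino-acid composition, and Hopp–Woods hydrophilicity;
* forms the samples × V–J-combination matrix (reads per million),
  detects **asymmetric combinations** (positive in ≥ 3 samples of one
  group, zero of the other), runs Welch t tests, chi-square, PCA, and
  PERMANOVA (Bray–Curtis, permutation or exhaustive null);
* classifies case vs control with a **leave-one-out cross-validated
  random forest** (500 trees, `mtry = √p`, implemented in C++), reporting
  pooled out-of-fold AUC = P(random case outscores random control), a
  stratified bootstrap 95% CI, and impurity-based importance of the
  signature V–J combinations.

The simulator (`cohort_spec()`, `simulate_cohort()`) generates cohorts
with power-law clone abundances, case-specific clonal expansion,
group-exclusive spiked V–J combinations, V(D)J trims and N-inserts, and
per-base sequencing errors — emitting FASTQ plus full ground truth, all
byte-reproducible from one seed.

## Worked example

```r
library(tcrlens)

ref  <- mini_reference(20, 13, seed = 7)          # bundled synthetic germline
spec <- cohort_spec(n_cases = 10, n_controls = 10,
                    clones_per_sample = 1000, reads_per_sample = 20000,
                    expansion_boost = 3, error_rate = 0,
                    spiked_combinations = signature_spikes(1e-3), seed = 5)
sim  <- simulate_cohort(spec, ref, "cohort/")

reps <- lapply(seq_len(nrow(sim$metadata)), function(i)
  build_repertoire(sim$metadata$fastq[i], ref,
                   sample_id = sim$metadata$sample_id[i],
                   group     = sim$metadata$group[i]))

st <- repertoire_stats(reps)
aggregate(d50_vj ~ group, st, mean)
#>     group   d50_vj
#> 1    case 3.606229
#> 2 control 6.967291

m <- build_vj_matrix(reps)
nrow(detect_asymmetric(m))            # recovers all 21 planted combinations
#> [1] 21
permanova(m, n_perm = 999, seed = 1)$p
#> [1] 0.017

loocv_classify(m, seed = 1, features = "asymmetric")
#> loocv_result: AUC 0.920 (95% CI 0.730-1.000), 20 samples, 500 trees
```

Reading this: cases show roughly half the V–J-level D50 of controls
(clonal expansion), the 21 group-exclusive combinations planted by the
simulator are all detected with zero false positives, PERMANOVA rejects
exchangeability of the V–J usage profiles at p = 0.017, and the
signature-combination classifier separates the groups well — with the CI
reminding you how wide AUC uncertainty is at n = 20.

One-command version of the above, printing the AUC and D50 comparison:

```r
tcrlens_demo("demo/", seed = 1)
```

## Command line

```sh
tcrlens ref make-mini --n-v 20 --n-j 13 --seed 7 -o mini.fasta
tcrlens simulate --spec spec.json --ref mini.fasta -o cohort/
tcrlens annotate --ref mini.fasta --in cohort/fastq/case01.fastq \
                 --out case01.airr.tsv --clonotypes case01.clonotypes.csv
tcrlens stats    --in 'clonotypes/*.csv' --meta cohort/metadata.csv -o stats/
tcrlens compare  --in 'clonotypes/*.csv' --meta cohort/metadata.csv -o compare/
tcrlens classify --matrix compare/vj_matrix.csv -o clf/
tcrlens run --config run.json
tcrlens demo -o demo/
```

The `tcrlens` executable is installed under `exec/` in the package
library; equivalently call `tcrlens_main(c("demo", "-o", "demo/"))` from R.

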