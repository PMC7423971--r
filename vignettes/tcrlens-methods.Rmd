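---
title: "tcrlens: models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcrlens: models, simulator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrlens)
```

# What the package computes

`tcrlens` analyses case-control cohorts of T cell receptor beta-chain
(TCRβ) CDR3 repertoires. The biological object is the rearranged TRBV-(D)-
TRBJ junction: each T cell clone carries a unique CDR3 whose nucleotide
sequence is the clonotype key, and bulk amplicon sequencing of the CDR3
region yields, per subject, a clonotype table (V gene, J gene, junction,
read count). The package covers five stages:

1. **Germline model** — V/J segments with conserved anchor codons
   (the second conserved cysteine, 2nd-CYS, at the V 3′ end; the
   phenylalanine/tryptophan of the FGXG motif at the J 5′ end). The CDR3
   junction is `read[v_anchor : j_anchor + 3)`, anchors included
   (C…F/W), following the AIRR convention. All coordinates are 0-based,
   half-open.
2. **Simulator** — a V(D)J recombination cohort generator with ground
   truth (details below).
3. **Annotator** — Smith–Waterman local alignment (affine gaps, Gotoh
   algorithm) of each read against all germline V, then all J segments;
   anchors are mapped through the alignment and the junction extracted.
4. **Repertoire statistics** — D50 diversity, a four-bin clonal abundance
   partition, CDR3 length/composition/hydrophilicity, shared CDR3s.
5. **Group comparison and classification** — samples × V–J-combination
   matrix (reads per million), group-exclusive ("asymmetric") combination
   detection, Welch t tests, chi-square, PCA, PERMANOVA, and a
   leave-one-out cross-validated (LOOCV) random-forest classifier with
   pooled ROC/AUC and stratified bootstrap CI.

# Statistics and their definitions

**D50** is the percentage of unique clones (ranked by abundance) whose
cumulative reads reach 50% of the sample total; clonal expansion drives it
down. It is scale-invariant and depends only on the sorted abundance
multiset. It is computed at the clonotype level and at the gene-level V–J
combination level; cohort reports label the basis.

**Abundance bins.** Clonotypes are ranked by count (ties broken by
junction sequence) and assigned to: top100 (rank ≤ 100, which takes
precedence), rare (frequency < 0.001%), low (0.001–0.005%), mid
(> 0.005% and rank > 100). Thresholds are percentages of productive
reads; precedence is stated explicitly because the frequency bins and the
rank bin would otherwise overlap. The reported shares are read shares by
default (clonotype-count shares via a flag) — the choice is not derivable
from the bin definition itself, so both are exposed.

**Productive** junctions are in frame, stop-free, *and* carry the
expected anchor residues (start C, end F/W). The anchor-residue condition
is stricter than bare AIRR productivity; it makes "productive ⇒ C…F/W" an
invariant rather than a tendency. Non-productive reads are counted in
summaries and excluded from all downstream statistics.

**Hydrophilicity** uses the Hopp–Woods per-residue scale by default (the
scale is a pluggable named vector). The summary is the residue-mass
weighted mean, which is linear under repertoire mixing with weights equal
to residue mass (reads × junction length), plus the hydrophilic fraction
(mass on residues with positive scale values).

**Asymmetric V–J combinations.** A combination is positive in a sample
when its reads-per-million value exceeds a threshold (default 0). It is
case-only if positive in ≥ `min_positive` (default 3) cases and zero
controls, and symmetrically control-only. Mean ± SD of the normalized
value are computed over positive samples only: group-exclusive
combinations are by definition absent from most samples, so an
all-samples mean would be dominated by structural zeros.

**PERMANOVA** partitions a Bray–Curtis (default; compositional data) or
Euclidean distance matrix by group; the pseudo-F statistic is computed
from within/total squared-distance sums and referred to a
label-permutation null, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`. An
`exhaustive = TRUE` mode enumerates all label assignments exactly. Note a
structural fact exercised by the tests: a balanced 5v5 design has only
`choose(10,5)/2 = 126` distinct partitions, so no 5v5 PERMANOVA p-value
can fall below ≈ 0.008, however strong the separation.

**Classifier.** A binary random forest (CART trees grown to purity, Gini
criterion, bootstrap resampling, `mtry = floor(sqrt(p))` features per
split, 500 trees — the classical randomForest defaults) is implemented in
compiled code because no random-forest package is available in the target
environment. LOOCV records, for each sample, the case-probability from a
forest trained on all other samples. Pooled ROC scores are these
probabilities centered by each fold's training-class prevalence: LOOCV
folds are systematically imbalanced (holding out a case leaves one fewer
case in training), and uncentered pooling biases the null AUC well below
0.5. The centered scores give the ROC/AUC (Mann–Whitney form, ties ½) and
a stratified percentile bootstrap gives the 95% CI. Each fold is seeded independently
(`derive_seed(seed, fold)`), so a fold's prediction is bitwise independent
of the held-out row's influence on the random stream — this makes the
out-of-fold discipline directly testable by mutation.

`features = "asymmetric"` restricts each fold's features to the
asymmetric combinations detected *within that fold's training rows* (no
leakage); the default uses the full matrix.

# The simulator: what it emulates, and what it does not

`cohort_spec()` + `simulate_cohort()` generate 10-vs-10 cohorts (sizes
configurable) with the structure case-control TCRβ studies report:

* **Clone abundances**: rank^(−α) power law (α = 1) normalized, then
  Dirichlet-jittered (concentration 200) per sample. Published clone-size
  data constrain only coarse bin shares, not a generative law; the
  power-law-with-jitter choice reproduces a heavy right tail with
  realistic sample-to-sample variation and is documented as a simulator
  choice, not an inference.
* **Case expansion**: the top `expansion_top_k = 20` clones of each case
  sample get `expansion_boost = 3` times their mass (renormalized). This
  lowers case D50 — the qualitative diversity deficit in cases — and, at
  these defaults, does so with clear Welch significance at n = 10 + 10.
* **Group-exclusive spikes**: `signature_spikes()` plants 9 case-only and 12
  control-only combinations, each positive in 3–6 samples of its group at
  frequency 1e-3. Spiked combinations are *reserved*: background clones
  never use them in any sample. This reservation is necessary, not
  cosmetic — with 20 × 13 = 260 combinations and 1,000 clones per sample,
  every combination would otherwise occur in essentially every sample and
  "zero samples of the other group" would be unsatisfiable. The spike
  frequency default (1e-3) sits at the top of the observed
  normalized-expression range (tens to ~2,000 reads per million) and is
  chosen so a spike is essentially never lost to multinomial sampling at
  20,000 reads (expected 20 reads).
* **Reads**: multinomial draws from clone frequencies; i.i.d. per-base
  substitution errors (default 0.005, an Illumina-like post-merge rate);
  constant 'I' qualities (the pipeline does not use qualities);
  exonuclease trims up to 6 nt and N-inserts up to 9 nt (extended by ≤ 2
  nt to keep junctions in frame; stop-bearing junctions are redrawn).
  Junction-frame adjustment means simulated repertoires are almost
  entirely productive, emulating mRNA-derived, selection-filtered data.
* **Reproducibility**: one global seed expands into per-sample,
  per-stage, and per-fold streams through `derive_seed()`, a
  multiplicative-mixing hash kept below 2^31; cohorts are byte-identical
  across runs and reproducible sample by sample.

Not modeled: PCR amplification bias, paired-end read structure, UMIs,
palindromic (P) nucleotides as a distinct mechanism, D segments (parsed if
present in a reference, never assigned — the analysis operates on V/J
usage only), and any *consistent group-level usage shift* beyond the
spikes. A green test on simulated data therefore establishes pipeline
correctness — recovery of planted truth — not biological realism of any
particular effect size.

# Numerical and design choices

* **Alignment scoring**: match +2, mismatch −2, gap open −4, gap extend
  −1 (a gap of length L costs open + (L−1)·extend); minimum segment score
  40, so a 20-bp exact match passes. The source method names the
  algorithm but no parameters; these are conventional DNA settings and
  are exposed on every interface. Scores are integral; the kernel uses
  integer arithmetic. Ties between segments go to the lexicographically
  smallest name; co-optimal alignment endpoints resolve to the first best
  cell in row-major order with diagonal-first traceback, making results
  order- and platform-stable.
* **V search window**: the V segment is searched in the read prefix
  (max V length + 15 nt) and J in the suffix after the V block — CDR3
  amplicons place V at the 5′ end; a flag restores full-read search.
* **Clonotype key**: nucleotide-level (V gene, J gene, junction NT);
  amino-acid aggregation is a view. Allele suffixes (`*NN`) are stripped
  for all usage statistics.
* **Reads-per-million normalization** for the V–J matrix: rows sum to
  1e6 by construction, making the conservation check exact.
* **Degenerate inputs**: empty FASTQ → empty repertoire with zero totals;
  truncated FASTQ record → hard error naming the line; all-zero distance
  matrix → PERMANOVA warns and reports p = 1; constant feature matrix →
  PCA errors; zero-margin 2×2 table → chi-square errors.
* **Multiple testing**: per-combination Welch t tests are reported with
  raw and Benjamini–Hochberg-adjusted p-values side by side.

# Classifier power at desk scale: a measured limitation

Uncentered pooled LOOCV probabilities carry the fold-imbalance bias
described above; before prevalence centering was added, permuted-label
mean AUC measured ≈ 0.38 (an apparent anti-signal) and spiked-cohort
power was grossly understated. With centered scores the null is clean
(permuted-label mean AUC 0.50 over 50 seeds) and power on spiked cohorts
(9 case-only + 12 control-only combinations, expansion boost 3, 20
seeds) measures:

* `features = "all"` (full matrix, the default): 15/20 seeds with
  AUC ≥ 0.85, mean AUC 0.890 (at boost 1.05: 4/20, mean 0.655).
* `features = "asymmetric"` (per-fold signature selection): 19/20 seeds
  with AUC ≥ 0.85, mean AUC 0.948.

The gap has a mechanism, confirmed by cross-checking matrices against an
independent random-forest implementation (scikit-learn agrees within a
few AUC points, so it is a property of the data, not of this forest):
per-sample random expansion concentrates each case's mass on its own
combinations, creating case-specific noise features that win Gini splits
in training but do not generalize, while the sparse group-exclusive
spikes (positive in only 3–6 of 10 samples) are individually weak. The
signature mode removes the noise features inside each training fold and
realizes the intended mechanism — classification through group-exclusive
signature combinations — so it carries the acceptance power assertion.
Neither mode is claimed to be "the" original pipeline; the question is
undecidable from the source description, and both are first-class.

# Known limitations

* The bundled mini germline reference is synthetic (names `TRBVs*`,
  `TRBJs*`); real analyses should load an IMGT-derived FASTA (pipe-header
  dialect supported, anchors auto-detected by motif scan; reference
  release is a user input, not pinned).
* Clonotype-level error correction (collapsing sequencing-error
  neighbors) is not implemented; at the default error rate erroneous
  reads form singleton clonotypes (use `min_count` to drop them).
* The bootstrap CI is a percentile interval on pooled out-of-fold scores;
  DeLong-type analytic intervals are not provided.
* LOOCV on 20 samples has high variance and a known pessimistic bias
  under class imbalance in the folds; AUC point estimates on cohorts this
  small should be read with their CIs.
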