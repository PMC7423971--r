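# Shared fixtures, built once per test run and cached. The full-size
# cohorts match the acceptance-scale stated world: 10 vs 10 samples,
# 1,000 clones and 20,000 reads per sample, expansion boost 3 on the top
# 20 clones, and the 9 + 12 group-exclusive spiked combinations.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_ref <- function() cached("ref", function() mini_reference(20, 13, seed = 7))

acc_spec <- function(error_rate, seed = 42) {
  cohort_spec(n_cases = 10, n_controls = 10, clones_per_sample = 1000,
              reads_per_sample = 20000, expansion_boost = 3,
              expansion_top_k = 20, error_rate = error_rate,
              spiked_combinations = signature_spikes(1e-3), seed = seed)
}

# error-free cohort: FASTQ on disk + per-sample annotations + repertoires
acc_cohort_errfree <- function() cached("cohort0", function() {
  ref <- fix_ref()
  spec <- acc_spec(error_rate = 0)
  dir <- file.path(tempdir(), "acc_cohort0")
  sim <- simulate_cohort(spec, ref, dir)
  anns <- lapply(seq_len(nrow(sim$metadata)), function(i)
    annotate_fastq(sim$metadata$fastq[i], ref))
  names(anns) <- sim$metadata$sample_id
  reps <- lapply(seq_len(nrow(sim$metadata)), function(i)
    build_repertoire(anns[[i]], sample_id = sim$metadata$sample_id[i],
                     group = sim$metadata$group[i]))
  list(spec = spec, sim = sim, anns = anns, reps = reps)
})

# per-read gene-level V/J recovery rate against ground truth (all reads in
# the denominator; a missing call counts as a miss)
recovery_rate <- function(sim, anns) {
  truth_genes <- sim$truth[, c("clone_id", "v_gene", "j_gene")]
  hits <- 0; total <- 0
  for (sid in names(anns)) {
    ann <- anns[[sid]]
    x <- merge(ann, sim$read_truth, by.x = "sequence_id", by.y = "read_id")
    x <- merge(x, truth_genes, by = "clone_id")
    ok <- !is.na(x$v_call) & !is.na(x$j_call) &
      x$v_call == x$v_gene & x$j_call == x$j_gene
    hits <- hits + sum(ok); total <- total + nrow(x)
  }
  hits / total
}
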