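#' Cohort simulation parameters
#'
#' Describes a synthetic case-control TCR-beta repertoire cohort: sample
#' counts per group, clones and reads per sample, a power-law clone-abundance
#' model with Dirichlet jitter, case-specific clonal expansion (mass boost on
#' the top-ranked clones, the pattern behind a depressed D50 in cases),
#' group-exclusive spiked V-J combinations, and a per-base substitution
#' error rate.
#'
#' @param n_cases,n_controls samples per group.
#' @param clones_per_sample clones simulated per sample.
#' @param reads_per_sample reads drawn (multinomially) per sample.
#' @param abundance_alpha power-law exponent for clone frequencies
#'   (`rank^-alpha`, normalized); larger values give heavier tails.
#' @param dirichlet_conc Dirichlet concentration for per-sample jitter around
#'   the power-law profile; `Inf` disables jitter.
#' @param expansion_boost multiplicative mass factor applied to the top
#'   `expansion_top_k` clones of each case sample (then renormalized);
#'   `1` makes the groups exchangeable.
#' @param expansion_top_k number of top clones boosted in cases.
#' @param spiked_combinations `NULL` or a data.frame with columns `v_gene`,
#'   `j_gene`, `group` (`"case"`/`"control"`), `n_positive`, `frequency`:
#'   each combination is planted at the given per-sample frequency in exactly
#'   `n_positive` samples of its group and excluded from the background
#'   repertoire of every sample, so it occurs in zero samples of the other
#'   group.
#' @param error_rate per-base substitution probability in `[0, 0.1)`.
#' @param trim_max maximum 3'V / 5'J exonuclease deletion (nt).
#' @param insert_max maximum N-region insertion length (nt); actual inserts
#'   may exceed this by up to 2 nt to keep junctions in frame.
#' @param seed integer global seed; expanded into per-sample streams via
#'   [derive_seed()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 10, n_controls = 10,
                        clones_per_sample = 1000, reads_per_sample = 20000,
                        abundance_alpha = 1, dirichlet_conc = 200,
                        expansion_boost = 3, expansion_top_k = 20,
                        spiked_combinations = NULL, error_rate = 0.005,
                        trim_max = 6, insert_max = 9, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, clones_per_sample >= 1,
            reads_per_sample >= 1, expansion_top_k >= 1,
            expansion_boost > 0, abundance_alpha > 0, dirichlet_conc > 0,
            error_rate >= 0, error_rate < 0.1, trim_max >= 0, insert_max >= 0)
  if (!is.null(spiked_combinations)) {
    spk <- as.data.table(spiked_combinations)
    need <- c("v_gene", "j_gene", "group", "n_positive", "frequency")
    if (!all(need %in% names(spk)))
      stop("spiked_combinations needs columns: ", paste(need, collapse = ", "))
    if (!all(spk$group %in% c("case", "control")))
      stop("spike group must be 'case' or 'control'")
    gsize <- ifelse(spk$group == "case", n_cases, n_controls)
    if (any(spk$n_positive > gsize))
      stop("spike n_positive exceeds group size")
    if (any(spk$frequency <= 0 | spk$frequency >= 1))
      stop("spike frequency must be in (0, 1)")
    spiked_combinations <- spk[]
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    clones_per_sample = as.integer(clones_per_sample),
    reads_per_sample = as.integer(reads_per_sample),
    abundance_alpha = abundance_alpha, dirichlet_conc = dirichlet_conc,
    expansion_boost = expansion_boost,
    expansion_top_k = as.integer(expansion_top_k),
    spiked_combinations = spiked_combinations,
    error_rate = error_rate, trim_max = as.integer(trim_max),
    insert_max = as.integer(insert_max), seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Join a V and a J segment into a rearranged sequence
#'
#' Returns `V[0 : len(V) - trim_v] + n_insert + J[trim_j :]` (0-based,
#' half-open). The anchor codons are always retained: trims that would
#' delete the V 2nd-CYS codon or reach past the J anchor are an error.
#'
#' @param v,j single rows of a [germline_reference] segment table (anything
#'   list-like with `sequence` and `anchor`).
#' @param trim_v,trim_j number of bases removed from the V 3' end / J 5' end.
#' @param n_insert N-region DNA string (possibly empty).
#' @return the recombined DNA string.
#' @export
recombine <- function(v, j, trim_v = 0, trim_j = 0, n_insert = "") {
  lv <- nchar(v$sequence)
  if (trim_v < 0 || trim_v > lv - v$anchor - 3L)
    stop("trim_v would delete the V anchor codon")
  if (trim_j < 0 || trim_j > j$anchor)
    stop("trim_j would delete the J anchor codon")
  paste0(substr(v$sequence, 1L, lv - trim_v), n_insert,
         substr(j$sequence, trim_j + 1L, nchar(j$sequence)))
}

#' Power-law clone frequencies with Dirichlet jitter
#'
#' Base profile `rank^-alpha` (normalized), optionally jittered by a
#' Dirichlet draw with concentration `conc` (shape `conc * base`). Uses the
#' current RNG state.
#'
#' @param n_clones number of clones.
#' @param alpha power-law exponent (>= 0; 0 with `conc = Inf` is uniform).
#' @param conc Dirichlet concentration; `Inf` disables jitter.
#' @return a positive frequency vector summing to 1.
#' @export
sample_abundances <- function(n_clones, alpha, conc = Inf) {
  stopifnot(n_clones >= 1, alpha >= 0)
  base <- seq_len(n_clones)^(-alpha)
  base <- base / sum(base)
  if (!is.finite(conc)) return(base)
  g <- rgamma(n_clones, shape = base * conc, rate = 1)
  g <- pmax(g, .Machine$double.xmin)
  g / sum(g)
}

# sample IDs: case01..caseNN, ctrl01..ctrlNN
cohort_sample_ids <- function(spec) {
  data.table(
    sample_id = c(sprintf("case%02d", seq_len(spec$n_cases)),
                  sprintf("ctrl%02d", seq_len(spec$n_controls))),
    group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  )
}

# vectorized clone construction: trims, in-frame N-inserts (stop-bearing
# junctions redrawn), full sequence + junction per clone
make_clones <- function(vseg, jseg, vi, ji, trim_max, insert_max) {
  n <- length(vi)
  lv <- nchar(vseg$sequence)[vi]; av <- vseg$anchor[vi]
  aj <- jseg$anchor[ji]; jq <- jseg$sequence[ji]
  vq <- vseg$sequence[vi]
  trim_v <- floor(runif(n) * (pmin(trim_max, lv - av - 3L) + 1L))
  trim_j <- floor(runif(n) * (pmin(trim_max, aj) + 1L))
  v_part <- lv - av - trim_v
  j_part <- aj - trim_j + 3L
  vcut <- substr(vq, 1L, lv - trim_v)
  jcut <- substring(jq, trim_j + 1L)
  seqs <- character(n); junction <- character(n)
  todo <- seq_len(n)
  for (try in 1:20) {
    k <- length(todo)
    n_ins <- floor(runif(k) * (insert_max + 1L))
    n_ins <- n_ins + (3L - (v_part[todo] + n_ins + j_part[todo]) %% 3L) %% 3L
    pool <- paste(sample(c("A", "C", "G", "T"), sum(n_ins) + 1L,
                         replace = TRUE), collapse = "")
    ends <- cumsum(n_ins)
    ins <- substring(pool, ends - n_ins + 1L, ends)
    seqs[todo] <- paste0(vcut[todo], ins, jcut[todo])
    junction[todo] <- substr(seqs[todo], av[todo] + 1L,
                             lv[todo] - trim_v[todo] + n_ins +
                               (aj[todo] - trim_j[todo]) + 3L)
    aa <- translate_dna(junction[todo])
    bad <- is.na(aa) | grepl("*", aa, fixed = TRUE)
    if (!any(bad)) break
    todo <- todo[bad]
  }
  list(sequence = seqs, junction_nt = junction)
}

# one clone: pick trims and an in-frame, stop-free junction
make_clone <- function(v, j, trim_max, insert_max) {
  tv_max <- min(trim_max, nchar(v$sequence) - v$anchor - 3L)
  tj_max <- min(trim_max, j$anchor)
  trim_v <- sample.int(tv_max + 1L, 1L) - 1L
  trim_j <- sample.int(tj_max + 1L, 1L) - 1L
  v_part <- nchar(v$sequence) - v$anchor - trim_v       # from anchor to cut
  j_part <- j$anchor - trim_j + 3L                      # from cut through anchor codon
  for (try in 1:20) {
    n_ins <- sample.int(insert_max + 1L, 1L) - 1L
    n_ins <- n_ins + (3L - (v_part + n_ins + j_part) %% 3L) %% 3L
    ins <- if (n_ins > 0L) random_dna(n_ins) else ""
    seqr <- recombine(v, j, trim_v, trim_j, ins)
    jstart <- v$anchor + 1L
    jend <- nchar(v$sequence) - trim_v + n_ins + (j$anchor - trim_j) + 3L
    junction <- substr(seqr, jstart, jend)
    aa <- translate_dna(junction)
    if (!is.na(aa) && !grepl("\\*", aa)) break
  }
  list(sequence = seqr, junction_nt = junction)
}

#' Simulate cohort ground truth (clone tables, no reads)
#'
#' Generates the per-sample clone tables of a cohort: V/J gene choice
#' (uniform over the reference, excluding all spiked combinations), junction
#' construction via [recombine()], power-law + Dirichlet abundances, case
#' expansion, and group-exclusive spikes. Fully reproducible from
#' `spec$seed`, sample by sample.
#'
#' @param spec a [cohort_spec].
#' @param ref a [germline_reference].
#' @return a `data.table` with columns `sample_id`, `group`, `clone_id`,
#'   `v_gene`, `j_gene`, `sequence` (full rearranged read template),
#'   `junction_nt`, `true_freq` (summing to 1 per sample).
#' @export
simulate_truth <- function(spec, ref) {
  vseg <- v_segments(ref)
  jseg <- j_segments(ref)
  spk <- spec$spiked_combinations
  if (!is.null(spk)) {
    miss_v <- setdiff(spk$v_gene, vseg$gene)
    miss_j <- setdiff(spk$j_gene, jseg$gene)
    if (length(miss_v) || length(miss_j))
      stop("spiked genes absent from reference: ",
           paste(c(miss_v, miss_j), collapse = ", "))
    if (any(spk$frequency * spec$reads_per_sample < 1))
      warning("spike frequency x reads_per_sample < 1: spike may be unseen in reads")
  }
  reserved <- if (is.null(spk)) character(0) else
    unique(paste(spk$v_gene, spk$j_gene, sep = "|"))
  meta <- cohort_sample_ids(spec)

  # deterministic, cohort-level choice of spike-positive samples
  spike_assign <- NULL
  if (!is.null(spk)) {
    spike_assign <- with_seed(derive_seed(spec$seed, 555L), {
      rbindlist(lapply(seq_len(nrow(spk)), function(k) {
        pool <- meta$sample_id[meta$group == spk$group[k]]
        data.table(spike = k, sample_id = sample(pool, spk$n_positive[k]))
      }))
    })
  }

  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    grp <- meta$group[i]
    out[[i]] <- with_seed(derive_seed(spec$seed, 1000L + i), {
      nc <- spec$clones_per_sample
      vi <- sample.int(nrow(vseg), nc, replace = TRUE)
      ji <- sample.int(nrow(jseg), nc, replace = TRUE)
      if (length(reserved)) {
        repeat {
          bad <- paste(vseg$gene[vi], jseg$gene[ji], sep = "|") %in% reserved
          if (!any(bad)) break
          vi[bad] <- sample.int(nrow(vseg), sum(bad), replace = TRUE)
          ji[bad] <- sample.int(nrow(jseg), sum(bad), replace = TRUE)
        }
      }
      clones <- make_clones(vseg, jseg, vi, ji, spec$trim_max, spec$insert_max)
      freq <- sample_abundances(nc, spec$abundance_alpha, spec$dirichlet_conc)
      freq <- sort(freq, decreasing = TRUE)
      if (grp == "case" && spec$expansion_boost != 1) {
        k <- min(spec$expansion_top_k, nc)
        freq[seq_len(k)] <- freq[seq_len(k)] * spec$expansion_boost
        freq <- freq / sum(freq)
      }
      dt <- data.table(
        sample_id = sid, group = grp,
        clone_id = sprintf("%s_c%04d", sid, seq_len(nc)),
        v_gene = vseg$gene[vi], j_gene = jseg$gene[ji],
        sequence = clones$sequence,
        junction_nt = clones$junction_nt,
        true_freq = freq)
      # spikes for this sample
      if (!is.null(spike_assign)) {
        mine <- spike_assign[spike_assign$sample_id == sid]
        if (nrow(mine)) {
          srows <- lapply(mine$spike, function(k) {
            v <- vseg[vseg$gene == spk$v_gene[k]][1]
            j <- jseg[jseg$gene == spk$j_gene[k]][1]
            cl <- make_clone(v, j, spec$trim_max, spec$insert_max)
            data.table(sample_id = sid, group = grp,
                       clone_id = sprintf("%s_spike%02d", sid, k),
                       v_gene = v$gene, j_gene = j$gene,
                       sequence = cl$sequence, junction_nt = cl$junction_nt,
                       true_freq = spk$frequency[k])
          })
          srows <- rbindlist(srows)
          dt[, true_freq := true_freq * (1 - sum(srows$true_freq))]
          dt <- rbindlist(list(dt, srows))
        }
      }
      dt
    })
  }
  rbindlist(out)
}

# multinomial read counts for one sample's truth table
draw_clone_counts <- function(truth_sample, reads_per_sample) {
  as.integer(rmultinom(1, reads_per_sample, truth_sample$true_freq))
}

#' Build in-memory repertoires directly from ground truth
#'
#' The fast statistical path: per-sample clone read counts are drawn
#' multinomially from the true frequencies and aggregated straight into
#' [repertoire_sample] objects, bypassing read generation and alignment
#' (equivalent to the full pipeline at `error_rate = 0` up to annotation).
#' Used for calibration studies where many cohorts are needed.
#'
#' @param truth output of [simulate_truth()].
#' @param spec the matching [cohort_spec].
#' @return a list of [repertoire_sample] objects, one per sample.
#' @export
truth_to_repertoires <- function(truth, spec) {
  meta <- cohort_sample_ids(spec)
  lapply(seq_len(nrow(meta)), function(i) {
    ts <- truth[truth$sample_id == meta$sample_id[i]]
    counts <- with_seed(derive_seed(spec$seed, 2000L + i),
                        draw_clone_counts(ts, spec$reads_per_sample))
    keep <- counts > 0L
    cl <- data.table(v_gene = ts$v_gene[keep], j_gene = ts$j_gene[keep],
                     junction_nt = ts$junction_nt[keep],
                     count = counts[keep])
    cl <- cl[, .(count = sum(count)), by = .(v_gene, j_gene, junction_nt)]
    cl[, junction_aa := translate_dna(junction_nt)]
    repertoire_sample(meta$sample_id[i], meta$group[i], cl,
                      total_reads = spec$reads_per_sample,
                      annotated_reads = sum(cl$count))
  })
}

#' Simulate a cohort to FASTQ with ground truth on disk
#'
#' Renders [simulate_truth()] into per-sample single-end FASTQ files:
#' multinomial read counts per clone, i.i.d. per-base substitution errors at
#' `spec$error_rate`, constant `'I'` (Phred 40) qualities. Writes
#' `fastq/<sample>.fastq`, `metadata.csv` (sample_id, group, fastq),
#' `truth_clones.tsv`, `truth_reads.tsv` (read id to clone id) and
#' `spec.json`. Byte-identical across runs for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @param ref a [germline_reference].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `metadata`, `truth`, `fastq` (named paths)
#'   and `spec`.
#' @export
simulate_cohort <- function(spec, ref, out_dir) {
  dir.create(file.path(out_dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(spec, ref)
  meta <- cohort_sample_ids(spec)
  fq_paths <- character(nrow(meta))
  read_truth <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    ts <- truth[truth$sample_id == sid]
    recs <- with_seed(derive_seed(spec$seed, 2000L + i), {
      counts <- draw_clone_counts(ts, spec$reads_per_sample)
      seqs <- rep(ts$sequence, counts)
      clones <- rep(ts$clone_id, counts)
      if (spec$error_rate > 0)
        seqs <- mutate_reads_cpp(seqs, spec$error_rate)
      list(seqs = seqs, clones = clones)
    })
    ids <- sprintf("%s_r%06d", sid, seq_along(recs$seqs))
    read_truth[[i]] <- data.table(read_id = ids, clone_id = recs$clones)
    fq <- file.path(out_dir, "fastq", paste0(sid, ".fastq"))
    writeLines(paste0("@", ids, " clone=", recs$clones, "\n", recs$seqs,
                      "\n+\n", strrep("I", nchar(recs$seqs))), fq)
    fq_paths[i] <- fq
  }
  names(fq_paths) <- meta$sample_id
  meta_out <- data.table(meta, fastq = fq_paths)
  fwrite(meta_out, file.path(out_dir, "metadata.csv"))
  fwrite(truth, file.path(out_dir, "truth_clones.tsv"), sep = "\t")
  fwrite(rbindlist(read_truth), file.path(out_dir, "truth_reads.tsv"), sep = "\t")
  spec_json <- spec
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(metadata = meta_out, truth = truth, fastq = fq_paths,
                 read_truth = rbindlist(read_truth), spec = spec))
}
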