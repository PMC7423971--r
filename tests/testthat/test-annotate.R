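test_that("smith_waterman: exact substring and self-alignment", {
  hit <- smith_waterman("ACGT", "GGGACGTGGG")
  expect_equal(hit$score, 8)
  expect_equal(hit$seg_start, 3L)
  expect_equal(hit$seg_end, 7L)
  expect_equal(hit$read_start, 0L)
  expect_equal(hit$read_end, 4L)
  set.seed(4)
  for (len in c(1, 7, 25)) {
    s <- random_dna_str(len)
    expect_equal(smith_waterman(s, s)$score, 2 * len)
  }
})

test_that("smith_waterman agrees with the brute-force DP oracle", {
  set.seed(20)
  for (rep in 1:60) {
    q <- random_dna_str(sample(1:30, 1))
    t <- random_dna_str(sample(1:30, 1))
    expect_equal(smith_waterman(q, t)$score, sw_oracle_score(q, t),
                 info = paste(q, t))
  }
  # and under a different scoring scheme
  sc <- default_scoring(3, -1, -5, -2)
  for (rep in 1:20) {
    q <- random_dna_str(sample(2:20, 1))
    t <- random_dna_str(sample(2:20, 1))
    expect_equal(smith_waterman(q, t, sc)$score,
                 sw_oracle_score(q, t, 3, -1, -5, -2))
  }
})

test_that("assign_segment: winner, tie rule, and min_score", {
  ref <- fix_ref()
  vseg <- v_segments(ref)
  read <- paste0(substr(vseg$sequence[4], 1, 40), "ACGTACGTAC")
  hit <- assign_segment(read, vseg)
  expect_equal(hit$segment_name, vseg$name[4])
  # identical segments under different names: smallest name wins
  twins <- data.table::data.table(
    name = c("TRBVzz", "TRBVaa"), segment_type = "V",
    sequence = vseg$sequence[1], anchor = vseg$anchor[1], gene = "x")
  expect_equal(assign_segment(vseg$sequence[1], twins)$segment_name, "TRBVaa")
  # unattainable threshold
  expect_null(assign_segment("ACGTACGTAC", vseg, min_score = 1000))
})

test_that("extract_junction reconstructs the recombined junction", {
  ref <- fix_ref()
  v <- v_segments(ref)[2]
  j <- j_segments(ref)[5]
  read <- recombine(v, j, 0, 0, "GGC")
  v_hit <- assign_segment(read, v_segments(ref))
  j_hit <- assign_segment(read, j_segments(ref))
  ann <- extract_junction(read, v_hit, j_hit, ref)
  expected <- paste0(substring(v$sequence, v$anchor + 1), "GGC",
                     substr(j$sequence, 1, j$anchor + 3))
  expect_equal(ann$status, "ok")
  expect_equal(ann$v_call, v$gene)
  expect_equal(ann$j_call, j$gene)
  expect_equal(ann$junction_nt, expected)
  expect_match(ann$junction_aa, "^C.*[FW]$")
  expect_true(ann$productive)
})

test_that("extract_junction flags frame problems and missing anchors", {
  ref <- fix_ref()
  v <- v_segments(ref)[2]
  j <- j_segments(ref)[5]
  # insert of length 1 knocks the junction out of frame
  read <- recombine(v, j, 0, 0, "G")
  ann <- extract_junction(read, assign_segment(read, v_segments(ref)),
                          assign_segment(read, j_segments(ref)), ref)
  expect_equal(ann$status, "unproductive")
  expect_false(ann$productive)
  # J hit whose aligned block stops short of the anchor codon
  read2 <- recombine(v, j, 0, 0, "")
  j_hit <- assign_segment(read2, j_segments(ref))
  j_hit$map <- j_hit$map[j_hit$map[, "seg"] < j_segments(ref)$anchor[5], ,
                         drop = FALSE]
  ann2 <- extract_junction(read2, assign_segment(read2, v_segments(ref)),
                           j_hit, ref)
  expect_equal(ann2$status, "anchor_missing")
  # missing V / J hits
  expect_equal(extract_junction(read2, NULL, j_hit, ref)$status, "no_v")
  expect_equal(extract_junction(read2, assign_segment(read2, v_segments(ref)),
                                NULL, ref)$status, "no_j")
})

test_that("the R per-read route and the C++ batch route agree", {
  ref <- fix_ref()
  spec <- cohort_spec(n_cases = 1, n_controls = 1, clones_per_sample = 30,
                      reads_per_sample = 60, error_rate = 0.01, seed = 77)
  sim <- simulate_cohort(spec, ref, file.path(tempdir(), "sim_agree"))
  fq <- tcrlens:::read_fastq(sim$fastq[[1]])
  batch <- annotate_fastq(sim$fastq[[1]], ref, v_prefix_margin = -1L)
  for (k in sample(nrow(fq), 12)) {
    read <- fq$sequence[k]
    v_hit <- assign_segment(read, v_segments(ref))
    j_hit <- if (is.null(v_hit)) NULL else {
      suffix <- substr(read, v_hit$read_end + 1, nchar(read))
      jh <- assign_segment(suffix, j_segments(ref))
      if (!is.null(jh)) {
        jh$read_start <- jh$read_start + v_hit$read_end
        jh$read_end <- jh$read_end + v_hit$read_end
        jh$map[, "read"] <- jh$map[, "read"] + v_hit$read_end
      }
      jh
    }
    ann <- extract_junction(read, v_hit, j_hit, ref)
    expect_equal(ann$v_call, batch$v_call[k])
    expect_equal(ann$j_call, batch$j_call[k])
    expect_equal(ann$status, batch$status[k])
    if (ann$status == "ok")
      expect_equal(ann$junction_nt, batch$junction[k])
  }
})

test_that("build_repertoire aggregates productive reads into clonotypes", {
  ref <- fix_ref()
  v <- v_segments(ref)[1]
  j <- j_segments(ref)[1]
  r1 <- recombine(v, j, 0, 0, "AAA")
  r2 <- recombine(v_segments(ref)[3], j, 3, 3, "")
  rs <- build_repertoire(c(r1, r1, r2), ref, sample_id = "s1")
  expect_equal(nrow(rs$clonotypes), 2L)
  expect_equal(rs$clonotypes$count[1], 2L)  # sorted by count desc
  expect_equal(sum(rs$clonotypes$frequency), 1, tolerance = 1e-12)
  expect_equal(rs$productive_reads, 3L)
})

test_that("build_repertoire is order-independent", {
  ref <- fix_ref()
  spec <- cohort_spec(n_cases = 1, n_controls = 1, clones_per_sample = 40,
                      reads_per_sample = 400, error_rate = 0.005, seed = 21)
  sim <- simulate_cohort(spec, ref, file.path(tempdir(), "sim_order"))
  fq <- tcrlens:::read_fastq(sim$fastq[[1]])
  a <- build_repertoire(fq$sequence, ref, sample_id = "a")
  set.seed(1)
  b <- build_repertoire(sample(fq$sequence), ref, sample_id = "a")
  expect_equal(a$clonotypes, b$clonotypes)
})

test_that("empty and malformed FASTQ inputs behave as contracted", {
  ref <- fix_ref()
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  rs <- build_repertoire(empty, ref, sample_id = "e")
  expect_equal(rs$total_reads, 0L)
  expect_equal(nrow(rs$clonotypes), 0L)
  trunc <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(annotate_fastq(trunc, ref), "line 5")
})

test_that("AIRR writer emits the contracted columns", {
  ref <- fix_ref()
  v <- v_segments(ref)[1]; j <- j_segments(ref)[1]
  ann <- annotate_fastq(rep(recombine(v, j, 0, 0, ""), 3), ref)
  out <- tempfile(fileext = ".tsv")
  write_airr(ann, out)
  airr <- data.table::fread(out)
  expect_equal(names(airr),
               c("sequence_id", "sequence", "v_call", "j_call", "junction",
                 "junction_aa", "productive", "duplicate_count"))
  expect_equal(airr$duplicate_count, 3L)
})
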