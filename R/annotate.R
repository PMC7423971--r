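#' Default Smith-Waterman scoring parameters
#'
#' match +2, mismatch -2, gap open -4, gap extend -1 (a gap of length L costs
#' `gap_open + (L-1) * gap_extend`). The minimum segment score defaults to
#' 40, so a 20-bp exact match passes.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return a named list of scoring parameters.
#' @export
default_scoring <- function(match = 2, mismatch = -2, gap_open = -4,
                            gap_extend = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  vals <- c(match, mismatch, gap_open, gap_extend)
  if (any(vals != round(vals)))
    stop("scoring parameters must be integer-valued")
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gaps (Gotoh algorithm), computed by
#' the full O(nm) dynamic program. Coordinates are 0-based half-open.
#'
#' @param query read DNA string.
#' @param target segment DNA string.
#' @param scoring a [default_scoring()] list.
#' @return an `alignment_hit`: list with `segment_name` (`NA` here), `score`,
#'   `read_start`, `read_end`, `seg_start`, `seg_end`, and `map` (two-column
#'   matrix of diagonally aligned read/segment positions, 0-based).
#' @export
smith_waterman <- function(query, target, scoring = default_scoring()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  a <- sw_align_cpp(query, target, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  structure(list(segment_name = NA_character_, score = a$score,
                 read_start = a$query_start, read_end = a$query_end,
                 seg_start = a$target_start, seg_end = a$target_end,
                 map = cbind(read = a$map_query, seg = a$map_target)),
            class = "alignment_hit")
}

#' Assign the best-scoring germline segment to a read
#'
#' Aligns the read against every segment; the best score wins, ties broken
#' by lexicographically smallest segment name; a best score below
#' `min_score` returns `NULL` (no call).
#'
#' @param read DNA string.
#' @param segments segment table rows (e.g. [v_segments()] output).
#' @param scoring a [default_scoring()] list.
#' @param min_score minimum acceptable alignment score.
#' @return an `alignment_hit` with `segment_name` set, or `NULL`.
#' @export
assign_segment <- function(read, segments, scoring = default_scoring(),
                           min_score = 40) {
  stopifnot(nrow(segments) >= 1)
  segments <- segments[order(segments$name)]
  scores <- sw_score_many_cpp(read, segments$sequence, scoring$match,
                              scoring$mismatch, scoring$gap_open,
                              scoring$gap_extend)
  best <- which.max(scores)  # first max = smallest name after sort
  if (scores[best] < min_score) return(NULL)
  hit <- smith_waterman(read, segments$sequence[best], scoring)
  hit$segment_name <- segments$name[best]
  hit
}

# read position diagonally aligned to segment position `pos`, or NA
mapped_pos <- function(hit, pos) {
  k <- match(pos, hit$map[, "seg"])
  if (is.na(k)) NA_integer_ else hit$map[k, "read"]
}

aa_productive <- function(junction_nt) {
  aa <- translate_dna(junction_nt)
  ok <- !is.na(aa) & !grepl("*", aa, fixed = TRUE) &
    substr(aa, 1, 1) == "C" & substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
  list(aa = aa, productive = ok & !is.na(ok))
}

#' Extract the CDR3 junction from a V and a J alignment
#'
#' Maps the V and J anchor offsets onto read coordinates through the
#' alignments and extracts `read[v_anchor : j_anchor + 3)` (the AIRR-style
#' junction, anchors included: C...F/W). A junction is `productive` when it
#' is in frame, stop-free, and carries the expected anchor residues.
#'
#' @param read DNA string.
#' @param v_hit,j_hit `alignment_hit`s for the V and J segment (read
#'   coordinates must refer to `read`).
#' @param ref the [germline_reference] the hits refer to.
#' @return an `annotation`: list with `v_call`, `j_call` (gene-level),
#'   `junction_nt`, `junction_aa`, `productive`, and `status` (one of
#'   `ok`, `no_v`, `no_j`, `anchor_missing`, `unproductive`).
#' @export
extract_junction <- function(read, v_hit, j_hit, ref) {
  ann <- list(v_call = NA_character_, j_call = NA_character_,
              junction_nt = NA_character_, junction_aa = NA_character_,
              productive = FALSE, status = "ok")
  if (is.null(v_hit)) { ann$status <- "no_v"; return(structure(ann, class = "annotation")) }
  ann$v_call <- gene_of(v_hit$segment_name)
  if (is.null(j_hit)) { ann$status <- "no_j"; return(structure(ann, class = "annotation")) }
  ann$j_call <- gene_of(j_hit$segment_name)
  seg <- ref$segments
  va <- seg$anchor[seg$name == v_hit$segment_name]
  ja <- seg$anchor[seg$name == j_hit$segment_name]
  vpos <- mapped_pos(v_hit, va)
  jpos <- mapped_pos(j_hit, ja + 2L)
  if (is.na(vpos) || is.na(jpos) || vpos >= jpos + 1L) {
    ann$status <- "anchor_missing"
    return(structure(ann, class = "annotation"))
  }
  ann$junction_nt <- substr(read, vpos + 1L, jpos + 1L)
  pr <- aa_productive(ann$junction_nt)
  ann$junction_aa <- pr$aa
  ann$productive <- pr$productive
  if (!ann$productive) ann$status <- "unproductive"
  structure(ann, class = "annotation")
}

# strict 4-line FASTQ reader; errors name the offending line
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L)
    return(data.table(read_id = character(0), sequence = character(0)))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record starting at line ",
         4L * (length(lines) %/% 4L) + 1L, " of ", path)
  hd <- lines[seq(1L, length(lines), by = 4L)]
  sq <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(substr(hd, 1, 1) != "@" | substr(plus, 1, 1) != "+")
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1] - 1L) * 4L + 1L, " of ", path)
  data.table(read_id = sub("\\s.*$", "", sub("^@", "", hd)), sequence = sq)
}

status_labels <- c("ok", "no_v", "no_j", "anchor_missing")

#' Annotate every read of a FASTQ file
#'
#' The alignment stage: each read is aligned to all germline V segments
#' (best score wins, ties to the smallest name), then to all J segments in
#' the read suffix following the aligned V block (set `j_after_v = FALSE`
#' to search the whole read), and the junction between the mapped anchors is
#' extracted. Reads are de-duplicated internally, so runtime scales with
#' unique sequences.
#'
#' @param fastq path to a FASTQ file (optionally gzipped), or a character
#'   vector of read sequences.
#' @param ref a [germline_reference].
#' @param scoring a [default_scoring()] list.
#' @param min_score_v,min_score_j minimum alignment scores for a V / J call.
#' @param j_after_v restrict the J search to the read after the V block.
#' @param v_prefix_margin confine the V search to the read prefix of length
#'   `max(V length) + v_prefix_margin` (the V segment sits at the read 5'
#'   end in CDR3 amplicons); negative = search the whole read.
#' @return a `data.table` with one row per read: `sequence_id`, `sequence`,
#'   `v_call`, `j_call` (gene-level or `NA`), `junction`, `junction_aa`,
#'   `productive`, `status`.
#' @export
annotate_fastq <- function(fastq, ref, scoring = default_scoring(),
                           min_score_v = 40, min_score_j = 40,
                           j_after_v = TRUE, v_prefix_margin = 15L) {
  if (length(fastq) == 1L && file.exists(fastq)) {
    reads <- read_fastq(fastq)
  } else {
    reads <- data.table(read_id = sprintf("read%06d", seq_along(fastq)),
                        sequence = toupper(fastq))
  }
  if (nrow(reads) == 0L)
    return(data.table(sequence_id = character(0), sequence = character(0),
                      v_call = character(0), j_call = character(0),
                      junction = character(0), junction_aa = character(0),
                      productive = logical(0), status = character(0)))
  vseg <- v_segments(ref)  # name-sorted: C++ tie rule keeps smallest name
  jseg <- j_segments(ref)
  uniq <- unique(reads$sequence)
  res <- annotate_batch_cpp(uniq, vseg$sequence, vseg$anchor, jseg$sequence,
                            jseg$anchor, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            min_score_v, min_score_j, j_after_v,
                            as.integer(v_prefix_margin))
  u <- data.table(
    sequence = uniq,
    v_call = ifelse(is.na(res$v_idx), NA_character_, vseg$gene[res$v_idx]),
    j_call = ifelse(is.na(res$j_idx), NA_character_, jseg$gene[res$j_idx]),
    junction = ifelse(res$status == 0L,
                      substr(uniq, res$junc_start + 1L, res$junc_end),
                      NA_character_),
    status = status_labels[res$status + 1L])
  pr <- aa_productive(u$junction)
  u[, junction_aa := pr$aa]
  u[, productive := pr$productive]
  u[status == "ok" & !productive, status := "unproductive"]
  out <- u[reads, on = "sequence"]
  setnames(out, "read_id", "sequence_id")
  out[, .(sequence_id, sequence, v_call, j_call, junction, junction_aa,
          productive, status)]
}

#' Construct a repertoire sample
#'
#' @param sample_id sample identifier.
#' @param group group label (e.g. `"case"` / `"control"`), or `NA`.
#' @param clonotypes data.frame with columns `v_gene`, `j_gene`,
#'   `junction_nt`, `junction_aa`, `count`.
#' @param total_reads,annotated_reads read totals for the summary; default
#'   to the productive total.
#' @return an object of class `repertoire_sample`; clonotype `frequency` is
#'   `count / sum(count)` (productive reads), rows ordered by decreasing
#'   count then junction.
#' @export
repertoire_sample <- function(sample_id, group = NA_character_, clonotypes,
                              total_reads = NULL, annotated_reads = NULL) {
  cl <- as.data.table(clonotypes)
  stopifnot(all(c("v_gene", "j_gene", "junction_nt", "junction_aa", "count")
                %in% names(cl)))
  if (nrow(cl) && any(cl$count < 1)) stop("clonotype counts must be >= 1")
  productive_reads <- if (nrow(cl)) sum(cl$count) else 0L
  cl[, frequency := if (.N) count / productive_reads else numeric(0)]
  setorder(cl, -count, junction_nt)
  structure(list(
    sample_id = sample_id, group = group, clonotypes = cl[],
    total_reads = if (is.null(total_reads)) productive_reads else total_reads,
    annotated_reads = if (is.null(annotated_reads)) productive_reads
                      else annotated_reads,
    productive_reads = productive_reads
  ), class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "repertoire_sample %s [%s]: %d clonotypes, %d/%d productive/total reads\n",
    x$sample_id, x$group, nrow(x$clonotypes), x$productive_reads,
    x$total_reads))
  invisible(x)
}

#' Build a clonotype table from a FASTQ file or annotation table
#'
#' Productive reads are aggregated into clonotypes keyed by
#' `(v_gene, j_gene, junction_nt)`; non-productive and failed reads are
#' counted in the summary totals but excluded from the clonotype table.
#' An empty FASTQ yields an empty repertoire with zero totals.
#'
#' @param x FASTQ path, read-sequence character vector, or the output of
#'   [annotate_fastq()].
#' @param ref a [germline_reference] (ignored when `x` is already annotated).
#' @param sample_id,group sample metadata.
#' @param min_count drop clonotypes with fewer reads (default 1 = keep all);
#'   frequencies are computed after filtering.
#' @param ... passed to [annotate_fastq()].
#' @return a [repertoire_sample].
#' @export
build_repertoire <- function(x, ref = NULL, sample_id = "sample",
                             group = NA_character_, min_count = 1, ...) {
  ann <- if (is.data.frame(x)) as.data.table(x) else annotate_fastq(x, ref, ...)
  total <- nrow(ann)
  annotated <- sum(!is.na(ann$v_call) & !is.na(ann$j_call))
  prod <- ann[productive == TRUE]
  cl <- prod[, .(count = .N), by = .(v_gene = v_call, j_gene = j_call,
                                     junction_nt = junction,
                                     junction_aa = junction_aa)]
  cl <- cl[count >= min_count]
  repertoire_sample(sample_id, group, cl, total_reads = total,
                    annotated_reads = annotated)
}

#' Write per-read annotations as an AIRR Rearrangement TSV
#'
#' One row per unique read sequence with `duplicate_count`; columns
#' `sequence_id` (first read carrying the sequence), `sequence`, `v_call`,
#' `j_call`, `junction`, `junction_aa`, `productive`, `duplicate_count`.
#'
#' @param annotations output of [annotate_fastq()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(annotations, path) {
  ann <- as.data.table(annotations)
  agg <- ann[, .(sequence_id = sequence_id[1], duplicate_count = .N),
             by = .(sequence, v_call, j_call, junction, junction_aa,
                    productive)]
  setorder(agg, -duplicate_count, sequence)
  fwrite(agg[, .(sequence_id, sequence, v_call, j_call, junction,
                 junction_aa, productive, duplicate_count)],
         path, sep = "\t", na = "")
  invisible(path)
}

#' Write a clonotype table as CSV
#'
#' @param sample a [repertoire_sample].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(sample, path) {
  out <- data.table(sample_id = sample$sample_id, sample$clonotypes)
  fwrite(out, path)
  invisible(path)
}
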