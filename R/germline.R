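#' @title Germline V/J segment references
#' @description A `germline_reference` holds the germline TRBV and TRBJ
#' segments that reads are aligned against, each with the 0-based offset of
#' its conserved anchor codon: the second conserved cysteine (2nd-CYS) for V
#' segments and the phenylalanine/tryptophan of the FGXG motif for J
#' segments. The CDR3 junction runs from the V anchor codon through the J
#' anchor codon, inclusive. All coordinates in this package are 0-based,
#' half-open.
#' @name germline
NULL

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Strip the IMGT allele suffix from a segment name
#'
#' `"TRBV6-4*01"` becomes `"TRBV6-4"`. All usage statistics in this package
#' are gene-level.
#'
#' @param name character vector of segment or allele names.
#' @return character vector of gene-level names.
#' @export
gene_of <- function(name) sub("\\*.*$", "", name)

# anchor codon must translate to C (V) or F/W (J)
anchor_residue_ok <- function(sequence, anchor, segment_type) {
  codon <- substr(sequence, anchor + 1, anchor + 3)
  aa <- translate_dna(codon)
  if (segment_type == "V") identical(aa, "C")
  else if (segment_type == "J") aa %in% c("F", "W")
  else TRUE
}

#' Construct a germline reference from a segment table
#'
#' @param segments data.frame with columns `name`, `segment_type` (one of
#'   `"V"`, `"J"`, `"D"`), `sequence` (DNA over ACGT), and `anchor` (0-based
#'   offset of the anchor codon; ignored for D segments).
#' @return an object of class `germline_reference`.
#' @details D segments are retained if present but never used for assignment:
#'   the analysis operates on V/J usage and V-J combinations only.
#' @export
germline_reference <- function(segments) {
  seg <- as.data.table(segments)
  need <- c("name", "segment_type", "sequence", "anchor")
  if (!all(need %in% names(seg)))
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  seg[, sequence := toupper(sequence)]
  if (anyDuplicated(seg$name))
    stop("duplicate segment names: ",
         paste(unique(seg$name[duplicated(seg$name)]), collapse = ", "))
  if (any(!seg$segment_type %in% c("V", "J", "D")))
    stop("segment_type must be V, J or D")
  bad <- grepl("[^ACGT]", seg$sequence) | nchar(seg$sequence) == 0L
  if (any(bad))
    stop("non-ACGT or empty sequence in segments: ",
         paste(seg$name[bad], collapse = ", "))
  vj <- seg$segment_type != "D"
  if (any(vj & (seg$anchor < 0L | seg$anchor > nchar(seg$sequence) - 3L)))
    stop("anchor out of range for: ",
         paste(seg$name[vj & (seg$anchor < 0L | seg$anchor > nchar(seg$sequence) - 3L)],
               collapse = ", "))
  for (i in which(vj)) {
    if (!anchor_residue_ok(seg$sequence[i], seg$anchor[i], seg$segment_type[i]))
      stop("anchor codon of ", seg$name[i], " does not translate to ",
           if (seg$segment_type[i] == "V") "C" else "F/W")
  }
  if (sum(seg$segment_type == "V") < 1L || sum(seg$segment_type == "J") < 1L)
    stop("reference needs at least one V and one J segment")
  seg[, gene := gene_of(name)]
  structure(list(segments = seg[]), class = "germline_reference")
}

#' @export
print.germline_reference <- function(x, ...) {
  tab <- table(x$segments$segment_type)
  cat("germline_reference:",
      sum(x$segments$segment_type == "V"), "V,",
      sum(x$segments$segment_type == "J"), "J",
      if ("D" %in% names(tab)) paste0("(+", tab[["D"]], " D, unused)") else "",
      "segments\n")
  invisible(x)
}

#' @rdname germline
#' @param ref a `germline_reference`.
#' @return `v_segments()` / `j_segments()`: the V / J rows of the segment
#'   table, ordered by name.
#' @export
v_segments <- function(ref) {
  s <- ref$segments[ref$segments$segment_type == "V"]
  s[order(s$name)]
}

#' @rdname germline
#' @export
j_segments <- function(ref) {
  s <- ref$segments[ref$segments$segment_type == "J"]
  s[order(s$name)]
}

# V anchor: 3'-most in-frame TGT/TGC codon (frame 0); the CDR3 sits at the V
# 3' end, so the last conserved cysteine is the junction anchor.
detect_v_anchor <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq.int(1L, by = 3L, length.out = n %/% 3L)
  codons <- substring(sequence, starts, starts + 2L)
  hit <- which(codons %in% c("TGT", "TGC"))
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[length(hit)]] - 1L)
}

# J anchor: 5'-most offset (any frame) where a TTT/TTC/TGG codon begins an
# [FW]-G-X-G amino-acid motif.
detect_j_anchor <- function(sequence) {
  n <- nchar(sequence)
  if (n < 12L) return(NA_integer_)
  for (k in 0:(n - 12L)) {
    c1 <- substr(sequence, k + 1L, k + 3L)
    if (!c1 %in% c("TTT", "TTC", "TGG")) next
    g1 <- substr(sequence, k + 4L, k + 5L)
    g2 <- substr(sequence, k + 10L, k + 11L)
    if (g1 == "GG" && g2 == "GG") return(as.integer(k))
  }
  NA_integer_
}

#' Read a germline V/J reference from FASTA
#'
#' Two header dialects are supported. `"plain"` headers carry an explicit
#' anchor: `>name|V|18` means a V segment whose anchor codon starts at
#' 0-based offset 18. `"imgt"` headers are pipe-delimited with the allele
#' name in field 2 (as in IMGT/GENE-DB flat files); the segment type is
#' inferred from the name (`TRBV`/`TRBJ`/`TRBD`) and anchors are located by
#' motif scan: the 3'-most in-frame TGT/TGC codon for V, the 5'-most
#' TTT/TTC/TGG codon opening an FGXG motif for J.
#'
#' Records whose anchor cannot be located are rejected with a warning (not
#' silently dropped); a malformed header is an error naming the record.
#'
#' @param path FASTA file path.
#' @param dialect `"plain"` or `"imgt"`.
#' @return a [germline_reference].
#' @export
read_reference <- function(path, dialect = c("plain", "imgt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  fa <- Biostrings::readDNAStringSet(path)
  headers <- names(fa)
  seqs <- toupper(as.character(fa))
  rows <- vector("list", length(fa))
  for (i in seq_along(fa)) {
    fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    if (dialect == "plain") {
      if (length(fields) < 3L)
        stop("malformed plain header (need name|type|anchor): ", headers[i])
      nm <- trimws(fields[1]); ty <- trimws(fields[2])
      anc <- suppressWarnings(as.integer(fields[3]))
      if (!ty %in% c("V", "J", "D") || (ty != "D" && is.na(anc)))
        stop("malformed plain header: ", headers[i])
    } else {
      if (length(fields) < 2L)
        stop("malformed imgt header (need >= 2 pipe fields): ", headers[i])
      nm <- trimws(fields[2])
      ty <- if (grepl("^TRBV", nm)) "V" else if (grepl("^TRBJ", nm)) "J"
            else if (grepl("^TRBD", nm)) "D"
            else stop("cannot infer segment type from name: ", nm)
      anc <- if (ty == "V") detect_v_anchor(seqs[i])
             else if (ty == "J") detect_j_anchor(seqs[i]) else 0L
      if (ty != "D" && is.na(anc)) {
        warning("anchor not locatable, record rejected: ", nm)
        next
      }
    }
    if (ty == "D" && (is.na(anc) || !length(anc))) anc <- 0L
    if (ty != "D" &&
        !anchor_residue_ok(seqs[i], anc, ty)) {
      warning("anchor codon check failed, record rejected: ", nm)
      next
    }
    rows[[i]] <- data.table(name = nm, segment_type = ty,
                            sequence = seqs[i], anchor = anc)
  }
  seg <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(seg) == 0L) stop("no usable records in ", path)
  germline_reference(seg)
}

#' Write a germline reference as FASTA (plain dialect)
#'
#' Headers are `name|type|anchor` with 0-based anchors; sequence lines are
#' wrapped at 60 characters. `read_reference(write_reference(ref))`
#' round-trips names, sequences and anchors exactly.
#'
#' @param ref a [germline_reference].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  seg <- ref$segments
  dna <- Biostrings::DNAStringSet(seg$sequence)
  names(dna) <- paste(seg$name, seg$segment_type, seg$anchor, sep = "|")
  Biostrings::writeXStringSet(dna, path, width = 60L)
  invisible(path)
}

#' Generate a deterministic miniature germline reference
#'
#' A synthetic stand-in for an IMGT download so the package is testable
#' offline. V segments (`TRBVs1..TRBVs{n_v}`) are 54-66 nt with a TGT
#' (cysteine) anchor placed 9 nt before the 3' end, leaving 6 nt of
#' trimmable overhang; J segments (`TRBJs1..TRBJs{n_j}`) are 48 nt with a
#' TTT-GGN-NNN-GGN (F-G-X-G) motif whose phenylalanine codon sits at offset
#' 6. Byte-identical for a fixed seed.
#'
#' @param n_v,n_j number of V and J segments (each >= 1).
#' @param seed integer seed.
#' @return a [germline_reference].
#' @export
mini_reference <- function(n_v = 20, n_j = 13, seed = 7) {
  stopifnot(n_v >= 1, n_j >= 1)
  with_seed(derive_seed(seed, 101L), {
    vs <- lapply(seq_len(n_v), function(i) {
      len <- 54L + 3L * sample(0:4, 1)
      anchor <- len - 9L
      repeat {
        body <- random_dna(anchor)
        tail6 <- paste(sample(c("GCA", "ACC", "GAA", "CTG", "AGC", "CCT"),
                              2, replace = TRUE), collapse = "")
        seqv <- paste0(body, "TGT", tail6)
        # intended anchor must be the 3'-most in-frame cysteine codon
        if (identical(detect_v_anchor(seqv), anchor)) break
      }
      data.table(name = paste0("TRBVs", i), segment_type = "V",
                 sequence = seqv, anchor = anchor)
    })
    js <- lapply(seq_len(n_j), function(i) {
      repeat {
        prefix <- random_dna(6L)
        g1 <- sample(c("GGA", "GGC", "GGG", "GGT"), 1)
        x <- sample(c("CAA", "ACC", "CTC", "AGT", "GTG", "AAG"), 1)
        g2 <- sample(c("GGA", "GGC", "GGG", "GGT"), 1)
        seqj <- paste0(prefix, "TTT", g1, x, g2, random_dna(48L - 18L))
        # the region 5' of the anchor enters the junction in a frame that
        # depends on the trim, so it must be stop-free in every frame
        # (as real germline J regions are)
        head9 <- substring(seqj, 1:7, 3:9)
        if (!any(head9 %in% c("TAA", "TAG", "TGA")) &&
            identical(detect_j_anchor(seqj), 6L)) break
      }
      data.table(name = paste0("TRBJs", i), segment_type = "J",
                 sequence = seqj, anchor = 6L)
    })
    germline_reference(rbindlist(c(vs, js)))
  })
}
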