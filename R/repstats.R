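#' Hopp-Woods hydrophilicity scale
#'
#' Per-residue hydrophilicity values (Hopp & Woods 1981); positive values
#' are hydrophilic. The default scale for [hydrophilicity_profile()];
#' any complete named residue-to-value vector can be substituted.
#'
#' @format named numeric vector over the 20 standard amino acids.
#' @export
hopp_woods <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0, G = 0.0,
  H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
  S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

#' D50 repertoire diversity index
#'
#' Sort abundances in decreasing order; `k` is the smallest number of top
#' entries whose cumulative sum reaches 50% of the total; D50 is
#' `100 * k / n_entries` (percent). Lower values indicate clonal expansion.
#' Zero entries are dropped before ranking; the result is scale-invariant
#' and depends only on the sorted multiset of abundances.
#'
#' @param abundances non-negative count (or frequency) vector with at least
#'   one positive entry.
#' @return D50 as a percentage in (0, 100].
#' @export
d50 <- function(abundances) {
  x <- abundances[abundances > 0]
  if (!length(x)) stop("d50 needs at least one positive abundance")
  x <- sort(x, decreasing = TRUE)
  k <- which(cumsum(x) >= sum(x) / 2)[1]
  100 * k / length(x)
}

#' Per-sample diversity report
#'
#' D50 at the clonotype level or aggregated to gene-level V-J combinations
#' (the latter matching how repertoire diversity is commonly compared across
#' case/control groups), plus the unique-CDR3 count.
#'
#' @param sample a [repertoire_sample].
#' @param basis `"clonotype"` or `"vj_combination"`.
#' @return list with `d50`, `n_unique_cdr3`, `basis`.
#' @export
sample_d50 <- function(sample, basis = c("clonotype", "vj_combination")) {
  basis <- match.arg(basis)
  cl <- sample$clonotypes
  counts <- if (basis == "clonotype") cl$count
            else cl[, .(count = sum(count)), by = .(v_gene, j_gene)]$count
  list(d50 = d50(counts), n_unique_cdr3 = length(unique(cl$junction_nt)),
       basis = basis)
}

#' Four-bin clonotype abundance partition
#'
#' Clonotypes are ranked by count (descending, ties by junction sequence)
#' and partitioned into four bins: `top100` (rank <= 100, taking precedence
#' over the frequency bins), `rare` (frequency < 0.001%), `low` (0.001% <=
#' frequency <= 0.005%), and `mid` (frequency > 0.005% with rank > 100).
#' Thresholds are percentages of productive reads.
#'
#' @param sample a [repertoire_sample].
#' @param share_basis `"reads"` (share of productive reads per bin, default)
#'   or `"clonotypes"` (share of clonotype count per bin).
#' @return named numeric `c(bin_rare, bin_low, bin_mid, bin_top100)`,
#'   summing to 1.
#' @export
bin_abundances <- function(sample, share_basis = c("reads", "clonotypes")) {
  share_basis <- match.arg(share_basis)
  cl <- sample$clonotypes
  if (!nrow(cl)) stop("empty clonotype table")
  ord <- order(-cl$count, cl$junction_nt)
  rank <- integer(nrow(cl)); rank[ord] <- seq_len(nrow(cl))
  freq_pct <- 100 * cl$count / sum(cl$count)
  bin <- ifelse(rank <= 100, "bin_top100",
         ifelse(freq_pct < 0.001, "bin_rare",
         ifelse(freq_pct <= 0.005, "bin_low", "bin_mid")))
  w <- if (share_basis == "reads") cl$count else rep(1L, nrow(cl))
  out <- vapply(c("bin_rare", "bin_low", "bin_mid", "bin_top100"),
                function(b) sum(w[bin == b]) / sum(w), 0.0)
  out
}

#' CDR3 amino-acid length distribution
#'
#' Junction amino-acid lengths weighted by read count; the returned
#' histogram masses sum to 1.
#'
#' @param sample a [repertoire_sample].
#' @param weight `"reads"` (default) or `"clonotypes"`.
#' @return named numeric vector: mass per length.
#' @export
cdr3_length_distribution <- function(sample, weight = c("reads", "clonotypes")) {
  weight <- match.arg(weight)
  cl <- sample$clonotypes
  w <- if (weight == "reads") cl$count else rep(1L, nrow(cl))
  len <- nchar(cl$junction_aa)
  tab <- tapply(w, len, sum)
  tab <- tab / sum(tab)
  out <- as.numeric(tab); names(out) <- names(tab)
  out
}

#' Amino-acid composition of the repertoire
#'
#' Residue frequencies across all junction amino-acid sequences, weighted by
#' read count; sums to 1.
#'
#' @param sample a [repertoire_sample].
#' @param weight `"reads"` (default) or `"clonotypes"`.
#' @return named numeric vector of residue frequencies.
#' @export
aa_composition <- function(sample, weight = c("reads", "clonotypes")) {
  weight <- match.arg(weight)
  cl <- sample$clonotypes
  w <- if (weight == "reads") cl$count else rep(1L, nrow(cl))
  chars <- strsplit(cl$junction_aa, "")
  res <- unlist(chars, use.names = FALSE)
  wts <- rep(w, lengths(chars))
  tab <- tapply(wts, res, sum)
  tab <- tab / sum(tab)
  out <- as.numeric(tab); names(out) <- names(tab)
  out
}

#' Hydrophilicity summary of the repertoire
#'
#' Read-weighted mean of per-residue hydrophilicity values over all junction
#' residues, plus the hydrophilic fraction (mass of residues with scale
#' value > 0). The mean is linear under repertoire mixing.
#'
#' @param sample a [repertoire_sample].
#' @param scale named residue-to-value vector covering every residue that
#'   occurs (default [hopp_woods]).
#' @param weight `"reads"` (default) or `"clonotypes"`.
#' @return list with `mean` and `hydrophilic_fraction`.
#' @export
hydrophilicity_profile <- function(sample, scale = hopp_woods,
                                   weight = c("reads", "clonotypes")) {
  comp <- aa_composition(sample, weight = weight)
  missing <- setdiff(names(comp), names(scale))
  if (length(missing))
    stop("residues missing from the hydrophilicity scale: ",
         paste(missing, collapse = ", "))
  vals <- scale[names(comp)]
  list(mean = sum(comp * vals),
       hydrophilic_fraction = sum(comp[vals > 0]))
}

#' Shared CDR3 sequences between two samples
#'
#' Set intersection of junction keys (nucleotide or amino-acid level);
#' symmetric in its arguments.
#'
#' @param a,b [repertoire_sample] objects.
#' @param key `"nt"` or `"aa"`.
#' @return list with `n` and `shared` (the common keys).
#' @export
shared_cdr3 <- function(a, b, key = c("nt", "aa")) {
  key <- match.arg(key)
  col <- if (key == "nt") "junction_nt" else "junction_aa"
  common <- intersect(unique(a$clonotypes[[col]]), unique(b$clonotypes[[col]]))
  list(n = length(common), shared = common)
}

#' Per-sample summary statistics table
#'
#' One row per repertoire: totals, unique CDR3s, clonotype- and
#' V-J-combination-level D50, abundance-bin shares, mean CDR3 length and
#' hydrophilicity.
#'
#' @param samples list of [repertoire_sample] objects.
#' @return a `data.table`, one row per sample.
#' @export
repertoire_stats <- function(samples) {
  rbindlist(lapply(samples, function(s) {
    bins <- bin_abundances(s)
    lens <- cdr3_length_distribution(s)
    hyd <- hydrophilicity_profile(s)
    data.table(
      sample_id = s$sample_id, group = s$group,
      total_reads = s$total_reads, annotated_reads = s$annotated_reads,
      productive_reads = s$productive_reads,
      n_clonotypes = nrow(s$clonotypes),
      n_unique_cdr3 = length(unique(s$clonotypes$junction_nt)),
      d50_clonotype = sample_d50(s, "clonotype")$d50,
      d50_vj = sample_d50(s, "vj_combination")$d50,
      bin_rare = bins[["bin_rare"]], bin_low = bins[["bin_low"]],
      bin_mid = bins[["bin_mid"]], bin_top100 = bins[["bin_top100"]],
      mean_cdr3_len = sum(as.numeric(names(lens)) * lens),
      mean_hydrophilicity = hyd$mean,
      hydrophilic_fraction = hyd$hydrophilic_fraction)
  }))
}
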