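#' Samples-by-(V-J combination) normalized abundance matrix
#'
#' Entry `(s, v|j)` is the number of productive reads of sample `s` carrying
#' that gene-level V-J combination, scaled to reads per million productive
#' reads; row sums are therefore 1e6. Columns are restricted to
#' combinations observed in at least one sample and ordered
#' lexicographically; column names are `"TRBVx|TRBJy"`.
#'
#' @param samples list of [repertoire_sample] objects with unique ids.
#' @return an object of class `vj_matrix`: list with `values` (numeric
#'   matrix, rownames = sample ids) and `group` (character vector aligned
#'   with rows).
#' @export
build_vj_matrix <- function(samples) {
  stopifnot(length(samples) >= 2)
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  per <- lapply(samples, function(s) {
    cl <- s$clonotypes[, .(reads = sum(count)), by = .(v_gene, j_gene)]
    cl[, combo := paste(v_gene, j_gene, sep = "|")]
    stats::setNames(1e6 * cl$reads / s$productive_reads, cl$combo)
  })
  cols <- sort(unique(unlist(lapply(per, names))))
  m <- matrix(0, nrow = length(samples), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(per)) m[i, names(per[[i]])] <- per[[i]]
  structure(list(values = m,
                 group = vapply(samples, `[[`, "", "group")),
            class = "vj_matrix")
}

#' @export
print.vj_matrix <- function(x, ...) {
  cat("vj_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "V-J combinations; groups:",
      paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Detect group-exclusive (asymmetric) V-J combinations
#'
#' A combination is positive in a sample when its normalized abundance
#' exceeds `positivity_threshold`. It is flagged `case_only` when it is
#' positive in at least `min_positive` case samples and zero control
#' samples (and symmetrically `control_only`). Mean and SD of the
#' normalized abundance are computed over the positive samples only.
#'
#' @param m a [build_vj_matrix()] result with two groups.
#' @param min_positive minimum positive samples in the non-zero group.
#' @param positivity_threshold normalized-abundance positivity cutoff.
#' @param case_label which group label is the case group.
#' @return a `data.table` with columns `v_gene`, `j_gene`, `direction`,
#'   `n_positive_case`, `n_positive_control`, `mean_norm`, `sd_norm`.
#' @export
detect_asymmetric <- function(m, min_positive = 3, positivity_threshold = 0,
                              case_label = "case") {
  grp <- m$group
  if (length(unique(grp)) != 2) stop("need exactly two groups")
  is_case <- grp == case_label
  pos <- m$values > positivity_threshold
  n_case <- colSums(pos[is_case, , drop = FALSE])
  n_ctrl <- colSums(pos[!is_case, , drop = FALSE])
  hit_case <- n_case >= min_positive & n_ctrl == 0
  hit_ctrl <- n_ctrl >= min_positive & n_case == 0
  sel <- which(hit_case | hit_ctrl)
  if (!length(sel))
    return(data.table(v_gene = character(0), j_gene = character(0),
                      direction = character(0), n_positive_case = integer(0),
                      n_positive_control = integer(0), mean_norm = numeric(0),
                      sd_norm = numeric(0)))
  rows <- lapply(sel, function(k) {
    vals <- m$values[pos[, k], k]
    vj <- strsplit(colnames(m$values)[k], "|", fixed = TRUE)[[1]]
    data.table(v_gene = vj[1], j_gene = vj[2],
               direction = if (hit_case[k]) "case_only" else "control_only",
               n_positive_case = as.integer(n_case[k]),
               n_positive_control = as.integer(n_ctrl[k]),
               mean_norm = mean(vals),
               sd_norm = if (length(vals) > 1) sd(vals) else 0)
  })
  out <- rbindlist(rows)
  setorder(out, direction, v_gene, j_gene)
  out[]
}

#' Welch two-sample t test
#'
#' Two-sided t test for independent samples without the equal-variance
#' assumption.
#'
#' @param values_case,values_control numeric vectors.
#' @return list with `statistic` and `p`.
#' @export
group_t_test <- function(values_case, values_control) {
  tt <- t.test(values_case, values_control, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Continuity correction off by default (the classical
#' \eqn{\sum (O-E)^2 / E} statistic).
#'
#' @param table 2x2 matrix of counts.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic` and `p`.
#' @export
counting_chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square table has a zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' PCA ordination of the V-J matrix
#'
#' Principal components of the column-centered (unscaled) matrix. For
#' reproducibility the sign of each axis is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param m a [build_vj_matrix()] result.
#' @param n_components number of axes to return.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained` (variance fractions, non-increasing, total <= 1) and
#'   `group`.
#' @export
pca_ordination <- function(m, n_components = 2) {
  x <- m$values
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  if (all(apply(x, 2, function(col) diff(range(col)) == 0)))
    stop("constant matrix: no variance to ordinate")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0.0)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(scores = scores, loadings = loadings, explained = explained,
       group = m$group)
}

bray_curtis <- function(x) vegan::vegdist(x, method = "bray")

# pseudo-F for a two-group (or a-group) partition of a distance matrix:
# SS_total = sum d^2 / n over all pairs; SS_within from within-group pairs.
permanova_f <- function(d2, grp) {
  n <- nrow(d2)
  labs <- unique(grp)
  a <- length(labs)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in labs) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' PERMANOVA on the V-J matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from the partition of a Bray-Curtis (default) or Euclidean distance
#' matrix by group, with a label-permutation null. The p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_perm)`; with
#' `exhaustive = TRUE` all distinct label assignments are enumerated and
#' the p-value is the exact fraction of assignments (including the
#' observed one) with `F >= F_obs`.
#'
#' @param m a [build_vj_matrix()] result, two groups with >= 2 samples each.
#' @param distance `"bray_curtis"` or `"euclidean"`.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all assignments instead of sampling.
#' @return list with `f`, `p`, `n_perm` (or the number of enumerated
#'   assignments) and `distance`.
#' @export
permanova <- function(m, distance = c("bray_curtis", "euclidean"),
                      n_perm = 999, seed = 1, exhaustive = FALSE) {
  distance <- match.arg(distance)
  grp <- m$group
  stopifnot(length(unique(grp)) == 2, all(table(grp) >= 2))
  d <- if (distance == "bray_curtis") suppressWarnings(bray_curtis(m$values))
       else stats::dist(m$values)
  d2 <- as.matrix(d)^2
  d2[!is.finite(d2)] <- 0  # bray-curtis of two all-zero rows is undefined
  if (all(d2 == 0)) {
    warning("degenerate all-zero distance matrix; p = 1")
    return(list(f = NaN, p = 1, n_perm = 0L, distance = distance))
  }
  f_obs <- permanova_f(d2, grp)
  n <- length(grp)
  if (exhaustive) {
    labs <- unique(grp)
    n1 <- sum(grp == labs[1])
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      g <- rep(labs[2], n); g[idx] <- labs[1]
      permanova_f(d2, g)
    })
    p <- mean(fs >= f_obs - 1e-12)
    return(list(f = f_obs, p = p, n_perm = ncol(combos), distance = distance))
  }
  f_perm <- with_seed(derive_seed(seed, 777L),
                      vapply(seq_len(n_perm),
                             function(i) permanova_f(d2, sample(grp)), 0.0))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  list(f = f_obs, p = p, n_perm = n_perm, distance = distance)
}

#' Per-combination univariate Welch tests
#'
#' Welch t test of each V-J combination's normalized abundance between the
#' two groups, with Benjamini-Hochberg adjusted p-values reported alongside
#' the raw ones.
#'
#' @param m a [build_vj_matrix()] result.
#' @param case_label the case group label.
#' @return a `data.table` with `combo`, `t`, `p`, `p_adj`.
#' @export
vj_univariate_tests <- function(m, case_label = "case") {
  is_case <- m$group == case_label
  res <- lapply(colnames(m$values), function(cn) {
    a <- m$values[is_case, cn]; b <- m$values[!is_case, cn]
    tt <- tryCatch(group_t_test(a, b),
                   error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.table(combo = cn, t = tt$statistic, p = tt$p)
  })
  out <- rbindlist(res)
  out[, p_adj := stats::p.adjust(p, method = "BH")]
  out[]
}

#' Write a V-J matrix as CSV
#'
#' Samples in rows (first columns `sample_id`, `group`), combinations in
#' columns headed `"TRBVx|TRBJy"`.
#'
#' @param m a [build_vj_matrix()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vj_matrix <- function(m, path) {
  dt <- data.table(sample_id = rownames(m$values), group = m$group,
                   as.data.table(m$values))
  fwrite(dt, path)
  invisible(path)
}

#' Read a V-J matrix written by [write_vj_matrix()]
#'
#' @param path CSV path.
#' @return a `vj_matrix`.
#' @export
read_vj_matrix <- function(path) {
  dt <- fread(path)
  vals <- as.matrix(dt[, -(1:2)])
  rownames(vals) <- dt$sample_id
  structure(list(values = vals, group = dt$group), class = "vj_matrix")
}
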