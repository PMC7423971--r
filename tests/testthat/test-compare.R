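toy_sample <- function(id, group, combos, counts) {
  junctions <- paste0("TGT", strrep("GCA", 3), "TTT",
                      strrep("A", 3 * seq_along(counts)))
  repertoire_sample(id, group, data.frame(
    v_gene = sub("\\|.*", "", combos), j_gene = sub(".*\\|", "", combos),
    junction_nt = junctions, junction_aa = tcrlens:::translate_dna(junctions),
    count = counts))
}

toy_matrix <- function(values, group) {
  structure(list(values = values, group = group), class = "vj_matrix")
}

test_that("build_vj_matrix normalizes to reads-per-million", {
  s1 <- toy_sample("a", "case", c("TRBV1|TRBJ1", "TRBV2|TRBJ1"),
                   c(50, 500000 - 50))
  s2 <- toy_sample("b", "control", c("TRBV1|TRBJ1", "TRBV3|TRBJ2"),
                   c(10, 90))
  m <- build_vj_matrix(list(s1, s2))
  expect_equal(m$values["a", "TRBV1|TRBJ1"], 100.0)
  expect_equal(unname(rowSums(m$values)), c(1e6, 1e6), tolerance = 1e-3)
  expect_equal(colnames(m$values), sort(colnames(m$values)))
  # shuffled input: identical up to row order
  m2 <- build_vj_matrix(list(s2, s1))
  expect_equal(m$values, m2$values[rownames(m$values), ])
  expect_error(build_vj_matrix(list(s1, s1)), "duplicate")
})

test_that("detect_asymmetric applies the min-positive / zero-other rule", {
  vals <- matrix(0, 20, 3,
                 dimnames = list(sprintf("s%02d", 1:20),
                                 c("TRBV1|TRBJ1", "TRBV2|TRBJ1", "TRBV3|TRBJ2")))
  grp <- rep(c("case", "control"), each = 10)
  vals[1:3, 1] <- 100    # 3 cases, 0 controls -> hit
  vals[4:5, 2] <- 50     # 2 cases only -> below min_positive
  vals[6:8, 3] <- 80     # 3 cases ...
  vals[11, 3] <- 10      # ... but 1 control -> not flagged
  hits <- detect_asymmetric(toy_matrix(vals, grp))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$v_gene, "TRBV1")
  expect_equal(hits$j_gene, "TRBJ1")
  expect_equal(hits$direction, "case_only")
  expect_equal(hits$n_positive_case, 3L)
  expect_equal(hits$n_positive_control, 0L)
  expect_equal(hits$mean_norm, 100)
  # mirrored control-only pattern
  vals2 <- vals * 0
  vals2[11:16, 2] <- c(10, 20, 30, 40, 50, 60)
  hits2 <- detect_asymmetric(toy_matrix(vals2, grp))
  expect_equal(hits2$direction, "control_only")
  expect_equal(hits2$n_positive_control, 6L)
  expect_equal(hits2$mean_norm, 35)
  expect_equal(hits2$sd_norm, sd(c(10, 20, 30, 40, 50, 60)))
})

test_that("group_t_test matches the Welch formula and its symmetries", {
  x <- c(1, 2, 3)
  expect_equal(group_t_test(x, x)$statistic, 0)
  expect_equal(group_t_test(x, x)$p, 1)
  a <- c(4.1, 5.2, 6.0); b <- c(2.0, 2.5, 3.1)
  res <- group_t_test(a, b)
  swapped <- group_t_test(b, a)
  expect_equal(res$statistic, -swapped$statistic)
  expect_equal(res$p, swapped$p)
  # hand-computed Welch statistic
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$statistic, tstat)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$p, 2 * pt(-abs(tstat), df))
})

test_that("counting_chi_square: hand-computed statistic and symmetries", {
  tab <- matrix(c(9, 3, 1, 7), 2)  # [[9,1],[3,7]]
  res <- counting_chi_square(tab)
  expect_equal(res$statistic, 7.5)  # sum (O-E)^2/E
  expect_equal(counting_chi_square(tab[2:1, ])$statistic, res$statistic)
  expect_error(counting_chi_square(matrix(c(0, 0, 5, 7), 2)), "zero margin")
  # continuity correction available
  expect_lt(counting_chi_square(tab, correct = TRUE)$statistic, 7.5)
})

test_that("pca_ordination: degenerate inputs, variance bookkeeping, eigen oracle", {
  vals <- matrix(c(1, 1, 5, 2, 2, 6, 3, 3, 9, 4, 4, 1), 4, 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), paste0("c", 1:3)))
  ord <- pca_ordination(toy_matrix(vals, rep(c("case", "control"), 2)))
  expect_true(all(diff(ord$explained) <= 1e-12))
  expect_lte(sum(ord$explained), 1)
  # oracle: eigendecomposition of the covariance matrix
  cv <- stats::cov(vals)
  ev <- eigen(cv, symmetric = TRUE)
  expect_equal(abs(ord$explained),
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-12)
  centered <- scale(vals, center = TRUE, scale = FALSE)
  oracle_scores <- centered %*% ev$vectors[, 1:2]
  expect_equal(abs(unname(ord$scores)), abs(unname(oracle_scores)),
               tolerance = 1e-9)
  # identical samples receive identical scores
  vals2 <- rbind(vals, s5 = vals[1, ])
  ord2 <- pca_ordination(toy_matrix(vals2, c(rep("case", 3), "control", "control")))
  expect_equal(ord2$scores["s1", ], ord2$scores["s5", ])
  expect_error(pca_ordination(toy_matrix(matrix(1, 3, 3), rep("case", 3))),
               "constant")
})

test_that("permanova: exhaustive enumeration matches the oracle on a 3v3 toy", {
  set.seed(33)
  vals <- matrix(rpois(6 * 8, 40), 6, 8,
                 dimnames = list(paste0("s", 1:6), paste0("c", 1:8)))
  vals[1:3, 1:3] <- vals[1:3, 1:3] + 60
  grp <- rep(c("case", "control"), each = 3)
  m <- toy_matrix(vals, grp)
  for (dist in c("bray_curtis", "euclidean")) {
    res <- permanova(m, distance = dist, exhaustive = TRUE)
    expect_equal(res$n_perm, 20L)
    d <- if (dist == "bray_curtis") vegan::vegdist(vals, "bray")
         else dist(vals)
    d2 <- as.matrix(d)^2
    expect_equal(res$f, permanova_f_oracle(d2, grp), tolerance = 1e-10)
    expect_equal(res$p, permanova_p_oracle(d2, grp))
  }
})

test_that("permanova: relabeling invariance, separation power, degeneracy", {
  set.seed(44)
  # a balanced 5v5 design has only choose(10,5)/2 = 126 distinct
  # partitions, so the smallest attainable p is 2/252; well-separated
  # clusters must hit exactly that floor under exhaustive enumeration
  vals5 <- matrix(abs(rnorm(10 * 6, 100, 5)), 10, 6,
                  dimnames = list(paste0("s", 1:10), paste0("c", 1:6)))
  vals5[1:5, 1:3] <- vals5[1:5, 1:3] + 400
  grp5 <- rep(c("case", "control"), each = 5)
  expect_equal(permanova(toy_matrix(vals5, grp5), exhaustive = TRUE)$p, 2 / 252)
  # at 6v6 the floor (2/924) is below 0.005 and sampled permutations
  # detect the separation
  vals <- matrix(abs(rnorm(12 * 6, 100, 5)), 12, 6,
                 dimnames = list(paste0("s", 1:12), paste0("c", 1:6)))
  vals[1:6, 1:3] <- vals[1:6, 1:3] + 400
  grp <- rep(c("case", "control"), each = 6)
  m <- toy_matrix(vals, grp)
  res <- permanova(m, n_perm = 999, seed = 2)
  expect_lte(res$p, 0.005)
  flipped <- toy_matrix(vals, ifelse(grp == "case", "control", "case"))
  expect_equal(permanova(flipped, n_perm = 999, seed = 2)$p, res$p)
  zero <- toy_matrix(matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), NULL)),
                     rep(c("case", "control"), 2))
  expect_warning(rz <- permanova(zero), "degenerate")
  expect_equal(rz$p, 1)
})

test_that("univariate tests report BH-adjusted p alongside raw", {
  set.seed(55)
  vals <- matrix(rnorm(20 * 5, 100, 10), 20, 5,
                 dimnames = list(sprintf("s%02d", 1:20), paste0("c", 1:5)))
  vals[1:10, 1] <- vals[1:10, 1] + 50
  tt <- vj_univariate_tests(toy_matrix(vals, rep(c("case", "control"), each = 10)))
  expect_equal(nrow(tt), 5L)
  expect_true(all(tt$p_adj >= tt$p - 1e-15))
  expect_equal(tt$p_adj, p.adjust(tt$p, "BH"))
  expect_lt(tt$p[1], 0.001)
})

test_that("vj_matrix CSV round-trips", {
  s1 <- toy_sample("a", "case", c("TRBV1|TRBJ1", "TRBV2|TRBJ1"), c(5, 15))
  s2 <- toy_sample("b", "control", c("TRBV1|TRBJ1", "TRBV3|TRBJ2"), c(1, 9))
  m <- build_vj_matrix(list(s1, s2))
  f <- tempfile(fileext = ".csv")
  write_vj_matrix(m, f)
  back <- read_vj_matrix(f)
  expect_equal(back$values, m$values)
  expect_equal(back$group, m$group)
})
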