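test_that("summarize_group computes the standard descriptive block", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$minimum, 1)
  expect_equal(s$maximum, 5)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sd(1:5))
  expect_equal(s$n, 5L)

  s1 <- summarize_group(7.3)
  expect_equal(unlist(s1[c("mean", "median", "minimum", "maximum")]),
               c(mean = 7.3, median = 7.3, minimum = 7.3, maximum = 7.3))
  expect_equal(s1$sd, 0)

  # permutation invariance, extremes preserved
  v <- c(0.8628, 1.1865, 1.0021, 1.2884, 1.0789)
  expect_equal(summarize_group(v), summarize_group(rev(sample(v))))
  expect_equal(summarize_group(v)$minimum, 0.8628)
  expect_equal(summarize_group(v)$maximum, 1.2884)
  expect_error(summarize_group(numeric(0)), class = "petkin_invalid_input")
})

test_that("normal-approximation rank-sum test reproduces the published p-values", {
  # sizes 4 & 5, no continuity or tie correction
  cases <- list(
    list(a = c(1, 2, 3, 5), p4 = 0.0275),
    list(a = c(1, 2, 3, 6), p4 = 0.0500),
    list(a = c(1, 2, 5, 9), p4 = 0.4624),
    list(a = c(1, 3, 7, 8), p4 = 0.8065)
  )
  for (cs in cases) {
    b <- setdiff(1:9, cs$a)
    r <- wilcoxon_ranksum_normal(cs$a, b)
    expect_equal(round(r$p_two_sided, 4), cs$p4)
    expect_equal(r$rank_sum_w, sum(cs$a))
    # symmetric under group swap
    expect_equal(wilcoxon_ranksum_normal(b, cs$a)$p_two_sided, r$p_two_sided)
  }
})

test_that("rank-sum z uses the stated mean and variance", {
  a <- c(1, 2, 3, 5); b <- setdiff(1:9, a)
  r <- wilcoxon_ranksum_normal(a, b)
  expect_equal(r$z, (11 - 20) / sqrt(4 * 5 * 10 / 12))
  # W at its null mean gives z = 0, p = 1
  a0 <- c(1, 4, 6, 9)  # sums to 20 = E[W]
  r0 <- wilcoxon_ranksum_normal(a0, setdiff(1:9, a0))
  expect_equal(r0$z, 0)
  expect_equal(r0$p_two_sided, 1)
  # continuity correction flag shrinks |z|
  rc <- wilcoxon_ranksum_normal(a, b, continuity = TRUE)
  expect_lt(abs(rc$z), abs(r$z))
  # tie correction reduces the variance, growing |z|
  at <- c(1, 1, 2, 3); bt <- c(2, 4, 5, 6, 7)
  expect_gt(abs(wilcoxon_ranksum_normal(at, bt, tie_correction = TRUE)$z),
            abs(wilcoxon_ranksum_normal(at, bt)$z))
})

test_that("exact rank-sum enumeration matches hand counts", {
  # complete separation at sizes 4 & 5: 2 of 126 assignments as extreme
  r <- wilcoxon_ranksum_exact(1:4, 5:9)
  expect_equal(r$p_two_sided, 2 / 126)
  # ranks {1,2,3,5}: assignments with |W-20| >= 9 are {10, 11, 29, 30}
  r2 <- wilcoxon_ranksum_exact(c(1, 2, 3, 5), c(4, 6, 7, 8, 9))
  expect_equal(r2$p_two_sided, 4 / 126)
  expect_equal(wilcoxon_ranksum_exact(3, 8)$p_two_sided, 1)  # m = n = 1
  expect_error(wilcoxon_ranksum_exact(1:6, 7:13),
               class = "petkin_exact_too_large")
  expect_error(wilcoxon_ranksum_normal(numeric(0), 1:3),
               class = "petkin_invalid_input")
})

test_that("compare_groups produces the eight-parameter comparison table", {
  set.seed(99)
  tab <- random_param_table()
  res <- compare_groups(tab)
  expect_equal(res$parameter, c("VB", "K1", "k2", "k3", "k4", "RBP", "SUV", "FD"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$significant, res$p < 0.05)
  expect_error(compare_groups(tab[, -3]), class = "petkin_invalid_input")
  # single animal per group, exact method: any split is as extreme
  tab1 <- tab[c(1, 6), ]
  res1 <- compare_groups(tab1, method = "exact")
  expect_true(all(res1$p == 1))
})

test_that("compare_groups has power where the groups actually differ", {
  # K1 separated by the published group medians, k2 identical: over seeds,
  # K1 must be starred more often than k2
  base <- c(VB = 0.08, K1 = 0.2728, k2 = 0.5, k3 = 0.12, k4 = 0.08,
            RBP = 0.06, SUV = 1.1, FD = 1.05)
  shifted <- base; shifted["K1"] <- 0.3506 * 2  # strong separation
  stars_k1 <- 0L; stars_k2 <- 0L
  for (s in 1:60) {
    set.seed(s)
    tab <- random_param_table(center_b = shifted, center_r = base, cv = 0.15)
    res <- compare_groups(tab)
    stars_k1 <- stars_k1 + res$significant[res$parameter == "K1"]
    stars_k2 <- stars_k2 + res$significant[res$parameter == "k2"]
  }
  expect_gt(stars_k1, stars_k2)
  expect_gt(stars_k1, 30L)  # strong separation found most of the time
})

test_that("svm-rfe ranks a perfectly separating feature first", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    sep <- c(rnorm(5, -2, 0.3), rnorm(4, 2, 0.3))   # clean separation
    noise <- matrix(rnorm(9 * 3), 9, 3)
    X <- cbind(signal = sep, n1 = noise[, 1], n2 = noise[, 2], n3 = noise[, 3])
    rk <- svm_rfe_rank(X, rep(c("B", "R"), c(5, 4)))
    hits <- hits + (rk$ranking[1] == "signal")
  }
  expect_gte(hits, 95L)
})

test_that("svm-rfe is symmetric, consistent with |w|, and validates input", {
  set.seed(7)
  f <- rnorm(9)
  X <- cbind(a = f, b = f, c = rnorm(9))
  y <- rep(c("B", "R"), c(5, 4))
  rk <- svm_rfe_rank(X, y)
  w2 <- rk$weight_squares[[1]]
  expect_lt(abs(w2[["a"]] - w2[["b"]]), 1e-6)  # identical copies, equal weight

  # 2-feature case: ranking equals the |w| order of a single full fit
  set.seed(8)
  X2 <- cbind(p = rnorm(9, rep(c(0, 3), c(5, 4))), q = rnorm(9))
  rk2 <- svm_rfe_rank(X2, y)
  w2f <- rk2$weight_squares[[1]]
  expect_equal(rk2$ranking, names(sort(w2f, decreasing = TRUE)))
  expect_setequal(rk2$ranking, c("p", "q"))

  expect_warning(svm_rfe_rank(cbind(k = rep(1, 9), ok = rnorm(9)), y),
                 "constant")
  expect_error(svm_rfe_rank(X2, rep("B", 9)), class = "petkin_invalid_input")
})

test_that("group_summary_table mirrors the per-group descriptive block", {
  set.seed(3)
  tab <- random_param_table()
  gs <- group_summary_table(tab)
  expect_equal(nrow(gs), 12L)  # 2 groups x 6 statistics
  med_b_k1 <- gs$K1[gs$group == "B" & gs$statistic == "median"]
  expect_equal(med_b_k1, median(tab$K1[tab$group == "B"]))
  expect_equal(gs$SUV[gs$group == "R" & gs$statistic == "n"], 4)
})
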