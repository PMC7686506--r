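# independent brute-force oracle: two-tailed Mann-Whitney p by enumerating
# every assignment of the pooled values to group 1
brute_force_mwu_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  sets <- combn(N, n1)
  mean(apply(sets, 2, function(idx) abs(u_of(idx) - mu) >= obs - 1e-9))
}

test_that("per-sample summaries average the sampled pixels", {
  inv <- default_inventory()[1:3, ]
  pts <- list(
    data.frame(row = 0:2, col = 0:2, tau_nadh_ns = c(1, 2, 3),
               tau_ppix_ns = c(11, 11, 11)),
    data.frame(row = 0:2, col = 0:2, tau_nadh_ns = c(2, 2, 2),
               tau_ppix_ns = c(4, 6, 8)),
    data.frame(row = 0:2, col = 0:2, tau_nadh_ns = c(1, 1, 1),
               tau_ppix_ns = c(3, 3, 3)))
  names(pts) <- inv$sample_id
  s <- summarize_samples(build_cohort_table(inv, pts))
  expect_equal(nrow(s), 3L)
  expect_equal(s$mean_tau_nadh_ns, c(2, 2, 1))
  expect_equal(s$mean_tau_ppix_ns, c(11, 6, 3))
})

test_that("group quantiles use linear interpolation over per-sample means", {
  s <- data.frame(patient_id = "P", sample_id = paste0("S", 1:4),
                  diagnosis = "d", grade = "HGG",
                  tissue = c("TUM", "TUM", "TUM", "NEC"),
                  ala = "ALA_POS",
                  mean_tau_nadh_ns = c(1, 2, 3, 9),
                  mean_tau_ppix_ns = c(1, 2, 3, 4), n_points = 3)
  g <- summarize_groups(s, "tissue")
  tum <- g[g$group == "TUM", ]
  expect_equal(tum$ppix_median_ns, 2)
  expect_equal(tum$nadh_q25_ns, 1.5)  # type-7 interpolation
  nec <- g[g$group == "NEC", ]
  expect_equal(c(nec$nadh_q25_ns, nec$nadh_median_ns, nec$nadh_q75_ns),
               c(9, 9, 9))  # single-sample group collapses
  g4 <- summarize_groups(s, "ala")
  expect_equal(g4$ppix_median_ns, 2.5)  # median of {1,2,3,4}
  expect_error(summarize_groups(s, "nonsense"))
})

test_that("Mann-Whitney U handles the canonical exact cases", {
  t0 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t0$U, 0)
  expect_equal(t0$p_value, 0.1)  # 2/20 assignments are as extreme
  expect_equal(t0$method, "exact")
  # identical multisets
  tid <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tid$p_value, 1)
  # symmetry under group swap
  set.seed(10)
  x <- rnorm(5); y <- rnorm(6) + 1
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  # U + U' = n1 * n2
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 30)
})

test_that("exact path equals brute-force enumeration for all n1, n2 <= 6", {
  set.seed(20)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2)  # continuous, ties a.s. absent
    res <- mann_whitney_u(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, brute_force_mwu_p(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("normal approximation agrees with the reference implementation", {
  set.seed(30)
  x <- rnorm(25); y <- rnorm(30) + 0.6
  ours <- mann_whitney_u(x, y)
  expect_equal(ours$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # with ties (midranks + tie correction)
  xt <- round(rnorm(20), 0); yt <- round(rnorm(20) + 0.8, 0)
  ot <- mann_whitney_u(xt, yt)
  rt <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                            correct = TRUE))
  expect_equal(ot$p_value, rt$p.value, tolerance = 1e-10)
})

test_that("the p-value is invariant under strictly monotone transforms", {
  set.seed(40)
  x <- rlnorm(8); y <- rlnorm(9) * 2
  p0 <- mann_whitney_u(x, y)$p_value
  expect_equal(mann_whitney_u(log(x), log(y))$p_value, p0)
  expect_equal(mann_whitney_u(x^3, y^3)$p_value, p0)
  expect_equal(mann_whitney_u(exp(x), exp(y))$p_value, p0)
})

test_that("pairwise comparisons cover all group pairs with flags", {
  s <- data.frame(patient_id = "P", sample_id = paste0("S", 1:9),
                  diagnosis = "d",
                  grade = rep(c("LGG", "HGG", "MET"), each = 3),
                  tissue = "TUM", ala = "ALA_POS",
                  mean_tau_nadh_ns = c(1, 1.1, 0.9, 5, 5.2, 4.9, 5, 5.1, 5.2),
                  mean_tau_ppix_ns = rep(c(2, 9, 9), each = 3), n_points = 3)
  pc <- pairwise_comparisons(s, "grade", "ppix")
  expect_equal(nrow(pc), 3L)  # C(3,2)
  expect_setequal(paste(pc$group1, pc$group2),
                  c("HGG LGG", "HGG MET", "LGG MET"))
  # identical groups cannot be significant
  hm <- pc[pc$group1 == "HGG" & pc$group2 == "MET", ]
  expect_false(hm$significant)
  expect_true(all(!pc$low_n))
  # single-sample groups are tested but flagged
  s2 <- s[c(1, 4:9), ]
  pc2 <- pairwise_comparisons(s2, "grade", "nadh")
  expect_true(any(pc2$low_n))
})
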