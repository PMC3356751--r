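test_that("descriptive summary matches closed forms", {
  d <- describe_values(c(2, 4, 6))
  expect_equal(d$n, 3)
  expect_equal(d$mean, 4)
  expect_equal(d$median, 4)
  expect_equal(d$sd, 2)
  expect_equal(d$se, 2 / sqrt(3))
  expect_equal(d$min, 2)
  expect_equal(d$max, 6)
  d1 <- describe_values(5)
  expect_equal(d1$mean, 5)
  expect_true(is.na(d1$sd) && is.na(d1$se))
  expect_error(describe_values(numeric(0)), "empty")
  big <- withr::with_seed(1, rnorm(1000))
  expect_lt(abs(describe_values(big)$mean), 0.1)
})

test_that("omnibus test separates clear effects from identical groups", {
  same <- list(rep(3, 5), rep(3, 5))
  om <- omnibus_test(same)
  expect_true(om$degenerate)
  expect_equal(om$p_gate, 1)
  gr <- withr::with_seed(2, list(rnorm(20, 0, 1), rnorm(20, 5, 1)))
  om2 <- omnibus_test(gr)
  expect_lt(om2$p_kruskal, 0.001)
  expect_lt(om2$p_anova, 0.001)
  expect_false(om2$degenerate)
  expect_error(omnibus_test(list(1:5)), "2 groups")
  expect_error(omnibus_test(list(1:5, 3)), "n >= 2")
})

test_that("Kruskal-Wallis H matches the hand-ranked formula with ties", {
  groups <- list(c(1, 2, 2, 5), c(3, 3, 7, 8, 9), c(2, 6, 6))
  om <- omnibus_test(groups)
  expect_equal(om$H, brute_force_kw_h(groups), tolerance = 1e-12)
})

test_that("Dunn z equals a hand-computed rank-sum value", {
  g1 <- 1:10; g2 <- 11:20; g3 <- c(5.5, 6.5, 7.5)
  res <- dunn_posthoc(list(a = g1, b = g2, c = g3), alpha = 0.05)
  # manual: joint ranks of 23 values, no ties -> variance N(N+1)/12
  x <- c(g1, g2, g3)
  rk <- rank(x)
  rb1 <- mean(rk[1:10]); rb2 <- mean(rk[11:20])
  z12 <- (rb1 - rb2) / sqrt(23 * 24 / 12 * (1 / 10 + 1 / 10))
  row12 <- res$comparisons[res$comparisons$group_i == "a" &
                           res$comparisons$group_j == "b", ]
  expect_equal(row12$z, z12, tolerance = 1e-12)
  expect_true(row12$significant)
})

test_that("Dunn z is antisymmetric under group reordering", {
  gr <- withr::with_seed(5, list(a = rnorm(8), b = rnorm(12, 1), c = rnorm(6)))
  r1 <- dunn_posthoc(gr)
  r2 <- dunn_posthoc(gr[c("b", "a", "c")])
  z_ab <- r1$comparisons$z[r1$comparisons$group_i == "a" &
                           r1$comparisons$group_j == "b"]
  z_ba <- r2$comparisons$z[r2$comparisons$group_i == "b" &
                           r2$comparisons$group_j == "a"]
  expect_equal(z_ab, -z_ba, tolerance = 1e-12)
})

test_that("identical groups share one letter; empty groups are dropped", {
  same <- replicate(4, rep(2, 5), simplify = FALSE)
  names(same) <- paste0("g", 1:4)
  res <- dunn_posthoc(same)
  expect_true(all(res$letters == "a"))
  expect_message(
    res2 <- dunn_posthoc(list(a = 1:5, b = numeric(0), c = 6:10)),
    "empty")
  expect_equal(res2$dropped, "b")
  expect_equal(nrow(res2$comparisons), 1L)
})

test_that("letter display reconstructs the decision matrix exactly", {
  for (s in 1:20) {
    k <- withr::with_seed(s, sample(3:6, 1))
    dm <- withr::with_seed(s + 50, {
      m <- matrix(FALSE, k, k)
      m[upper.tri(m)] <- runif(k * (k - 1) / 2) < 0.4
      m | t(m)
    })
    rownames(dm) <- colnames(dm) <- paste0("g", seq_len(k))
    lets <- compact_letters(dm)
    share <- function(a, b) {
      length(intersect(strsplit(lets[a], "")[[1]],
                       strsplit(lets[b], "")[[1]])) > 0
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      expect_equal(!share(i, j), dm[i, j],
                   label = sprintf("seed %d pair %d-%d", s, i, j))
    }
  }
})

test_that("Dunn decisions concord with a permutation null", {
  # moderate shifted groups; compare each pair's decision at alpha 0.05
  agree <- 0L; total <- 0L
  for (s in 1:8) {
    gr <- withr::with_seed(s, list(a = rnorm(9, 0), b = rnorm(11, 1.1),
                                   c = rnorm(7, 2.2)))
    res <- dunn_posthoc(gr)
    for (m in seq_len(nrow(res$comparisons))) {
      i <- match(res$comparisons$group_i[m], names(gr))
      j <- match(res$comparisons$group_j[m], names(gr))
      pp <- perm_rank_p(gr, i, j, nperm = 2000, seed = 1000 + s * 10 + m)
      total <- total + 1L
      if ((pp <= 0.05) == res$comparisons$significant[m])
        agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("grouped table letters mirror the injected group structure", {
  df <- withr::with_seed(3, data.frame(
    stage = rep(c("s1", "s2"), each = 40),
    interval = rep(rep(1:4, each = 10), 2),
    y = c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 4), rnorm(10, 4),
          rnorm(40, 1))))
  tab <- group_table(df, "y", within = "stage")
  s1 <- tab[tab$stage == "s1", ]
  # intervals 1,2 (mean 0) vs 3,4 (mean 4): two letter classes
  expect_equal(s1$letters[s1$interval == 1], s1$letters[s1$interval == 2])
  expect_equal(s1$letters[s1$interval == 3], s1$letters[s1$interval == 4])
  expect_false(s1$letters[s1$interval == 1] == s1$letters[s1$interval == 3])
  # homogeneous stage: everybody shares "a"
  s2 <- tab[tab$stage == "s2", ]
  expect_true(all(s2$letters == "a"))
  expect_equal(unname(s1$se), unname(s1$sd / sqrt(s1$n)))
})
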