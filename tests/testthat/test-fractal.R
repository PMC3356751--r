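test_that("fdp reproduces its smooth-boundary baselines", {
  expect_equal(fdp(P = 40, A = 100), 1)  # square of side 10 mm
  expect_warning(z <- fdp(P = 4, A = 100), "FDP = 0")
  expect_equal(z, 0)
  # direct evaluation on published stage means (illustrative values)
  expect_equal(fdp(8.95, 2.36), 2 * log(8.95 / 4) / log(2.36))
  expect_equal(fdp(8.95, 2.36), 1.87585, tolerance = 1e-5)
})

test_that("fda reproduces its plane-filling baselines", {
  expect_equal(fda(A = 100, ML = 10), 2)
  expect_equal(fda(A = 5, ML = 5), 1)
  expect_equal(fda(3.73, 3.11), log(3.73) / log(3.11))
  expect_equal(fda(3.73, 3.11), 1.16022, tolerance = 1e-5)
})

test_that("log-singular guard bands and sign constraints are enforced", {
  expect_error(fdp(P = 10, A = 1), "guard band")
  expect_error(fdp(P = 10, A = 1.04), "guard band")
  expect_error(fdp(P = 10, A = 0.96), "guard band")
  expect_error(fdp(P = -1, A = 10), "> 0")
  expect_error(fda(A = 10, ML = 1), "guard band")
  expect_error(fda(A = 10, ML = 1.01), "guard band")
  expect_error(fda(A = -2, ML = 3), "> 0")
  # just outside the band is fine
  expect_silent(fdp(P = 10, A = 1.06))
  expect_silent(fda(A = 10, ML = 0.95))
})

test_that("measured FDP of smooth ellipses matches the analytic form", {
  # closed-form FDP of an ellipse via the Ramanujan perimeter
  # approximation; the raster measurement must agree within 2%
  analytic_fdp <- function(a, b) {
    h <- ((a - b) / (a + b))^2
    P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    2 * log(P / 4) / log(pi * a * b)
  }
  for (A in c(1.5, 2.5, 3.5, 5)) {
    for (ef in c(1.3, 2, 2.9)) {
      a <- sqrt(A * ef / pi); b <- sqrt(A / (pi * ef))
      p <- grain_shape_params(a, b, 0, scale_mm_per_px = 0.01, seed = 1)
      r <- measure_grain(make_grain_mask(p))
      v <- fdp(r$P_mm, r$A_mm2)
      expect_equal(v, analytic_fdp(a, b), tolerance = 0.02)
    }
  }
})

test_that("ensemble exponents recover construction and scaling laws", {
  # geometric similarity: P ~ c, A ~ c^2 for scaled copies
  cs <- 1:10
  recs <- data.frame(ML_mm = 2 * cs, P_mm = 6.2 * cs, A_mm2 = 2.9 * cs^2)
  e <- ensemble_exponents(recs)
  expect_equal(e$fdp_slope, 1)
  expect_equal(e$fda_slope, 2)
  expect_equal(e$r2_p, 1)
  expect_equal(e$r2_a, 1)
  # constructed power law A = k * ML^1.8
  ml <- seq(1.5, 4, length.out = 12)
  recs2 <- data.frame(ML_mm = ml, P_mm = 3.1 * ml^1.13,
                      A_mm2 = 0.4 * ml^1.8)
  e2 <- ensemble_exponents(recs2)
  expect_equal(e2$fda_slope, 1.8)
  expect_equal(e2$fdp_slope, 1.13)
  expect_equal(e2$r2_a, 1)
})

test_that("ensemble fit equals the brute-force normal-equations solution", {
  recs <- withr::with_seed(3, data.frame(
    ML_mm = exp(runif(40, 0.2, 1.5)),
    P_mm = exp(runif(40, 0.5, 2.5)),
    A_mm2 = exp(runif(40, 0.3, 2))))
  e <- ensemble_exponents(recs)
  X <- cbind(1, log(recs$ML_mm))
  beta_p <- solve(t(X) %*% X, t(X) %*% log(recs$P_mm))
  beta_a <- solve(t(X) %*% X, t(X) %*% log(recs$A_mm2))
  expect_equal(e$fdp_slope, beta_p[2, 1], tolerance = 1e-12)
  expect_equal(e$fda_slope, beta_a[2, 1], tolerance = 1e-12)
})

test_that("degenerate ensembles are refused", {
  expect_error(ensemble_exponents(
    data.frame(ML_mm = c(2, 3), P_mm = c(5, 6), A_mm2 = c(2, 3))),
    "at least 3")
  expect_error(ensemble_exponents(
    data.frame(ML_mm = c(2, 2, 2), P_mm = c(5, 6, 7),
               A_mm2 = c(2, 3, 4))), "degenerate")
})

test_that("reduced major axis option differs from OLS as sd ratio", {
  recs <- withr::with_seed(8, {
    ml <- exp(runif(30, 0.3, 1.2))
    data.frame(ML_mm = ml, P_mm = 3 * ml * exp(rnorm(30, 0, 0.1)),
               A_mm2 = ml^2 * exp(rnorm(30, 0, 0.1)))
  })
  e_ols <- ensemble_exponents(recs, method = "ols")
  e_rma <- ensemble_exponents(recs, method = "rma")
  expect_equal(e_rma$fdp_slope,
               stats::sd(log(recs$P_mm)) / stats::sd(log(recs$ML_mm)))
  expect_gt(e_rma$fdp_slope, e_ols$fdp_slope)  # RMA >= |OLS| when r < 1
})
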