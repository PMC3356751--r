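test_that("same parameters and seed give bit-identical masks", {
  p <- grain_shape_params(1.2, 0.8, roughness_amp = 0.12,
                          scale_mm_per_px = 0.02, seed = 42)
  m1 <- make_grain_mask(p)
  m2 <- make_grain_mask(p)
  expect_identical(m1$pixels, m2$pixels)
  p2 <- p; p2$seed <- 43L
  m3 <- make_grain_mask(p2)
  expect_false(identical(m1$pixels, m3$pixels))
})

test_that("smooth masks recover their generating geometry", {
  # unit disk at fine scale: SF within 2% of 1, EF within 2% of 1
  pd <- grain_shape_params(1, 1, 0, scale_mm_per_px = 0.005, seed = 1)
  rd <- measure_grain(make_grain_mask(pd))
  expect_lt(abs(rd$SF - 1), 0.02)
  expect_lt(abs(rd$EF - 1), 0.02)
  # 2:1 ellipse: EF within 2% of 2, semi-axes recovered within 2%
  pe <- grain_shape_params(2, 1, 0, scale_mm_per_px = 0.01, seed = 1)
  re <- measure_grain(make_grain_mask(pe))
  expect_lt(abs(re$EF - 2) / 2, 0.02)
  expect_lt(abs(re$ML_mm - 4) / 4, 0.02)
  expect_lt(abs(re$mL_mm - 2) / 2, 0.02)
})

test_that("invalid shape parameters and undersized canvases error", {
  expect_error(grain_shape_params(0, 0), "semi_major")
  expect_error(grain_shape_params(1, 2), "semi_major")
  expect_error(grain_shape_params(1, 0.5, roughness_amp = 0.5),
               "roughness_amp")
  p <- grain_shape_params(1, 1, 0, scale_mm_per_px = 0.01)
  expect_error(make_grain_mask(p, canvas_px = c(50, 50)), "canvas")
})

test_that("single 8-connected component over the roughness range", {
  for (amp in c(0, 0.1, 0.2, 0.3)) {
    p <- grain_shape_params(1, 0.6, roughness_amp = amp,
                            roughness_harmonics = 8,
                            scale_mm_per_px = 0.02, seed = 7)
    m <- make_grain_mask(p)
    lab <- label_components(m$pixels, 8)
    expect_equal(max(lab), 1)
  }
})

test_that("filling series interpolates exactly without jitter", {
  p <- filling_series_params(n_per_group = 1L, noise_cv = 0,
                             scale_mm_per_px = 0.02, seed = 1)
  ser <- make_filling_series(p)
  f <- (seq_along(p$stages) - 1) / (length(p$stages) - 1)
  expect_equal(ser$sheet$true_area_mm2,
               p$area_start_mm2 + f * (p$area_end_mm2 - p$area_start_mm2))
  expect_equal(ser$sheet$true_ef,
               p$ef_start + f * (p$ef_end - p$ef_start))
  expect_equal(ser$sheet$true_rough,
               p$rough_start + f * (p$rough_end - p$rough_start))
})

test_that("mean measured area increases strictly across stages", {
  p <- filling_series_params(n_per_group = 30L, noise_cv = 0.05,
                             scale_mm_per_px = 0.02, seed = 11)
  ser <- make_filling_series(p)
  areas <- vapply(ser$masks, grain_area, 0)
  mu <- tapply(areas, ser$sheet$stage, mean)[p$stages]
  expect_true(all(diff(mu) > 0))
  # and tracks the interpolation targets closely (SE at n=30, cv=0.05
  # is about 1% of the mean; allow 5%)
  f <- (seq_along(p$stages) - 1) / (length(p$stages) - 1)
  target <- p$area_start_mm2 + f * (p$area_end_mm2 - p$area_start_mm2)
  expect_true(all(abs(mu - target) / target < 0.05))
})

test_that("mean FDP decreases across the filling series", {
  ser <- make_filling_series(small_series(n = 8L, seed = 5))
  rec <- fractal_records(measure_masks(ser$masks))
  rec$stage <- ser$sheet$stage
  mu <- tapply(rec$FDP, rec$stage, mean)[small_series()$stages]
  expect_true(all(diff(mu) < 0))
})

test_that("measured FDP rises monotonically with boundary roughness", {
  amps <- c(0, 0.08, 0.16, 0.24)
  mean_fdp <- vapply(amps, function(amp) {
    vals <- vapply(1:20, function(s) {
      p <- grain_shape_params(0.9, 0.6, roughness_amp = amp,
                              scale_mm_per_px = 0.01, seed = 100 + s)
      r <- measure_grain(make_grain_mask(p))
      fdp(r$P_mm, r$A_mm2)
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_fdp) > 0))
})

test_that("empty stage list is rejected", {
  expect_error(filling_series_params(stages = character(0)), "stage")
})

test_that("texture patch hits its organization endpoints", {
  # organization 1: constant image, E = 0, ASM = 1
  t1 <- make_texture_patch(texture_patch_params(64, 1, 8, seed = 1))
  expect_equal(length(unique(as.vector(t1))), 1L)
  g1 <- glcm(t1, Ng = 8)
  expect_equal(glcm_entropy(g1), 0)
  expect_equal(glcm_asm(g1), 1)
  # organization 0: i.i.d. uniform levels; E near ln(Ng^2)
  t0 <- make_texture_patch(texture_patch_params(256, 0, 8, seed = 2))
  e0 <- glcm_entropy(glcm(t0, Ng = 8))
  expect_lt(abs(e0 - log(64)) / log(64), 0.05)
})

test_that("entropy falls and ASM rises with organization", {
  orgs <- c(0, 0.25, 0.5, 0.75, 1)
  stats_at <- vapply(orgs, function(o) {
    es <- vapply(1:6, function(s) {
      g <- glcm(make_texture_patch(
        texture_patch_params(96, o, 8, seed = 200 + s)), Ng = 8)
      c(glcm_entropy(g), glcm_asm(g))
    }, c(0, 0))
    rowMeans(es)
  }, c(E = 0, ASM = 0))
  expect_true(all(diff(stats_at["E", ]) < 0))
  expect_true(all(diff(stats_at["ASM", ]) > 0))
})

test_that("texture patches vary by seed but not in expectation", {
  g <- lapply(1:20, function(s) make_texture_patch(
    texture_patch_params(128, 0.5, 8, seed = s)))
  expect_false(identical(g[[1]], g[[2]]))
  es <- vapply(g, function(p) glcm_entropy(glcm(p, Ng = 8)), 0)
  # spread across seeds is sampling noise, not systematic
  expect_lt(stats::sd(es) / mean(es), 0.05)
  expect_lt(max(es) - min(es), 0.25 * mean(es))
})

test_that("gray_levels below 2 is rejected", {
  expect_error(texture_patch_params(64, 0.5, 1), "gray_levels")
})

test_that("cohort writes PNG masks plus a readable sample sheet", {
  dir <- withr::local_tempdir()
  ser <- make_filling_series(
    filling_series_params(stages = c("s1", "s2"), n_per_group = 2L,
                          noise_cv = 0, scale_mm_per_px = 0.03, seed = 3))
  sheet_path <- write_cohort(ser, dir)
  sheet <- read.csv(sheet_path)
  expect_equal(nrow(sheet), 4L)
  expect_true(all(file.exists(sheet$path)))
  m <- read_mask(sheet$path[1], sheet$scale_mm_per_px[1])
  expect_identical(m$pixels, ser$masks[[1]]$pixels)
})
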