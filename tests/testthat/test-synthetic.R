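test_that("cohorts are reproducible and respect the pair-count structure", {
  mp <- default_map()
  sp <- cohort_spec(seed = 21)
  co1 <- generate_cohort(sp, mp)
  co2 <- generate_cohort(sp, mp)
  expect_identical(co1$cells, co2$cells)         # bit-identical under seed
  expect_identical(co1$truth, co2$truth)

  counts <- vapply(co1$cells, nrow, 0L)
  expect_true(all(counts >= 29 & counts <= 56))
  expect_true(sum(counts) >= 174 && sum(counts) <= 336)

  # slice-like preset: totals fixed at 294
  co294 <- generate_cohort(cohort_spec_294(seed = 3), mp)
  expect_equal(sum(vapply(co294$cells, nrow, 0L)), 294)
})

test_that("zero spread and zero noise reproduce the canonical map samples", {
  mp <- default_map()
  sp <- cohort_spec(n_cells = 2, sigma_x = 0, sigma_y = 0, noise_sd = 0,
                    seed = 5)
  co <- generate_cohort(sp, mp)
  expect_equal(co$truth$x_scale, c(1, 1))
  fd <- slice_family(mp, "dist")
  for (cell in co$cells) {
    sub <- cell[cell$view == "dist" & cell$modulation == 0, ]
    expect_equal(sub$peak, fd$curves[1, match(sub$driver, fd$x)])
  }
})

test_that("normalization recovers the hidden scale factors", {
  mp <- default_map()
  canon <- fit_scale_factors(extract_fiducials(slice_family(mp, "dist"),
                                               slice_family(mp, "prox")))
  rel_err <- function(cohort) {
    nr <- normalize_cohort(cohort)
    expected <- cbind(canon[["a_x"]] / cohort$truth$x_scale,
                      canon[["a_y"]] / cohort$truth$y_scale)
    got <- cbind(nr$factors$a_x, nr$factors$a_y)
    abs(got - expected) / expected
  }
  # zero noise: machine-accurate recovery
  e0 <- rel_err(generate_cohort(cohort_spec(noise_sd = 0, seed = 7), mp))
  expect_lt(max(e0), 1e-3)
  # default noise: within 5%
  e1 <- rel_err(generate_cohort(cohort_spec_294(seed = 11), mp))
  expect_lt(median(e1), 0.05)

  # idempotence: normalizing already-normalized data returns unit factors
  co <- generate_cohort(cohort_spec(n_cells = 2, noise_sd = 0, seed = 9), mp)
  nr <- normalize_cohort(co)
  renorm <- normalize_cohort(nr$data)
  # after scaling onto the template, canonical factors are 1
  expect_equal(renorm$factors$a_x, rep(1, 2), tolerance = 1e-9)
  expect_equal(renorm$factors$a_y, rep(1, 2), tolerance = 1e-9)
})

test_that("recovery degrades gracefully with noise", {
  mp <- default_map()
  canon <- fit_scale_factors(extract_fiducials(slice_family(mp, "dist"),
                                               slice_family(mp, "prox")))
  med_err <- vapply(c(0, 0.1, 0.3, 1.0), function(sdv) {
    co <- generate_cohort(cohort_spec(noise_sd = sdv, seed = 31), mp,
                          max_retries = 50)
    nr <- normalize_cohort(co)
    expected <- cbind(canon[["a_x"]] / co$truth$x_scale,
                      canon[["a_y"]] / co$truth$y_scale)
    got <- cbind(nr$factors$a_x, nr$factors$a_y)
    median(abs(got - expected) / expected)
  }, 0)
  expect_true(all(diff(med_err) >= -1e-9))
})

test_that("cohort CSV + manifest round-trips", {
  mp <- default_map()
  co <- generate_cohort(cohort_spec(n_cells = 2, seed = 13), mp)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$cells), 2)
  expect_equal(back$cells[[1]]$peak, co$cells[[1]]$peak, tolerance = 1e-9)
  expect_equal(back$truth$x_scale, co$truth$x_scale, tolerance = 1e-12)
})
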