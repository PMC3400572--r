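test_that("scale-factor fitting matches closed-form and brute-force optima", {
  tpl <- fiducial_template()
  expect_equal(tpl$x, c(1, 0, 0, 0.6))
  expect_equal(tpl$y, c(1, 0.6, 2.4, 2.2))

  # fiducials equal to the template -> identity factors
  f_id <- dendarith:::new_fiducial_set(c(1, 1), c(0, 0.6), c(0, 2.4),
                                       c(0.6, 2.2))
  expect_equal(fit_scale_factors(f_id), c(a_x = 1, a_y = 1))

  # x doubled and y halved -> factors (0.5, 2)
  f_sc <- dendarith:::new_fiducial_set(c(2, 0.5), c(0, 0.3), c(0, 1.2),
                                       c(1.2, 1.1))
  fac <- fit_scale_factors(f_sc)
  expect_equal(fac, c(a_x = 0.5, a_y = 2))

  # brute-force grid search over (a_x, a_y) agrees
  mse <- function(ax, ay, f) {
    mean((ax * f$x - tpl$x)^2 + (ay * f$y - tpl$y)^2)
  }
  grid <- seq(0.05, 4, by = 0.001)
  ax_best <- grid[which.min(vapply(grid, mse, 0, ay = fac[["a_y"]], f = f_sc))]
  ay_best <- grid[which.min(vapply(grid, function(a) mse(fac[["a_x"]], a, f_sc), 0))]
  expect_equal(fac[["a_x"]], ax_best, tolerance = 2e-3)
  expect_equal(fac[["a_y"]], ay_best, tolerance = 2e-3)

  # local optimality: +/-1% perturbations increase the MSE
  m0 <- mse(fac[["a_x"]], fac[["a_y"]], f_sc)
  for (d in c(0.99, 1.01)) {
    expect_gt(mse(fac[["a_x"]] * d, fac[["a_y"]], f_sc), m0)
    expect_gt(mse(fac[["a_x"]], fac[["a_y"]] * d, f_sc), m0)
  }
})

test_that("rigid single-fiducial scaling places the pentagon exactly", {
  dat <- data.frame(driver = c(0, 1, 2), modulation = 0, peak = c(0, 2.4, 4.8))
  sc <- rigid_scale_orthogonal(dat, pentagon = c(2, 4.8))
  expect_equal(unname(sc$factors), c(0.5, 0.5))
  expect_equal(sc$factors[["a_x"]] * 2, 1)
  expect_equal(sc$factors[["a_y"]] * 4.8, 2.4, tolerance = 1e-12)
  id <- rigid_scale_orthogonal(dat, pentagon = c(1, 2.4))
  expect_equal(unname(id$factors), c(1, 1))
  expect_error(rigid_scale_orthogonal(dat, pentagon = c(0, 2.4)), "nonzero")
})

test_that("fiducials extracted from a template-built family recover the template", {
  # synthesize a family whose landmark points are the template itself:
  # distal-alone curve with a jump at x=1 reaching 1, proximal-alone curve
  # jumping from 0.6 to 2.4, biased curve jumping at x=0.6 to 2.2
  x <- seq(0, 1.6, by = 0.2)
  jump_curve <- function(x, thr, lo_slope, hi) {
    ifelse(x < thr - 1e-9, lo_slope * x, hi + 0.05 * (x - thr))
  }
  dist_alone <- jump_curve(x, 1.0, 0.35, 1.0)
  biased <- 0.35 + jump_curve(x, 0.6, 0.4, 2.2 - 0.35)  # intercept 0.35
  prox_x <- seq(0, 1.6, by = 0.2)
  prox_alone <- jump_curve(prox_x, 1.0, 0.6, 2.4)       # sub at 0.8 -> 0.48?
  # make the just-subthreshold proximal point exactly 0.6
  prox_alone[prox_x == 0.8] <- 0.6
  fam_d <- structure(list(driver = "dist", x = x,
                          modulation = c(0, 0.8), curves = rbind(dist_alone, biased),
                          mod_alone = c(dist_alone[1], biased[1]), meta = list()),
                     class = "curve_family")
  fam_p <- structure(list(driver = "prox", x = prox_x,
                          modulation = c(0, 0), curves = rbind(prox_alone, prox_alone),
                          mod_alone = c(prox_alone[1], prox_alone[1]),
                          meta = list()),
                     class = "curve_family")
  fid <- extract_fiducials(fam_d, fam_p)
  expect_equal(fid$x[fid$point == "triangle"], 1.0)
  expect_equal(fid$y[fid$point == "triangle"], 1.0)
  expect_equal(fid$y[fid$point == "square"], 0.6)
  expect_equal(fid$y[fid$point == "pentagon"], 2.4)
  expect_equal(fid$x[fid$point == "circle"], 0.6)
  expect_equal(fid$y[fid$point == "circle"], 2.2)
  expect_equal(unname(fit_scale_factors(fid)), c(1, 1), tolerance = 1e-12)
})

test_that("families without spikes are rejected with a named fiducial", {
  x <- seq(0, 2, by = 0.25)
  flat <- structure(list(driver = "dist", x = x, modulation = c(0, 1),
                         curves = rbind(0.3 * x, 0.1 + 0.3 * x),
                         mod_alone = c(0, 0.1), meta = list()),
                    class = "curve_family")
  expect_error(extract_fiducials(flat, flat), "triangle")
})

test_that("model-derived fiducials show the proximal-bias threshold reduction", {
  mp <- default_map()
  fid <- extract_fiducials(slice_family(mp, "dist"), slice_family(mp, "prox"))
  expect_lt(fid$x[fid$point == "circle"], fid$x[fid$point == "triangle"])
  expect_gt(fid$y[fid$point == "pentagon"], fid$y[fid$point == "square"])
})
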