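test_that("two-input map margins equal the single-site ramps", {
  mp <- coarse_map_within()
  expect_equal(mp$peaks[1, 1], 0)
  # column 0 = proximal-only ramp; recompute two entries directly
  b <- dendarith:::first_basal(test_model)
  for (n in c(8, 24)) {
    ev <- double_pulse_events(cluster_at_path(test_model, b, 90, n))
    p <- peak_depolarization(simulate_cable(test_model$morph,
                                            test_model$membrane,
                                            test_model$channels, ev,
                                            duration = 120))
    expect_equal(mp$peaks[which(mp$n_prox == n), 1], p, tolerance = 1e-9)
  }
  for (n in c(8, 24)) {
    ev <- double_pulse_events(cluster_at_path(test_model, b, 150, n))
    p <- peak_depolarization(simulate_cable(test_model$morph,
                                            test_model$membrane,
                                            test_model$channels, ev,
                                            duration = 120))
    expect_equal(mp$peaks[1, which(mp$n_dist == n)], p, tolerance = 1e-9)
  }
})

test_that("co-localized clusters sum by total count and the corner is maximal", {
  # co-localization: (n1, n2) at the same site behaves like n1 + n2
  b <- dendarith:::first_basal(test_model)
  peak_at <- function(n1, n2) {
    ev <- rbind(double_pulse_events(cluster_at_path(test_model, b, 120, n1)),
                if (n2 > 0)
                  double_pulse_events(cluster_at_path(test_model, b, 120.25, n2))
                else empty_events())
    peak_depolarization(simulate_cable(test_model$morph, test_model$membrane,
                                       test_model$channels, ev,
                                       duration = 120))
  }
  expect_equal(peak_at(6, 6), peak_at(12, 0), tolerance = 0.05)
  expect_equal(peak_at(4, 8), peak_at(12, 0), tolerance = 0.05)

  mp <- coarse_map_within()
  expect_equal(unname(which(mp$peaks == max(mp$peaks), arr.ind = TRUE)[1, ]),
               c(length(mp$n_prox), length(mp$n_dist)))
  expect_true(all(apply(mp$peaks, 1, function(r) all(diff(r) >= -1e-6))))
})

test_that("slicing a map into curve families is invertible", {
  mp <- coarse_map_within()
  fd <- slice_family(mp, "dist")
  fp <- slice_family(mp, "prox")
  expect_equal(nrow(fd$curves), length(mp$n_prox))
  expect_equal(dendarith:::unslice_family(fd)$peaks, mp$peaks)
  expect_equal(dendarith:::unslice_family(fp)$peaks, mp$peaks)
  expect_equal(fd$mod_alone, mp$peaks[, 1])
  expect_equal(fp$mod_alone, mp$peaks[1, ])
  # zero-modulation curve is the single-site ramp
  expect_equal(fd$curves[1, ], mp$peaks[1, ])
})

test_that("modulation categories average correctly", {
  # four synthetic curves, known modulator-alone peaks
  x <- 0:5
  curves <- rbind(x, x + 1, x + 4, x + 5)
  fam <- structure(list(driver = "dist", x = x, modulation = c(0, 2, 4, 6),
                        curves = curves, mod_alone = curves[, 1],
                        meta = list()),
                   class = "curve_family")
  g4 <- categorize_and_average(fam, 4)
  expect_equal(nrow(g4$mean_curves), 4)
  expect_equal(g4$mean_curves[1, ], unname(curves[1, ]))
  g2 <- categorize_and_average(fam, 2)
  expect_equal(g2$mean_curves[1, ], unname(colMeans(curves[1:2, ])))
  expect_equal(g2$mean_curves[2, ], unname(colMeans(curves[3:4, ])))
  # bin means preserve modulation ordering at the driver midpoint
  mid <- 3
  expect_true(all(diff(g2$mean_curves[, mid]) > 0))

  # identical curves give identical bin means
  same <- fam
  same$curves <- rbind(x, x, x, x) + 1
  same$mod_alone <- same$curves[, 1]
  gs <- categorize_and_average(same, 2)
  expect_equal(gs$mean_curves[1, ], gs$mean_curves[2, ])

  # exclusion ceiling drops strong-modulation curves
  gx <- categorize_and_average(fam, 2, exclude_above = 4.5)
  expect_equal(gx$excluded, 6)

  # more bins than curves collapses with a warning
  expect_warning(categorize_and_average(fam, 7), "bins")
})

test_that("regional distribution conserves synapse count and reduces to one branch", {
  b1 <- dendarith:::first_basal(test_model)
  b2 <- dendarith:::nth_basal(test_model, 2)
  # split across two branches: 7 synapses -> 4 + 3
  sites_split <- rbind(cluster_at_path(test_model, b1, 100, 4),
                       cluster_at_path(test_model, b2, 100, 3))
  expect_equal(nrow(sites_split), 7)
  # one-branch regional variant delegates to map_two_input (tiny grid)
  m1 <- regional_variant(test_model, b1, n_max = 8, step = 4)
  m2 <- map_two_input(test_model, n_max = 8, step = 4,
                      branch_prox = b1, branch_dist = b1)
  expect_equal(m1$peaks, m2$peaks)
})

test_that("regional distribution over two sibling branches preserves the asymmetry", {
  b1 <- dendarith:::first_basal(test_model)
  b2 <- dendarith:::nth_basal(test_model, 2)
  mr <- regional_variant(test_model, c(b1, b2), n_max = 40, step = 8)
  gain <- function(f) (max(f$curves[nrow(f$curves), ]) - max(f$curves[1, ])) /
    max(f$curves[1, ])
  g_dist <- gain(slice_family(mr, "dist"))
  g_prox <- gain(slice_family(mr, "prox"))
  # same sign of the effect as on a single branch: proximal modulation boosts
  # the distally driven maximum far more than vice versa
  expect_gt(g_dist, g_prox)
  expect_gt(g_dist, 0)
})

test_that("map CSV export round-trips", {
  mp <- coarse_map_within()
  f <- tempfile(fileext = ".csv")
  g <- tempfile(fileext = ".json")
  write_two_input_map(mp, f, g)
  back <- read_two_input_map(f, g)
  expect_equal(back$peaks, mp$peaks, tolerance = 1e-9)
  expect_equal(back$n_prox, mp$n_prox)
  expect_equal(back$meta$loc_prox, 90)
})
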