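test_that("magnesium block evaluates the sigmoid exactly", {
  expect_equal(mg_block(-12, 12, 10), 0.5)
  expect_equal(mg_block(-22, 22, 12), 0.5)
  expect_equal(mg_block(38, 12, 10), 1 / (1 + exp(-5)))
  expect_true(all(diff(mg_block(seq(-90, 10, 1))) > 0))
  expect_error(mg_block(0, 12, 0), "nonzero")
})

test_that("dual-exponential conductance is peak-normalized to g_max", {
  a <- ampa_spec(1.5)
  expect_equal(dual_exp_g(0, a), 0)
  tstar <- log(a$tau_fall / a$tau_rise) * a$tau_rise * a$tau_fall /
    (a$tau_fall - a$tau_rise)
  expect_equal(dual_exp_g(tstar, a), 1.5)
  nm <- nmda_spec(3.56)
  grid <- seq(0, 200, by = 1e-3)
  expect_equal(max(dual_exp_g(grid, nm)), 3.56, tolerance = 1e-6)
  expect_error(synapse_spec("AMPA", 1, 2, 1), "tau_fall > tau_rise")
})

test_that("synapse clusters are placed symmetrically at 0.5 um spacing", {
  m <- build_ball_and_stick(1, 275, 1.0, 20)
  expect_equal(place_cluster(m, 2, 90, 1)$pos_um, 90)
  expect_equal(place_cluster(m, 2, 90, 5)$pos_um, c(89, 89.5, 90, 90.5, 91))
  c40 <- place_cluster(m, 2, 160, 40)
  expect_equal(range(c40$pos_um), c(150.25, 169.75))
  expect_equal(mean(c40$pos_um), 160)
  expect_error(place_cluster(m, 2, 5, 40), "exceeds")
})

test_that("the cell rests stably near the leak reversal", {
  r <- simulate_cable(test_model$morph, test_model$membrane,
                      test_model$channels, duration = 500)
  expect_lt(max(abs(r$v[, "soma"] - r$v[1, "soma"])), 0.5)
  expect_lt(abs(r$v[1, "soma"] - (-70)), 3)
})

test_that("passive somatic input resistance matches sealed-cable theory", {
  model <- passive_model(basal_model(n_basal = 4, dend_taper = NULL,
                                     dend_diam = 1.2, soma_diam = 17,
                                     axon = FALSE))
  r <- simulate_cable(model$morph, model$membrane, model$channels,
                      bias = list(amp_nA = 0.01, start = 0, stop = 400),
                      duration = 400)
  rin_sim <- (r$v[nrow(r$v), "soma"] - r$v[1, "soma"]) / 0.01   # MOhm
  # oracle: soma sphere in parallel with 4 sealed finite cables
  # (spine-corrected: Rm halved, lambda = sqrt(Rm a / (2 Ra)))
  soma_area <- pi * (17e-4)^2
  r_soma <- 20e3 / soma_area
  a_cm <- 1.2 / 2 * 1e-4
  rm_eff <- 10e3 / 2
  lam <- sqrt(rm_eff * a_cm / (2 * 100))
  r_inf <- (100 / (pi * a_cm^2)) * lam
  r_cable <- r_inf / tanh(275e-4 / lam)
  rin_theory <- 1 / (1 / r_soma + 4 / r_cable) / 1e6
  expect_lt(abs(rin_sim - rin_theory) / rin_theory, 0.02)
})

test_that("integration converges: halving dt changes peaks by < 0.5%", {
  b <- dendarith:::first_basal(test_model)
  ev <- synapse_events(cluster_at_path(test_model, b, 160, 20))
  p1 <- peak_depolarization(simulate_cable(test_model$morph, test_model$membrane,
                                           test_model$channels, ev,
                                           duration = 100, dt = 0.1))
  p2 <- peak_depolarization(simulate_cable(test_model$morph, test_model$membrane,
                                           test_model$channels, ev,
                                           duration = 100, dt = 0.05))
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("double-pulse protocol doubles the NMDA conductance on pulse two", {
  sites <- cluster_at_path(test_model, dendarith:::first_basal(test_model),
                           120, 10)
  ev <- double_pulse_events(sites)
  sched <- attr(ev, "nmda_gmax_pulse")
  expect_equal(sched, c(2.23, 4.46))
  expect_equal(sched[2] / sched[1], 2)
  nmda <- ev[ev$kind == "NMDA", ]
  expect_equal(sort(unique(nmda$onset)), c(5, 25))          # 20 ms = 50 Hz
  expect_equal(unique(ev$g_max[ev$kind == "AMPA"]), 1.5)

  # zero synapses -> flat trace at rest
  r0 <- simulate_cable(test_model$morph, test_model$membrane,
                       test_model$channels, duration = 60)
  expect_lt(max(r0$v[, 1]) - min(r0$v[, 1]), 0.1)

  # double pulse produces at least the single-pulse peak at matched site/count
  rs <- simulate_cable(test_model$morph, test_model$membrane,
                       test_model$channels,
                       synapse_events(sites, nmda_gmax = 2.23),
                       duration = 120)
  rd <- simulate_cable(test_model$morph, test_model$membrane,
                       test_model$channels, ev, duration = 120)
  expect_gte(peak_depolarization(rd), peak_depolarization(rs))
})

test_that("peak depolarization follows its definition and passive inputs sum sublinearly", {
  r0 <- simulate_cable(test_model$morph, test_model$membrane,
                       test_model$channels, duration = 50)
  expect_lt(peak_depolarization(r0), 0.05)

  pm <- passive_model(test_model)
  b <- dendarith:::first_basal(pm)
  s1 <- cluster_at_path(pm, b, 80, 5)
  s2 <- cluster_at_path(pm, b, 150, 5)
  ev1 <- synapse_events(s1, nmda_gmax = 0)
  ev2 <- synapse_events(s2, nmda_gmax = 0)
  p1 <- peak_depolarization(simulate_cable(pm$morph, pm$membrane, pm$channels,
                                           ev1, duration = 60))
  p2 <- peak_depolarization(simulate_cable(pm$morph, pm$membrane, pm$channels,
                                           ev2, duration = 60))
  p12 <- peak_depolarization(simulate_cable(pm$morph, pm$membrane, pm$channels,
                                            rbind(ev1, ev2), duration = 60))
  expect_lte(p12, p1 + p2)

  # brute-force definition check
  r1 <- simulate_cable(pm$morph, pm$membrane, pm$channels, ev1, duration = 60)
  expect_equal(peak_depolarization(r1), max(r1$v[, "soma"] - r1$v[1, "soma"]))
})

test_that("proximal sites give larger somatic responses and later NRLE points", {
  c70 <- cached_ramp(70)
  c160 <- cached_ramp(160)
  # matched subthreshold count (below both thresholds)
  expect_gt(c70$y[c70$x == 8], c160$y[c160$x == 8])
  n70 <- compute_nrle(c70)
  n160 <- compute_nrle(c160)
  expect_gt(c70$x[n70$index], c160$x[n160$index])
})
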