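test_that("steady state satisfies Kirchhoff's laws and matches the Newton oracle", {
  p <- two_comp_params()
  # no drive -> rest
  st0 <- solve_steady_state(p, 0, 0)
  expect_equal(st0$v_prox, -70)
  expect_equal(st0$v_dist, -70)

  # residuals below 1e-9 and agreement with the damped-Newton oracle from
  # 100 random starts, over assorted drives
  for (nn in list(c(5, 5), c(0, 20), c(30, 0), c(20, 20), c(40, 40))) {
    st <- solve_steady_state(p, nn[1], nn[2])
    expect_lt(max(abs(st$residuals)), 1e-9)
    oracle <- newton_two_comp(p, nn[1], nn[2])
    expect_gt(nrow(oracle), 0)
    expect_equal(st$v_dist, oracle$v_dist[1], tolerance = 1e-7)
    expect_equal(st$v_prox, oracle$v_prox[1], tolerance = 1e-7)
  }

  # enormous axial conductance collapses the two nodes
  p_inf <- two_comp_params(g_axial = 1e6)
  st <- solve_steady_state(p_inf, 10, 10)
  expect_lt(abs(st$v_prox - st$v_dist), 1e-3)
})

test_that("all bistable roots are reported and the rest branch is continuous", {
  p <- two_comp_params()
  n_roots <- integer(0)
  v_rest_branch <- numeric(0)
  for (nd in 0:40) {
    st <- solve_steady_state(p, 0, nd)
    n_roots <- c(n_roots, nrow(st$roots))
    v_rest_branch <- c(v_rest_branch, st$v_dist)
  }
  expect_gt(max(n_roots), 1)     # bistability occurs somewhere on this axis
  # rest-connected branch moves continuously until it disappears (one jump at
  # the fold at most)
  jumps <- sum(abs(diff(v_rest_branch)) > 10)
  expect_lte(jumps, 1)
})

test_that("response surface is monotone with the distal axis saturating lower", {
  p <- two_comp_params()
  surf <- response_surface(p, seq(0, 40, 2), seq(0, 40, 2))
  expect_equal(surf$peaks[1, 1], 0)
  expect_true(all(apply(surf$peaks, 1, function(r) all(diff(r) >= -1e-9))))
  expect_true(all(apply(surf$peaks, 2, function(cl) all(diff(cl) >= -1e-9))))
  expect_lt(max(surf$peaks[1, ]), max(surf$peaks[, 1]))  # dist-only < prox-only
})

test_that("output scaling maps the surface peak onto the target exactly", {
  p <- two_comp_params()
  surf <- response_surface(p, seq(0, 40, 5), seq(0, 40, 5))
  f <- fit_output_scale(surf, 15.2)
  expect_equal(max(surf$peaks) * f, 15.2)
  expect_equal(fit_output_scale(surf, max(surf$peaks)), 1)
  expect_equal(fit_output_scale(surf, 30.4), 2 * f)
  empty <- surf; empty$peaks[] <- 0
  expect_error(fit_output_scale(empty, 15.2), "zero")
})

test_that("current-to-overcome is zero at steady state with the expected signs", {
  p <- two_comp_params()
  st <- solve_steady_state(p, 10, 15)
  expect_lt(abs(compute_cto(p, st$v_dist, 15, "dist", n_other = 10)), 1e-6)
  # at rest with drive the NMDA current exceeds the (zero) restoring current
  expect_gt(compute_cto(p, p$e_rest, 10, "dist"), 0)
  # above rest with no drive only the restoring current remains
  expect_lt(compute_cto(p, p$e_rest + 20, 0, "dist"), 0)
  expect_lt(compute_cto(p, p$e_rest + 20, 0, "prox"), 0)
})
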