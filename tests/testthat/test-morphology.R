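test_that("ball-and-stick construction gives the expected sections and path lengths", {
  m <- build_ball_and_stick(4, 275, 1.0, 20)
  expect_equal(nrow(m$sections), 5)
  expect_equal(sum(is.na(m$sections$parent_id)), 1)
  dend <- m$sections$id[m$sections$kind == "basal"]
  expect_true(all(vapply(dend, function(id) path_distance(m, id), 0) == 275))
  expect_true(all(m$sections$spine_corrected[m$sections$kind == "basal"]))

  m1 <- build_ball_and_stick(1, 200, 1.0, 20)
  expect_equal(nrow(m1$sections), 2)
  expect_equal(path_distance(m1, 2), 200)

  m2 <- discretize(build_ball_and_stick(2, 100, 0.8, 15), membrane_params())
  dend2 <- which(m2$sections$kind == "basal")
  expect_equal(m2$nseg[dend2[1]], m2$nseg[dend2[2]])

  expect_error(build_ball_and_stick(2, -5, 1, 20), "positive")
  expect_error(build_ball_and_stick(0, 100, 1, 20), "n_basal")
})

test_that("discretization follows the lambda/10 and 10-um caps with odd counts", {
  mb <- membrane_params()
  # 5 um section: already below both caps
  s5 <- new_morphology(data.frame(
    id = 1:2, parent_id = c(NA, 1), kind = c("soma", "basal"),
    length = c(10, 5), diameter = c(10, 1), spine_corrected = c(FALSE, FALSE)))
  expect_equal(discretize(s5, mb)$nseg[2], 1)

  # 200 um, 1 um diameter, unspined: lambda100/10 ~ 20 um so the 10 um cap
  # binds; smallest odd count with 200/n <= 10 is 21
  s200 <- new_morphology(data.frame(
    id = 1:2, parent_id = c(NA, 1), kind = c("soma", "basal"),
    length = c(10, 200), diameter = c(10, 1), spine_corrected = c(FALSE, FALSE)))
  d <- discretize(s200, mb)
  expect_gte(d$nseg[2], 21)
  expect_equal(d$nseg[2] %% 2, 1)
  expect_lte(200 / d$nseg[2], 10)

  # frequency-dependent length constant, hand-checked: d=1um, f=100, Ra=100,
  # Cm=2 -> lambda = 0.5*sqrt(1e-4/(pi*100*100*2e-6)) cm = 199.47 um
  expect_equal(lambda_f(1, 100, 100, 2), 199.4711, tolerance = 1e-4)

  # halving the cap (finer mesh) changes simulated peaks by < 1%
  model <- basal_model(n_basal = 4, dend_taper = NULL, dend_diam = 0.8,
                       soma_diam = 16, axon = FALSE)
  fine <- model
  fine$morph <- discretize(fine$morph, model$membrane, cap_um = 5)
  b <- model$morph$sections$id[model$morph$sections$kind == "basal"][1]
  sites <- place_cluster(model$morph, b, 100, 10)
  ev <- synapse_events(sites)
  p1 <- peak_depolarization(simulate_cable(model$morph, model$membrane,
                                           model$channels, ev, duration = 80))
  p2 <- peak_depolarization(simulate_cable(fine$morph, fine$membrane,
                                           fine$channels, ev, duration = 80))
  expect_lt(abs(p1 - p2) / p2, 0.01)
})

test_that("path distance is additive along random trees", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 6
    lens <- runif(n, 10, 120)
    parent <- c(NA, 1, sample(2:2, 1), sample(2:3, 1), sample(2:4, 1),
                sample(2:5, 1))
    secs <- data.frame(id = 1:n, parent_id = parent,
                       kind = c("soma", rep("basal", n - 1)),
                       length = lens, diameter = 1, spine_corrected = FALSE)
    m <- new_morphology(secs)
    for (tip in 2:n) {
      d <- 0; i <- tip
      while (!is.na(i) && secs$kind[i] != "soma") {
        d <- d + lens[i]; i <- secs$parent_id[i]
      }
      expect_equal(path_distance(m, tip), d)
    }
  }
})

test_that("SWC import/export round-trips geometry and rejects malformed files", {
  # 3 collinear points, radius 0.5, spaced 10 um: one 20 um section of 1 um
  swc <- tempfile(fileext = ".swc")
  writeLines(c("1 3 0 0 0 0.5 -1", "2 3 10 0 0 0.5 1", "3 3 20 0 0 0.5 2"), swc)
  m <- load_swc(swc)
  expect_equal(nrow(m$sections), 1)
  expect_equal(m$sections$length, 20)
  expect_equal(m$sections$diameter, 1)

  # dangling parent
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 0.5 9"), bad)
  expect_error(load_swc(bad), "dangling parent")

  # malformed row (6 columns)
  bad2 <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5", "2 3 10 0 0 0.5 1"), bad2)
  expect_error(load_swc(bad2), "malformed")

  # write -> load preserves total cable length to 1e-9
  orig <- build_ball_and_stick(4, 275, 1.0, 20)
  out <- tempfile(fileext = ".swc")
  write_swc(orig, out)
  back <- load_swc(out)
  expect_equal(sum(back$sections$length), sum(orig$sections$length),
               tolerance = 1e-9)
})

test_that("the morphology summary table exports section geometry", {
  m <- discretize(build_ball_and_stick(2, 100, 0.8, 15), membrane_params())
  f <- tempfile(fileext = ".csv")
  tab <- morphology_summary(m, f)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("nseg", "tip_path_um") %in% names(tab)))
  back <- read.csv(f)
  expect_equal(back$length, tab$length)
})

test_that("site_at_path resolves positions across branch points", {
  m <- build_basal_tree(2, 275, 40, 1.4, 0.8, 2, 20)
  term <- m$sections$id[m$sections$kind == "basal" &
                          !(m$sections$id %in% m$sections$parent_id)]
  s <- site_at_path(m, term[1], 70)
  expect_equal(s$section, term[1])
  expect_equal(s$pos_um, 30)
  s2 <- site_at_path(m, term[1], 25)   # lands on the stem
  expect_equal(m$sections$kind[match(s2$section, m$sections$id)], "basal")
  expect_equal(s2$pos_um, 25)
  expect_error(site_at_path(m, term[1], 300), "exceeds")
})
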