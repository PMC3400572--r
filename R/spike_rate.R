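#' Poisson synaptic drive specification
#'
#' Independent homogeneous Poisson event trains, one per synapse in a
#' cluster. Events are unsynchronized within and between groups; each event
#' activates the synapse's AMPA and NMDA conductances (NMDA fixed at
#' `nmda_gmax`; no pulse-to-pulse facilitation in the rate regime).
#'
#' @param center_um cluster centre, um path distance from the soma
#' @param n_syn number of synapses
#' @param rate event rate per synapse, Hz
#' @param duration ms
#' @param nmda_gmax,ampa_gmax per-event peak conductances, nS
#' @return a `poisson_drive` list
#' @export
poisson_drive <- function(center_um, n_syn, rate = 50, duration = 500,
                          nmda_gmax = 3.9, ampa_gmax = 1.5) {
  stopifnot(n_syn >= 0, rate >= 0, duration > 0)
  structure(list(center_um = center_um, n_syn = n_syn, rate = rate,
                 duration = duration, nmda_gmax = nmda_gmax,
                 ampa_gmax = ampa_gmax),
            class = "poisson_drive")
}

#' Draw Poisson event trains for a drive
#'
#' Exponential inter-event intervals per synapse; reproducible under
#' `set.seed()` before the call (all stochastic pieces of the rate protocol
#' consume the session RNG stream).
#'
#' @param drive a [poisson_drive()]
#' @return list of numeric vectors (event times in ms), one per synapse
#' @export
generate_poisson <- function(drive) {
  lapply(seq_len(drive$n_syn), function(s) {
    if (drive$rate <= 0) return(numeric(0))
    # expected count + margin, then truncate to the window
    n_draw <- max(10, ceiling(drive$rate * drive$duration / 1000 * 2 + 20))
    t <- cumsum(rexp(n_draw, rate = drive$rate / 1000))
    while (length(t) && t[length(t)] < drive$duration) {
      t <- c(t, t[length(t)] + cumsum(rexp(n_draw, rate = drive$rate / 1000)))
    }
    t[t < drive$duration]
  })
}

# events data.frame for a Poisson drive on a given terminal branch
poisson_events <- function(model, branch, drive, trains = NULL) {
  if (is.null(trains)) trains <- generate_poisson(drive)
  sites <- cluster_at_path(model, branch, drive$center_um, drive$n_syn)
  n_ev <- vapply(trains, length, 0L)
  if (sum(n_ev) == 0) return(empty_events())
  sec <- rep(sites$section, n_ev)
  pos <- rep(sites$pos_um, n_ev)
  onset <- unlist(trains)
  a <- ampa_spec(drive$ampa_gmax)
  nm <- nmda_spec(drive$nmda_gmax)
  rbind(
    data.frame(section = sec, pos_um = pos, onset = onset, kind = "AMPA",
               g_max = a$g_max, tau_rise = a$tau_rise, tau_fall = a$tau_fall,
               e_rev = a$e_rev, mg_half = NA, mg_slope = NA),
    data.frame(section = sec, pos_um = pos, onset = onset, kind = "NMDA",
               g_max = nm$g_max, tau_rise = nm$tau_rise,
               tau_fall = nm$tau_fall, e_rev = nm$e_rev,
               mg_half = nm$mg_half, mg_slope = nm$mg_slope)
  )
}

#' Calibrate the somatic bias current to a target background rate
#'
#' The rate protocol biases the soma with a noisy current (sd 1 nA, redrawn
#' every 0.1 ms) so the cell fires a low background rate with no synaptic
#' drive. The printed mean of 0.75 nA applies to the full reconstructed cell;
#' on a reduced morphology the mean is found by bisection so that the
#' background rate lands in `target_hz` (default 0.5-2 Hz, i.e. the ~1 Hz
#' regime).
#'
#' @param model a [basal_model()]
#' @param target_hz acceptable background-rate window, Hz
#' @param sd_nA,interval_ms noise parameters
#' @param duration calibration run length per evaluation, ms
#' @param reps runs averaged per evaluation
#' @param seed RNG seed
#' @param lower,upper initial bisection bracket, nA
#' @return list with `mean_nA`, `rate_hz`, `evaluations`
#' @export
calibrate_bias <- function(model, target_hz = c(0.5, 2), sd_nA = 1,
                           interval_ms = 0.1, duration = 1000, reps = 2,
                           seed = 42, lower = 0, upper = 3) {
  rate_at <- function(mean_nA) {
    set.seed(seed)
    mean(vapply(seq_len(reps), function(r) {
      sim <- simulate_cable(model$morph, model$membrane, model$channels,
                            bias = list(mean_nA = mean_nA, sd_nA = sd_nA,
                                        interval_ms = interval_ms),
                            duration = duration, dt = model$dt)
      length(spike_times(sim)) / (duration / 1000)
    }, 0))
  }
  evals <- list()
  lo <- lower; hi <- upper
  r_hi <- rate_at(hi)
  if (r_hi < target_hz[1]) stop("upper bias bound gives rate below target")
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    evals[[length(evals) + 1]] <- c(mean_nA = mid, rate_hz = r)
    if (r >= target_hz[1] && r <= target_hz[2]) {
      return(list(mean_nA = mid, rate_hz = r,
                  evaluations = do.call(rbind, evals)))
    }
    if (r > target_hz[2]) hi <- mid else lo <- mid
  }
  list(mean_nA = mid, rate_hz = r, evaluations = do.call(rbind, evals))
}

#' Firing-rate input-output experiment
#'
#' Delivers independent 50 Hz Poisson trains to a driver group and a
#' modulator group of synapses (both on one dendrite, or on two different
#' dendrites for the between-branch control), biases the soma with noisy
#' current, and measures the mean somatic spike rate over the stimulus
#' window across repetitions.
#'
#' @param model a [basal_model()]
#' @param prox_counts,dist_counts synapse-count levels at the proximal
#'   (90 um) and distal (190 um) sites
#' @param reps repetitions per condition
#' @param layout `"same_branch"` or `"different_branches"`
#' @param bias_mean_nA somatic bias mean (from [calibrate_bias()]); sd 1 nA,
#'   redrawn every 0.1 ms
#' @param loc_prox,loc_dist site path distances, um
#' @param duration stimulus window, ms
#' @param rate Poisson rate per synapse, Hz
#' @param seed base RNG seed (each condition/rep derives its own substream)
#' @return a `rate_family`: list with `prox_counts`, `dist_counts`, `rates`
#'   (array reps x prox x dist), `mean` and `se` matrices (prox x dist),
#'   `layout`
#' @export
run_rate_experiment <- function(model, prox_counts = c(0, 17, 21, 25),
                                dist_counts = c(0, 3, 6, 9), reps = 20,
                                layout = c("same_branch", "different_branches"),
                                bias_mean_nA = 0.75, loc_prox = 90,
                                loc_dist = 190, duration = 500, rate = 50,
                                seed = 1) {
  layout <- match.arg(layout)
  b1 <- first_basal(model)
  b2 <- if (layout == "same_branch") b1 else nth_basal(model, 2)
  rates <- array(NA_real_,
                 dim = c(reps, length(prox_counts), length(dist_counts)))
  for (ip in seq_along(prox_counts)) {
    for (id in seq_along(dist_counts)) {
      for (r in seq_len(reps)) {
        set.seed(seed + 7919L * r + 101L * ip + 13L * id)
        ev <- empty_events()
        if (prox_counts[ip] > 0) {
          ev <- rbind(ev, poisson_events(model, b1,
            poisson_drive(loc_prox, prox_counts[ip], rate, duration)))
        }
        if (dist_counts[id] > 0) {
          ev <- rbind(ev, poisson_events(model, b2,
            poisson_drive(loc_dist, dist_counts[id], rate, duration)))
        }
        sim <- simulate_cable(model$morph, model$membrane, model$channels, ev,
                              bias = list(mean_nA = bias_mean_nA, sd_nA = 1,
                                          interval_ms = 0.1),
                              duration = duration, dt = model$dt)
        rates[r, ip, id] <- length(spike_times(sim)) / (duration / 1000)
      }
    }
  }
  mean_mat <- apply(rates, c(2, 3), mean)
  se_mat <- apply(rates, c(2, 3), function(x) sd(x) / sqrt(length(x)))
  structure(list(prox_counts = prox_counts, dist_counts = dist_counts,
                 rates = rates, mean = mean_mat, se = se_mat,
                 layout = layout, duration = duration, reps = reps),
            class = "rate_family")
}

#' @export
print.rate_family <- function(x, ...) {
  cat(sprintf("<rate_family> %s, %d reps, rates %.1f-%.1f Hz\n", x$layout,
              x$reps, min(x$mean), max(x$mean)))
  invisible(x)
}

#' Fit a sigmoid to a firing-rate input-output curve
#'
#' Least-squares fit of \eqn{r(x) = r_0 + A / (1 + e^{-(x - \theta)/s})}
#' with multiple starting points (theta started at each interior data point,
#' s at a quarter and a half of the x range). The gain is the maximum slope
#' \eqn{\alpha = A / (4 s)}. A curve with no appreciable range (flat) is
#' flagged `degenerate` and returns `A ~ 0` with `theta = NA`.
#'
#' @param x driver counts
#' @param y mean rates, Hz
#' @return a `sigmoid_fit`: list with `r0`, `A`, `theta`, `s`, `alpha`,
#'   `residual` (RMS), `degenerate`
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  rng <- diff(range(y))
  if (rng < max(1e-8, 0.02 * max(abs(y), 1e-8))) {
    return(structure(list(r0 = mean(y), A = 0, theta = NA_real_, s = NA_real_,
                          alpha = 0, residual = sd(y), degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  starts <- expand.grid(theta = x[2:(length(x) - 1)],
                        s = c(diff(range(x)) / 4, diff(range(x)) / 8))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ r0 + A / (1 + exp(-(x - theta) / s)),
                        start = list(r0 = min(y), A = rng,
                                     theta = starts$theta[k], s = starts$s[k]),
                        lower = c(r0 = -Inf, A = 0, theta = -Inf, s = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from all starts")
  cf <- coef(best$fit)
  structure(list(r0 = cf[["r0"]], A = cf[["A"]], theta = cf[["theta"]],
                 s = cf[["s"]], alpha = cf[["A"]] / (4 * cf[["s"]]),
                 residual = sqrt(best$rss / length(x)), degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<sigmoid_fit> degenerate (flat): r0=%.2f Hz\n", x$r0))
  } else {
    cat(sprintf("<sigmoid_fit> r0=%.2f A=%.2f theta=%.2f s=%.2f alpha=%.3f Hz/syn\n",
                x$r0, x$A, x$theta, x$s, x$alpha))
  }
  invisible(x)
}

#' Additivity score of a rate family
#'
#' Maximum absolute deviation of the interaction term
#' \eqn{r(i,j) - r(i,0) - r(0,j) + r(0,0)} over the grid, divided by the
#' family's dynamic range. Zero for perfectly additive rate surfaces
#' (between-branch summation); large for nonlinear within-branch
#' interaction. Invariant to adding a constant to all rates.
#'
#' @param fam a `rate_family` (mean rates are used)
#' @return deviation score (dimensionless)
#' @export
additivity_metric <- function(fam) {
  m <- fam$mean
  rng <- diff(range(m))
  if (rng == 0) return(0)
  dev <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      dev <- max(dev, abs(m[i, j] - m[i, 1] - m[1, j] + m[1, 1]))
    }
  }
  dev / rng
}
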