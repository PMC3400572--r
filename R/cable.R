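#' Voltage-dependent magnesium block of the NMDA conductance
#'
#' \eqn{B(V) = 1 / (1 + e^{-(V + V_{1/2})/k})}: the fraction of NMDA
#' conductance available at membrane potential V. The compartmental model uses
#' the midpoint/slope pair (12, 10) mV; the time-invariant two-compartment
#' circuit uses a softer (22, 12) mV variant to absorb the dilution of the
#' NMDA nonlinearity by co-activated AMPA channels it does not model.
#'
#' @param v membrane potential, mV (vectorized)
#' @param mg_half sigmoid midpoint offset, mV
#' @param mg_slope sigmoid slope, mV (nonzero)
#' @return fraction in (0, 1)
#' @export
mg_block <- function(v, mg_half = 12, mg_slope = 10) {
  if (mg_slope == 0) stop("mg_slope must be nonzero")
  1 / (1 + exp(-(v + mg_half) / mg_slope))
}

#' Dual-exponential synaptic conductance waveform
#'
#' \eqn{g(t) = g_{max} (e^{-t/\tau_{fall}} - e^{-t/\tau_{rise}}) / k}, where k
#' peak-normalizes the bracket so the waveform maximum is exactly `g_max`
#' (attained at \eqn{t^* = \ln(\tau_f/\tau_r)\,\tau_r\tau_f/(\tau_f-\tau_r)}).
#'
#' @param t time since onset, ms (vectorized; values < 0 give 0)
#' @param spec a [synapse_spec()]
#' @return conductance in nS
#' @export
dual_exp_g <- function(t, spec) {
  tr <- spec$tau_rise; tf <- spec$tau_fall
  tp <- log(tf / tr) * tr * tf / (tf - tr)
  norm <- exp(-tp / tf) - exp(-tp / tr)
  ifelse(t <= 0, 0, spec$g_max * (exp(-t / tf) - exp(-t / tr)) / norm)
}

#' Place a synapse cluster on a branch
#'
#' `n` sites at `spacing` um intervals, symmetric about `center`, each later
#' mapped to its containing electrical segment.
#'
#' @param m a `morphology`
#' @param branch section id of the target branch
#' @param center cluster centre, um path distance along the branch
#' @param n number of synapses
#' @param spacing inter-synapse spacing, um
#' @return data.frame with columns `section`, `pos_um`
#' @export
place_cluster <- function(m, branch, center, n, spacing = 0.5) {
  i <- match(branch, m$sections$id)
  if (is.na(i)) stop("unknown branch id: ", branch)
  if (n == 0) return(data.frame(section = integer(0), pos_um = numeric(0)))
  pos <- center + spacing * (seq_len(n) - (n + 1) / 2)
  if (min(pos) < 0 || max(pos) > m$sections$length[i]) {
    stop(sprintf("cluster span [%.2f, %.2f] um exceeds branch %d (length %.1f um)",
                 min(pos), max(pos), branch, m$sections$length[i]))
  }
  data.frame(section = branch, pos_um = pos)
}

#' Build AMPA+NMDA stimulus events for a set of sites
#'
#' Each site receives one AMPA and one NMDA synapse activated at `onset`.
#' Setting `nmda_gmax = 0` emulates NMDA-receptor block.
#'
#' @param sites data.frame with `section`, `pos_um` (e.g. from
#'   [place_cluster()])
#' @param onset activation time, ms
#' @param nmda_gmax,ampa_gmax peak conductances, nS
#' @return event data.frame (one row per synapse)
#' @export
synapse_events <- function(sites, onset = 5, nmda_gmax = 3.56, ampa_gmax = 1.5) {
  ev <- list()
  if (ampa_gmax > 0 && nrow(sites)) {
    a <- ampa_spec(ampa_gmax)
    ev$ampa <- data.frame(section = sites$section, pos_um = sites$pos_um,
                          onset = onset, kind = "AMPA", g_max = ampa_gmax,
                          tau_rise = a$tau_rise, tau_fall = a$tau_fall,
                          e_rev = a$e_rev, mg_half = NA, mg_slope = NA)
  }
  if (nmda_gmax > 0 && nrow(sites)) {
    nm <- nmda_spec(nmda_gmax)
    ev$nmda <- data.frame(section = sites$section, pos_um = sites$pos_um,
                          onset = onset, kind = "NMDA", g_max = nmda_gmax,
                          tau_rise = nm$tau_rise, tau_fall = nm$tau_fall,
                          e_rev = nm$e_rev, mg_half = nm$mg_half,
                          mg_slope = nm$mg_slope)
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(section = integer(0), pos_um = numeric(0), onset = numeric(0),
             kind = character(0), g_max = numeric(0), tau_rise = numeric(0),
             tau_fall = numeric(0), e_rev = numeric(0), mg_half = numeric(0),
             mg_slope = numeric(0))
}

#' Double-pulse stimulus events (50 Hz pair with NMDA facilitation)
#'
#' Two activations separated by `interval` ms (default 20 ms, i.e. 50 Hz).
#' The AMPA peak conductance is fixed across pulses while the NMDA peak
#' conductance doubles from the first to the second pulse (2.23 to 4.46 nS by
#' default), modelling use-dependent NMDA facilitation as a per-pulse
#' conductance schedule.
#'
#' @param sites data.frame with `section`, `pos_um`
#' @param t0 first-pulse onset, ms
#' @param interval inter-pulse interval, ms
#' @param nmda_g1 first-pulse NMDA peak conductance, nS
#' @param facilitation second-pulse/first-pulse NMDA conductance ratio
#' @param ampa_gmax AMPA peak conductance (both pulses), nS
#' @return event data.frame; attribute `nmda_gmax_pulse` records the per-pulse
#'   NMDA schedule
#' @export
double_pulse_events <- function(sites, t0 = 5, interval = 20,
                                nmda_g1 = 2.23, facilitation = 2,
                                ampa_gmax = 1.5) {
  g2 <- nmda_g1 * facilitation
  ev <- rbind(
    synapse_events(sites, onset = t0, nmda_gmax = nmda_g1, ampa_gmax = ampa_gmax),
    synapse_events(sites, onset = t0 + interval, nmda_gmax = g2,
                   ampa_gmax = ampa_gmax)
  )
  attr(ev, "nmda_gmax_pulse") <- c(nmda_g1, g2)
  ev
}

# ---- compartmentalization -------------------------------------------------

# Flatten a discretized morphology into compartment arrays for the C++ core.
build_compartments <- function(m, membrane, channels) {
  s <- m$sections
  ord <- topo_order(s)
  n_total <- sum(m$nseg[ord])
  parent <- integer(n_total); cm <- numeric(n_total)
  g_leak <- numeric(n_total); g_ax <- numeric(n_total)
  gna <- numeric(n_total); gk <- numeric(n_total)
  sec_first <- integer(nrow(s)); sec_last <- integer(nrow(s))
  seg_len <- numeric(n_total); seg_r_half <- numeric(n_total)
  sec_of <- integer(n_total); seg_idx <- integer(n_total)

  # path distance of each section's proximal end (soma contributes 0)
  prox_dist <- numeric(nrow(s))
  for (i in ord) {
    p <- match(s$parent_id[i], s$id)
    prox_dist[i] <- if (is.na(p)) 0
      else prox_dist[p] + if (s$kind[p] == "soma") 0 else s$length[p]
  }

  # optional linear taper: sections may carry diam_prox/diam_tip columns
  has_taper <- all(c("diam_prox", "diam_tip") %in% names(s))

  k <- 0L
  for (i in ord) {
    nseg <- m$nseg[i]
    L <- s$length[i] / nseg                       # um
    sp <- if (isTRUE(s$spine_corrected[i])) 2 else 1
    cm_spec <- region_value(membrane$c_m, s$kind[i]) * sp            # uF/cm^2
    rmi <- region_value(membrane$r_m, s$kind[i])                     # kOhm cm^2
    gna_base <- region_value(channels$gbar_na, s$kind[i])            # S/cm^2
    gk_base <- region_value(channels$gbar_k, s$kind[i])
    dp <- if (has_taper && !is.na(s$diam_prox[i])) s$diam_prox[i] else s$diameter[i]
    dtip <- if (has_taper && !is.na(s$diam_tip[i])) s$diam_tip[i] else s$diameter[i]
    for (j in seq_len(nseg)) {
      k <- k + 1L
      if (j == 1L) {
        p <- match(s$parent_id[i], s$id)
        parent[k] <- if (is.na(p)) 0L else sec_last[p]
      } else {
        parent[k] <- k - 1L
      }
      d <- dp + (j - 0.5) / nseg * (dtip - dp)    # segment-centre diameter, um
      area <- pi * d * L * 1e-8                   # cm^2
      r_half <- membrane$r_a * (L / 2 * 1e-4) / (pi * (d / 2 * 1e-4)^2)
      cm[k] <- cm_spec * area * 1e3               # nF
      g_leak[k] <- sp * area / rmi * 1e3          # uS
      gb_na <- gna_base
      if (s$kind[i] %in% c("basal", "apical")) {
        x <- prox_dist[i] + (j - 0.5) * L
        gb_na <- gna_base * max(0, 1 - x / channels$na_taper_end)
      }
      gna[k] <- gb_na * area * 1e6                                  # uS
      gk[k] <- gk_base * area * 1e6
      seg_len[k] <- L; seg_r_half[k] <- r_half
      sec_of[k] <- s$id[i]; seg_idx[k] <- j
      if (j == 1L) sec_first[i] <- k
    }
    sec_last[i] <- k
  }
  # axial conductance to parent: series of the two half-segment resistances
  for (k2 in seq_len(n_total)) {
    p <- parent[k2]
    if (p == 0L) { g_ax[k2] <- 0; next }
    g_ax[k2] <- 1e6 / (seg_r_half[k2] + seg_r_half[p])
  }
  list(parent = parent - 1L, cm = cm, g_leak = g_leak, g_ax = g_ax,
       gna = gna, gk = gk, sec_of = sec_of, seg_idx = seg_idx,
       sec_first = sec_first, sec_last = sec_last, seg_len = seg_len,
       sections = s, nseg = m$nseg)
}

# compartment index (1-based) containing path position pos_um on a section
comp_at <- function(comp, section, pos_um) {
  i <- match(section, comp$sections$id)
  if (is.na(i)) stop("unknown section id: ", section)
  nseg <- comp$nseg[i]
  L <- comp$sections$length[i]
  j <- pmin(nseg, pmax(1L, as.integer(ceiling(pos_um / L * nseg))))
  comp$sec_first[i] + j - 1L
}

# ---- simulation -----------------------------------------------------------

#' Simulate the compartmental model
#'
#' Solves the spatially discretized cable equation with leak,
#' Hodgkin-Huxley-style Na/K, and synaptic currents. The voltage step is
#' Crank-Nicolson (unconditionally stable, second order) with an exact sparse
#' tree solve per step; gating variables advance by exponential Euler. The
#' NMDA current at each synapse is \eqn{g(t) B(V) (E_{rev} - V)} with B the
#' instantaneous magnesium block. The initial condition is the resting state
#' obtained by a `pre_ms` equilibration phase with no inputs.
#'
#' @param m a discretized `morphology` (see [discretize()])
#' @param membrane [membrane_params()]
#' @param channels [channel_params()] (pass conductances of 0 for a passive run)
#' @param events event data.frame ([synapse_events()], [double_pulse_events()],
#'   or rows bound from several calls); may be empty
#' @param bias optional somatic current source: either
#'   `list(amp_nA=, start=, stop=, section=)` for a constant step or
#'   `list(mean_nA=, sd_nA=, interval_ms=, section=)` for a piecewise-constant
#'   noisy injection redrawn every `interval_ms`
#' @param duration simulated time, ms
#' @param dt integration step, ms
#' @param record data.frame of recording sites (`section`, `pos_um`) or
#'   `"soma"`; the soma is always recorded
#' @param pre_ms pre-equilibration time, ms
#' @return a `sim_result`: list with `time` (ms), `v` (matrix, mV, one column
#'   per recorded site, first column `soma`), `dt`, `duration`, `rest`
#'   (initial voltages)
#' @export
simulate_cable <- function(m, membrane = membrane_params(),
                           channels = channel_params(), events = empty_events(),
                           bias = NULL, duration = 100, dt = 0.1,
                           record = "soma", pre_ms = 200) {
  stopifnot(dt > 0, duration > 0)
  comp <- build_compartments(m, membrane, channels)
  soma_sec <- comp$sections$id[comp$sections$kind == "soma"][1]
  if (is.na(soma_sec)) soma_sec <- comp$sections$id[is.na(comp$sections$parent_id)]
  soma_comp <- comp_at(comp, soma_sec, comp$sections$length[
    match(soma_sec, comp$sections$id)] / 2)

  rec_comp <- soma_comp
  rec_names <- "soma"
  if (is.data.frame(record) && nrow(record)) {
    extra <- mapply(function(sec, pos) comp_at(comp, sec, pos),
                    record$section, record$pos_um)
    rec_comp <- c(rec_comp, extra)
    rec_names <- c(rec_names, sprintf("s%d@%g", record$section, record$pos_um))
  }

  if (nrow(events)) {
    syn_comp <- mapply(function(sec, pos) comp_at(comp, sec, pos),
                       events$section, events$pos_um)
    is_nmda <- events$kind == "NMDA"
    syn <- list(comp = as.integer(syn_comp) - 1L, onset = events$onset,
                gmax = events$g_max / 1000,     # nS -> uS
                tau_r = events$tau_rise, tau_f = events$tau_fall,
                erev = events$e_rev, nmda = is_nmda,
                mg_half = ifelse(is_nmda, events$mg_half, 0),
                mg_slope = ifelse(is_nmda, events$mg_slope, 1))
  } else {
    syn <- list(comp = integer(0), onset = numeric(0), gmax = numeric(0),
                tau_r = numeric(0), tau_f = numeric(0), erev = numeric(0),
                nmda = logical(0), mg_half = numeric(0), mg_slope = numeric(0))
  }

  inj_comp <- integer(0); inj_amp <- numeric(0)
  inj_start <- numeric(0); inj_stop <- numeric(0)
  noise_comp <- -1L; noise_mean <- 0; noise_sd <- 0; noise_int <- 1
  if (!is.null(bias)) {
    bsec <- if (!is.null(bias$section)) bias$section else soma_sec
    bcomp <- comp_at(comp, bsec,
                     comp$sections$length[match(bsec, comp$sections$id)] / 2)
    if (!is.null(bias$mean_nA)) {
      noise_comp <- bcomp - 1L
      noise_mean <- bias$mean_nA
      noise_sd <- if (!is.null(bias$sd_nA)) bias$sd_nA else 0
      noise_int <- if (!is.null(bias$interval_ms)) bias$interval_ms else dt
    } else {
      inj_comp <- bcomp - 1L
      inj_amp <- bias$amp_nA
      inj_start <- if (!is.null(bias$start)) bias$start else 0
      inj_stop <- if (!is.null(bias$stop)) bias$stop else duration
    }
  }

  res <- cable_core(comp$parent, comp$cm, comp$g_leak,
                    rep(membrane$e_leak, length(comp$cm)), comp$g_ax,
                    comp$gna, comp$gk, channels$e_na, channels$e_k,
                    channels$q10_rate, channels$k_exponent, channels$na_shift,
                    channels$na_inact_shift,
                    syn$comp, syn$onset, syn$gmax, syn$tau_r, syn$tau_f,
                    syn$erev, syn$nmda, syn$mg_half, syn$mg_slope,
                    as.integer(inj_comp), inj_amp, inj_start, inj_stop,
                    noise_comp, noise_mean, noise_sd, noise_int,
                    dt, duration, pre_ms, as.integer(rec_comp) - 1L)
  v <- res$v
  colnames(v) <- rec_names
  if (!all(is.finite(v))) stop("integration produced non-finite voltages")
  structure(list(time = res$time, v = v, dt = dt, duration = duration,
                 rest = v[1, ]),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g ms @ dt=%g ms, sites: %s\n", x$duration, x$dt,
              paste(colnames(x$v), collapse = ", ")))
  invisible(x)
}

#' Peak depolarization of a recorded site
#'
#' Maximum over time of V(site) - V_rest(site), where rest is the
#' post-equilibration initial voltage.
#'
#' @param r a `sim_result`
#' @param site column name (default `"soma"`)
#' @return peak depolarization, mV
#' @export
peak_depolarization <- function(r, site = "soma") {
  max(r$v[, site] - r$v[1, site])
}

#' Detect somatic spikes in a voltage trace
#'
#' Upward crossings of `threshold` (default 0 mV) separated by at least
#' `refractory_ms`.
#'
#' @param r a `sim_result`
#' @param site trace column
#' @param threshold crossing level, mV
#' @param refractory_ms minimum inter-spike interval
#' @return spike times, ms
#' @export
spike_times <- function(r, site = "soma", threshold = 0, refractory_ms = 2) {
  v <- r$v[, site]
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  t <- r$time[up + 1]
  if (!length(t)) return(numeric(0))
  keep <- t[1]
  for (tt in t[-1]) if (tt - keep[length(keep)] >= refractory_ms) keep <- c(keep, tt)
  keep
}
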