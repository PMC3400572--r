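#' Measure EPSP time-course metrics on a voltage trace
#'
#' Amplitude (peak minus baseline), half-width (width at 50% of amplitude,
#' linearly interpolated between samples) and 10-90% rise time on the rising
#' phase. Baseline is the mean over `baseline_window` (ms).
#'
#' @param time,v trace vectors (ms, mV)
#' @param baseline_window `c(t0, t1)` over which to average the baseline
#' @param noise_floor minimum amplitude counted as an EPSP, mV
#' @param rise_frac rise-time fractions (default 10-90%)
#' @return list with `amplitude` (mV), `halfwidth` (ms), `risetime` (ms),
#'   `t_peak` (ms)
#' @export
measure_epsp <- function(time, v, baseline_window = c(0, min(5, max(time))),
                         noise_floor = 1e-3, rise_frac = c(0.1, 0.9)) {
  stopifnot(length(time) == length(v), length(time) >= 3)
  base_idx <- time >= baseline_window[1] & time <= baseline_window[2]
  baseline <- mean(v[base_idx])
  dv <- v - baseline
  ipk <- which.max(dv)
  amp <- dv[ipk]
  if (amp <= noise_floor) stop("no peak above baseline + noise floor")

  cross <- function(level, idx_range, rising) {
    # first crossing of `level` scanning idx_range in order
    for (k in seq_along(idx_range)[-1]) {
      i0 <- idx_range[k - 1]; i1 <- idx_range[k]
      y0 <- dv[i0]; y1 <- dv[i1]
      hit <- if (rising) (y0 < level && y1 >= level) else (y0 >= level && y1 < level)
      if (hit) {
        return(time[i0] + (level - y0) / (y1 - y0) * (time[i1] - time[i0]))
      }
    }
    NA_real_
  }
  t_r1 <- cross(rise_frac[1] * amp, seq_len(ipk), rising = TRUE)
  t_r2 <- cross(rise_frac[2] * amp, seq_len(ipk), rising = TRUE)
  t_h1 <- cross(0.5 * amp, seq_len(ipk), rising = TRUE)
  t_h2 <- cross(0.5 * amp, ipk:length(dv), rising = FALSE)
  if (anyNA(c(t_r1, t_r2, t_h1, t_h2))) {
    stop("trace does not bracket the EPSP (incomplete rise or decay)")
  }
  list(amplitude = amp, halfwidth = t_h2 - t_h1, risetime = t_r2 - t_r1,
       t_peak = time[ipk])
}

#' Somatic EPSP metrics versus synapse distance
#'
#' For each requested distance, places 4 simultaneous AMPA-only synapses on
#' 4 randomly selected basal dendrites at that path distance and measures the
#' compound somatic EPSP, repeating over `n_sets` random dendrite sets. The
#' EPSP protocol uses fast AMPA kinetics (0.2/2 ms, 2 nS) on a passive
#' membrane with R_m and C_m scaled by 1.6 (matching the slower EPSP
#' half-width range of the cortical data this analysis mirrors).
#'
#' @param model a [basal_model()] (its passive 1.6x variant is built
#'   internally; set `rm_cm_factor = 1` to disable)
#' @param distances path distances, um
#' @param n_sets random dendrite sets per distance
#' @param synapses_per_set synapses (= dendrites) per set
#' @param seed RNG seed
#' @param rm_cm_factor joint R_m/C_m scale factor
#' @param g_max,tau_rise,tau_fall AMPA synapse parameters (nS, ms)
#' @param onset,duration simulation window, ms
#' @return data.frame: distance, set, amplitude, halfwidth, risetime
#' @export
distance_sweep <- function(model, distances = c(50, 150, 250), n_sets = 10,
                           synapses_per_set = 4, seed = 1, rm_cm_factor = 1.6,
                           g_max = 2, tau_rise = 0.2, tau_fall = 2,
                           onset = 5, duration = 120) {
  pm <- passive_model(model, rm_cm_factor = rm_cm_factor)
  s <- pm$morph$sections
  term <- s$id[s$kind == "basal" & !(s$id %in% s$parent_id)]
  reach <- vapply(term, function(id) path_distance(pm$morph, id), 0)
  for (d in distances) {
    if (!any(reach >= d)) stop(sprintf("no dendrite reaches %g um", d))
  }
  replace_draw <- length(term) < synapses_per_set
  if (replace_draw) {
    message(sprintf("only %d terminal dendrites; drawing sets with replacement",
                    length(term)))
  }
  set.seed(seed)
  out <- list()
  for (d in distances) {
    ok <- term[reach >= d]
    for (st in seq_len(n_sets)) {
      picks <- sample(ok, synapses_per_set, replace = replace_draw ||
                        length(ok) < synapses_per_set)
      sites <- do.call(rbind, lapply(picks, function(b) {
        si <- site_at_path(pm$morph, b, d)
        data.frame(section = si$section, pos_um = si$pos_um)
      }))
      spec <- synapse_spec("AMPA", g_max, tau_rise, tau_fall)
      ev <- data.frame(section = sites$section, pos_um = sites$pos_um,
                       onset = onset, kind = "AMPA", g_max = g_max,
                       tau_rise = tau_rise, tau_fall = tau_fall,
                       e_rev = spec$e_rev, mg_half = NA, mg_slope = NA)
      sim <- simulate_cable(pm$morph, pm$membrane, pm$channels, ev,
                            duration = duration, dt = pm$dt)
      met <- measure_epsp(sim$time, sim$v[, "soma"],
                          baseline_window = c(0, onset - 1))
      out[[length(out) + 1]] <- data.frame(distance = d, set = st,
                                           amplitude = met$amplitude,
                                           halfwidth = met$halfwidth,
                                           risetime = met$risetime)
    }
  }
  do.call(rbind, out)
}

#' Summarize a distance sweep
#'
#' @param sweep output of [distance_sweep()]
#' @return data.frame of per-distance means and s.d.
#' @export
summarize_sweep <- function(sweep) {
  agg <- function(f) {
    a <- stats::aggregate(cbind(amplitude, halfwidth, risetime) ~ distance,
                          data = sweep, FUN = f)
    a
  }
  m <- agg(mean); s <- agg(sd)
  names(m)[-1] <- paste0(names(m)[-1], "_mean")
  names(s)[-1] <- paste0(names(s)[-1], "_sd")
  merge(m, s, by = "distance")
}

#' Two-sample comparison report (Welch t and Wilcoxon rank-sum)
#'
#' Thin wrapper mirroring the comparison machinery used for EPSP time-course
#' group contrasts: Welch's two-sample t test and the Wilcoxon rank-sum
#' (Mann-Whitney) test.
#'
#' @param a,b numeric samples
#' @param alternative passed to the underlying tests
#' @param exact force the exact rank-sum null distribution (default: let
#'   `wilcox.test` decide, which uses the normal approximation when ties are
#'   present)
#' @return data.frame with method, statistic, p.value
#' @export
compare_groups <- function(a, b, alternative = "two.sided", exact = NULL) {
  tt <- t.test(a, b, alternative = alternative)
  if (is.null(exact) && anyDuplicated(c(a, b))) exact <- FALSE
  wt <- wilcox.test(a, b, alternative = alternative, exact = exact)
  data.frame(method = c("welch_t", "wilcoxon_rank_sum"),
             statistic = c(unname(tt$statistic), unname(wt$statistic)),
             p.value = c(tt$p.value, wt$p.value))
}
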