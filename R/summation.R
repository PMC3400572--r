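#' Two-input summation map
#'
#' Peak somatic depolarization over a grid of (proximal, distal) synapse
#' counts delivered simultaneously to two sites on a basal dendrite.
#'
#' @name two_input_map
NULL

new_two_input_map <- function(n_prox, n_dist, peaks, meta = list()) {
  stopifnot(nrow(peaks) == length(n_prox), ncol(peaks) == length(n_dist))
  if (n_prox[1] == 0 && n_dist[1] == 0 && abs(peaks[1, 1]) > 1e-9) {
    stop("peaks[0, 0] must be 0")
  }
  structure(list(n_prox = n_prox, n_dist = n_dist, peaks = peaks, meta = meta),
            class = "two_input_map")
}

#' @export
print.two_input_map <- function(x, ...) {
  cat(sprintf("<two_input_map> %dx%d grid, peak %.2f mV", length(x$n_prox),
              length(x$n_dist), max(x$peaks)))
  if (!is.null(x$meta$loc_prox)) {
    cat(sprintf(" (sites %g/%g um)", x$meta$loc_prox, x$meta$loc_dist))
  }
  cat("\n")
  invisible(x)
}

# package-local cache for grid maps (keyed by a hash of the full config)
.map_cache <- new.env(parent = emptyenv())

#' Map two-input summation on the compartmental model
#'
#' Simulates all combinations of (n_prox, n_dist) synapse counts at two path
#' distances on a basal branch (simultaneous activation of both clusters) and
#' records the peak somatic depolarization. Results are memoized in-session,
#' keyed by a hash of the morphology, parameters and protocol.
#'
#' @param model a [basal_model()]
#' @param loc_prox,loc_dist site path distances from the soma, um
#' @param n_max largest synapse count per site
#' @param step grid step in synapse count (2 gives the default 21x21 grid)
#' @param protocol `"double_pulse"` (50 Hz pair, facilitated NMDA 2.23/4.46
#'   nS - the two-input mapping condition) or `"single_pulse"` (NMDA
#'   `nmda_gmax`)
#' @param branch_prox,branch_dist terminal branch ids (defaults: both on the
#'   first basal branch; set `branch_dist` to a different dendrite for the
#'   between-branch control)
#' @param nmda_gmax single-pulse NMDA peak conductance, nS
#' @param duration,onset simulation window, ms
#' @param cache reuse memoized results for identical configurations
#' @return a `two_input_map`
#' @export
map_two_input <- function(model, loc_prox = 90, loc_dist = 150, n_max = 40,
                          step = 2, protocol = c("double_pulse", "single_pulse"),
                          branch_prox = NULL, branch_dist = NULL,
                          nmda_gmax = 3.56, duration = NULL, onset = 5,
                          cache = TRUE) {
  protocol <- match.arg(protocol)
  if (is.null(branch_prox)) branch_prox <- first_basal(model)
  if (is.null(branch_dist)) branch_dist <- branch_prox
  if (branch_prox == branch_dist && loc_prox >= loc_dist) {
    stop("need loc_prox < loc_dist for the within-branch configuration")
  }
  if (is.null(duration)) {
    duration <- if (protocol == "double_pulse") 120 else 100
  }
  counts <- seq(0, n_max, by = step)
  key <- rlang::hash(list(model, loc_prox, loc_dist, counts, protocol,
                          branch_prox, branch_dist, nmda_gmax, duration, onset))
  if (cache && !is.null(.map_cache[[key]])) return(.map_cache[[key]])

  build_events <- function(n_p, n_d) {
    ev <- empty_events()
    mk <- function(sites) {
      if (protocol == "double_pulse") {
        double_pulse_events(sites, t0 = onset)
      } else {
        synapse_events(sites, onset = onset, nmda_gmax = nmda_gmax)
      }
    }
    if (n_p > 0) ev <- rbind(ev, mk(cluster_at_path(model, branch_prox, loc_prox, n_p)))
    if (n_d > 0) ev <- rbind(ev, mk(cluster_at_path(model, branch_dist, loc_dist, n_d)))
    ev
  }
  peaks <- matrix(0, length(counts), length(counts))
  for (i in seq_along(counts)) {
    for (j in seq_along(counts)) {
      if (counts[i] == 0 && counts[j] == 0) next
      r <- simulate_cable(model$morph, model$membrane, model$channels,
                          build_events(counts[i], counts[j]),
                          duration = duration, dt = model$dt)
      peaks[i, j] <- peak_depolarization(r)
    }
  }
  out <- new_two_input_map(counts, counts, peaks,
                           meta = list(loc_prox = loc_prox, loc_dist = loc_dist,
                                       protocol = protocol,
                                       branch_prox = branch_prox,
                                       branch_dist = branch_dist))
  if (cache) .map_cache[[key]] <- out
  out
}

#' Regionally distributed two-input map
#'
#' Same protocol as [map_two_input()], but each cluster's synapses are split
#' evenly across several sibling terminal branches at matched path distances
#' (remainders assigned round-robin), emulating input pathways that target a
#' dendritic subtree rather than a single branch.
#'
#' @param model a [basal_model()]
#' @param branches terminal branch ids to distribute over
#' @inheritParams map_two_input
#' @return a `two_input_map`
#' @export
regional_variant <- function(model, branches, loc_prox = 90, loc_dist = 150,
                             n_max = 40, step = 2,
                             protocol = c("double_pulse", "single_pulse"),
                             nmda_gmax = 3.56, duration = NULL, onset = 5) {
  protocol <- match.arg(protocol)
  if (length(branches) == 1) {
    return(map_two_input(model, loc_prox, loc_dist, n_max, step, protocol,
                         branch_prox = branches, branch_dist = branches,
                         nmda_gmax = nmda_gmax, duration = duration,
                         onset = onset))
  }
  if (is.null(duration)) {
    duration <- if (protocol == "double_pulse") 120 else 100
  }
  counts <- seq(0, n_max, by = step)
  split_sites <- function(loc, n) {
    per <- rep(n %/% length(branches), length(branches))
    extra <- n %% length(branches)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    do.call(rbind, lapply(seq_along(branches)[per > 0], function(k) {
      cluster_at_path(model, branches[k], loc, per[k])
    }))
  }
  mk <- function(sites) {
    if (protocol == "double_pulse") double_pulse_events(sites, t0 = onset)
    else synapse_events(sites, onset = onset, nmda_gmax = nmda_gmax)
  }
  peaks <- matrix(0, length(counts), length(counts))
  for (i in seq_along(counts)) {
    for (j in seq_along(counts)) {
      if (counts[i] == 0 && counts[j] == 0) next
      ev <- empty_events()
      if (counts[i] > 0) ev <- rbind(ev, mk(split_sites(loc_prox, counts[i])))
      if (counts[j] > 0) ev <- rbind(ev, mk(split_sites(loc_dist, counts[j])))
      r <- simulate_cable(model$morph, model$membrane, model$channels, ev,
                          duration = duration, dt = model$dt)
      peaks[i, j] <- peak_depolarization(r)
    }
  }
  new_two_input_map(counts, counts, peaks,
                    meta = list(loc_prox = loc_prox, loc_dist = loc_dist,
                                protocol = protocol, branches = branches,
                                regional = TRUE))
}

#' Slice a two-input map into a driver/modulator curve family
#'
#' One input-output curve per modulation level; the driver axis runs along
#' `driver` counts and each curve's y-intercept (driver count 0) is the
#' modulator-alone peak.
#'
#' @param m a `two_input_map`
#' @param driver `"dist"` (curves indexed by proximal modulation) or
#'   `"prox"` (curves indexed by distal modulation)
#' @return a `curve_family`: list with `driver`, `x` (driver counts),
#'   `modulation` (modulator counts), `curves` (matrix, one row per
#'   modulation level), `mod_alone` (modulator-alone peaks)
#' @export
slice_family <- function(m, driver = c("dist", "prox")) {
  driver <- match.arg(driver)
  if (driver == "dist") {
    x <- m$n_dist; modulation <- m$n_prox; curves <- m$peaks
  } else {
    x <- m$n_prox; modulation <- m$n_dist; curves <- t(m$peaks)
  }
  structure(list(driver = driver, x = x, modulation = modulation,
                 curves = curves, mod_alone = curves[, 1], meta = m$meta),
            class = "curve_family")
}

#' @export
print.curve_family <- function(x, ...) {
  cat(sprintf("<curve_family> driver=%s, %d curves x %d points\n",
              x$driver, nrow(x$curves), length(x$x)))
  invisible(x)
}

# rebuild the map from a family (inverse of slice_family)
unslice_family <- function(f) {
  if (f$driver == "dist") {
    new_two_input_map(f$modulation, f$x, f$curves, meta = f$meta)
  } else {
    new_two_input_map(f$x, f$modulation, t(f$curves), meta = f$meta)
  }
}

# io_curve for one modulation level of a family (drops unsampled grid points)
family_curve <- function(f, level_index, meta = list()) {
  y <- f$curves[level_index, ]
  keep <- !is.na(y)
  io_curve(f$x[keep], y[keep],
           meta = c(meta, list(modulation = f$modulation[level_index])))
}

#' Group a curve family by modulation strength and average
#'
#' Curves are binned into `n_bins` contiguous quantile categories of
#' modulator-alone peak; within each category the pointwise mean curve is
#' computed. Curves whose modulator-alone peak exceeds `exclude_above` are
#' dropped before binning (modulation levels past the modulator's own spike,
#' for which no matching experimental cases exist).
#'
#' @param f a `curve_family`
#' @param n_bins number of modulation categories
#' @param exclude_above ceiling on modulator-alone peak, mV (default `Inf`)
#' @return list with `bins` (assignment per retained curve), `mean_curves`
#'   (matrix, one row per bin), `x`, `levels` (retained modulation levels),
#'   `excluded` (dropped modulation levels)
#' @export
categorize_and_average <- function(f, n_bins = 4, exclude_above = Inf) {
  keep <- f$mod_alone <= exclude_above
  excluded <- f$modulation[!keep]
  curves <- f$curves[keep, , drop = FALSE]
  mod_alone <- f$mod_alone[keep]
  n_curves <- nrow(curves)
  if (n_curves < n_bins) {
    warning(sprintf("only %d curves for %d bins; using %d bins",
                    n_curves, n_bins, n_curves))
    n_bins <- n_curves
  }
  qs <- quantile(mod_alone, probs = seq(0, 1, length.out = n_bins + 1))
  if (length(unique(qs)) - 1 >= n_bins) {
    bins <- cut(mod_alone, breaks = unique(qs), include.lowest = TRUE,
                labels = FALSE)
  } else {
    # tied modulation strengths collapse the quantiles; split evenly by rank
    bins <- as.integer(cut(rank(mod_alone, ties.method = "first"),
                           breaks = n_bins, labels = FALSE))
  }
  mean_curves <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    colMeans(curves[bins == b, , drop = FALSE])
  }))
  list(bins = bins, mean_curves = mean_curves, x = f$x,
       levels = f$modulation[keep], excluded = excluded)
}

#' Additivity score of a two-input map
#'
#' Maximum absolute interaction deviation
#' \eqn{|peak(i,j) - peak(i,0) - peak(0,j) + peak(0,0)|}, normalized by the
#' map's dynamic range. With `subthreshold_only = TRUE` (default) the maximum
#' is taken over combinations where each site's count is below that site's
#' own single-site spike threshold: this window isolates genuine two-input
#' interaction (cooperative NMDA-spike ignition within a branch) from the
#' shared somatic driving-force saturation that makes any pair of large
#' inputs sum sublinearly, whichever branches they are on. Between-branch
#' maps score near zero here; within-branch maps score high (the
#' threshold-lowering ignition).
#'
#' @param m a `two_input_map`
#' @param subthreshold_only restrict to the deep-subthreshold window
#' @param margin grid steps to back off below each single-site threshold;
#'   the default of 1 excludes the knee points immediately below threshold,
#'   where even between-branch inputs cooperate through the shared somatic
#'   depolarization
#' @param criterion NRLE jump criterion used to find the single-site
#'   thresholds
#' @return dimensionless score >= 0
#' @export
map_additivity_score <- function(m, subthreshold_only = TRUE, margin = 1L,
                                 criterion = 1.3) {
  i_max <- length(m$n_prox)
  j_max <- length(m$n_dist)
  if (subthreshold_only) {
    th_p <- detect_threshold(io_curve(m$n_prox, m$peaks[, 1]), criterion)
    th_d <- detect_threshold(io_curve(m$n_dist, m$peaks[1, ]), criterion)
    if (!is.null(th_p)) i_max <- th_p$index_supra - 1L - margin
    if (!is.null(th_d)) j_max <- th_d$index_supra - 1L - margin
    if (i_max < 2 || j_max < 2) {
      stop("subthreshold window too small for the additivity score")
    }
  }
  rng <- diff(range(m$peaks))
  if (rng == 0) return(0)
  dev <- 0
  for (i in seq_len(i_max)) {
    for (j in seq_len(j_max)) {
      dev <- max(dev, abs(m$peaks[i, j] - m$peaks[i, 1] - m$peaks[1, j] +
                            m$peaks[1, 1]))
    }
  }
  dev / rng
}

#' Export a two-input map as CSV
#'
#' Matrix layout with the distal count axis as columns and proximal counts as
#' rows; metadata goes to a JSON side-car if `meta_path` is given.
#'
#' @param m a `two_input_map`
#' @param path CSV path
#' @param meta_path optional JSON metadata path
#' @return `path`, invisibly
#' @export
write_two_input_map <- function(m, path, meta_path = NULL) {
  tab <- as.data.frame(m$peaks)
  names(tab) <- paste0("n_dist_", m$n_dist)
  tab <- cbind(data.frame(n_prox = m$n_prox), tab)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(m$meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_two_input_map
#' @export
read_two_input_map <- function(path, meta_path = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  n_prox <- tab$n_prox
  peaks <- as.matrix(tab[, -1, drop = FALSE])
  n_dist <- as.numeric(sub("^n_dist_", "", colnames(peaks)))
  dimnames(peaks) <- NULL
  meta <- if (!is.null(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  new_two_input_map(n_prox, n_dist, peaks, meta = meta)
}
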