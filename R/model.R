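#' The reduced basal-dendrite model
#'
#' Bundles a discretized reduced morphology with membrane and channel
#' parameters into the model object the protocol functions consume. The
#' default geometry - eleven 275 um basal dendrites tapering linearly from
#' 1.08 um at the soma to 0.43 um at the tip, on a 15 um soma - is the
#' package's one-time calibration of the reduced morphology: branch diameter
#' profile, dendrite count (which stands in for the conductance load of the
#' full dendritic tree) and soma size were adjusted once so the reduced cell
#' reproduces the behaviours of the full reconstructed neuron it replaces:
#' local-spike NRLE values near 3 that are similar at proximal and distal
#' sites, proximal spike thresholds reachable within 40 synapses, and a
#' two-input (90/150 um) grid peak near 15 mV. See the methods vignette for
#' the calibration rationale.
#'
#' @param n_basal number of basal dendrites
#' @param dend_length dendrite length, um
#' @param dend_diam dendrite diameter, um
#' @param soma_diam soma diameter, um
#' @param stem_length if > 0, build branched basal subtrees
#'   ([build_basal_tree()]): each dendrite becomes a stem of this length that
#'   bifurcates into `n_daughters` terminal branches of diameter `dend_diam`
#' @param stem_diam stem diameter for the branched topology, um
#' @param n_daughters terminal branches per stem
#' @param dend_taper optional `c(stem_diam, tip_diam)` um: linear diameter
#'   taper along each basal dendrite (overrides `dend_diam`); thick stems
#'   couple the branch strongly to the soma while thin distal segments keep
#'   local NMDA-spike thresholds reachable, as in reconstructed basal trees
#' @param apical_diam,apical_length optional apical-trunk load cylinder, um
#'   (`apical_diam = 0` omits it); emulates the conductance load of the apical
#'   tree on the soma, which the bare ball-and-stick lacks
#' @param axon include an axonal spike-initiation zone (hillock with dense
#'   sodium conductance, then alternating myelinated internodes and nodes of
#'   Ranvier); required for the firing-rate protocols, and electrically
#'   nearly invisible to the subthreshold summation experiments
#' @param membrane [membrane_params()]
#' @param channels [channel_params()]
#' @param dt default integration step, ms
#' @return a `basal_model` list: `morph` (discretized), `membrane`,
#'   `channels`, `dt`
#' @export
basal_model <- function(n_basal = 11, dend_length = 275, dend_diam = 0.755,
                        soma_diam = 15, stem_length = 0, stem_diam = 1.4,
                        n_daughters = 2, dend_taper = c(1.08, 0.43),
                        apical_diam = 0, apical_length = 600, axon = TRUE,
                        membrane = membrane_params(),
                        channels = channel_params(), dt = 0.1) {
  morph <- if (stem_length > 0) {
    build_basal_tree(n_basal, dend_length, stem_length, stem_diam,
                     dend_diam, n_daughters, soma_diam)
  } else {
    build_ball_and_stick(n_basal, dend_length, dend_diam, soma_diam)
  }
  if (!is.null(dend_taper)) {
    s <- morph$sections
    s$diam_prox <- ifelse(s$kind == "basal", dend_taper[1], NA_real_)
    s$diam_tip <- ifelse(s$kind == "basal", dend_taper[2], NA_real_)
    s$diameter <- ifelse(s$kind == "basal", mean(dend_taper), s$diameter)
    morph <- new_morphology(s)
  }
  if (apical_diam > 0) {
    s <- morph$sections
    ap <- data.frame(id = max(s$id) + 1L, parent_id = s$id[is.na(s$parent_id)],
                     kind = "apical", length = apical_length,
                     diameter = apical_diam, spine_corrected = TRUE,
                     stringsAsFactors = FALSE)
    for (extra in setdiff(names(s), names(ap))) ap[[extra]] <- NA_real_
    morph <- new_morphology(rbind(s, ap[names(s)]))
  }
  if (axon) {
    s <- morph$sections
    soma_id <- s$id[is.na(s$parent_id)]
    ax <- data.frame(
      id = max(s$id) + 1:5,
      parent_id = c(soma_id, max(s$id) + 1:4),
      kind = c("axon_hillock", "axon_myelin", "axon_node", "axon_myelin",
               "axon_node"),
      length = c(10, 100, 1, 100, 1),
      diameter = c(1.5, 1, 1, 1, 1),
      spine_corrected = FALSE, stringsAsFactors = FALSE)
    for (extra in setdiff(names(s), names(ax))) ax[[extra]] <- NA_real_
    morph <- new_morphology(rbind(s, ax[names(s)]))
  }
  morph <- discretize(morph, membrane)
  structure(list(morph = morph, membrane = membrane, channels = channels,
                 dt = dt),
            class = "basal_model")
}

#' @export
print.basal_model <- function(x, ...) {
  cat("<basal_model>\n")
  print(x$morph)
  invisible(x)
}

#' Passive variant of a model
#'
#' Zeroes all active conductance densities (for cable-theory checks and
#' passive EPSP work). Optional `rm_cm_factor` scales R_m and C_m jointly, as
#' used by the EPSP time-course analysis.
#'
#' @param model a `basal_model`
#' @param rm_cm_factor multiply R_m and C_m by this factor
#' @return modified model
#' @export
passive_model <- function(model, rm_cm_factor = 1) {
  ch <- model$channels
  ch$gbar_na[] <- 0
  ch$gbar_k[] <- 0
  model$channels <- ch
  if (rm_cm_factor != 1) {
    mb <- model$membrane
    mb$r_m <- mb$r_m * rm_cm_factor
    mb$c_m <- mb$c_m * rm_cm_factor
    model$membrane <- mb
    model$morph <- discretize(model$morph, mb)
  }
  model
}

# first terminal basal branch id of a model (a daughter in branched trees)
first_basal <- function(model) {
  s <- model$morph$sections
  term <- s$kind == "basal" & !(s$id %in% s$parent_id)
  s$id[term][1]
}

# nth terminal basal branch (for between-branch / sibling protocols)
nth_basal <- function(model, n) {
  s <- model$morph$sections
  term <- s$kind == "basal" & !(s$id %in% s$parent_id)
  s$id[term][n]
}

#' Place a synapse cluster at a path distance from the soma
#'
#' Resolves `center_path_um` on the path from the soma to terminal section
#' `branch` (crossing branch points if necessary) and places an `n`-synapse
#' cluster there.
#'
#' @param model a `basal_model`
#' @param branch terminal section id defining the path
#' @param center_path_um cluster centre, um path distance from the soma
#' @param n synapse count
#' @param spacing inter-synapse spacing, um
#' @return data.frame of sites (`section`, `pos_um`)
#' @export
cluster_at_path <- function(model, branch, center_path_um, n, spacing = 0.5) {
  site <- site_at_path(model$morph, branch, center_path_um)
  place_cluster(model$morph, site$section, site$pos_um, n, spacing = spacing)
}

#' Single-site input-output ramp
#'
#' Simulates a ramp of synapse counts at one dendritic site (a
#' glutamate-uncaging-like single-pulse protocol: each synapse contributes one
#' AMPA and one NMDA conductance activated simultaneously) and returns the
#' peak somatic depolarization per count as an [io_curve()].
#'
#' @param model a `basal_model`
#' @param distance_um site path distance from the soma, um
#' @param n_syn integer vector of synapse counts (strictly increasing)
#' @param nmda_gmax,ampa_gmax per-synapse peak conductances, nS (set
#'   `nmda_gmax = 0` for simulated NMDA-receptor block)
#' @param branch section id (default: first basal dendrite)
#' @param protocol `"single_pulse"` (one activation) or `"double_pulse"`
#'   (50 Hz pair with the facilitated NMDA schedule; `nmda_gmax` is then the
#'   first-pulse conductance and the second pulse doubles it)
#' @param onset stimulus onset, ms
#' @param duration simulated time, ms
#' @param dt integration step, ms (default: model's)
#' @return an `io_curve` (x = synapse count, y = peak somatic depolarization)
#' @export
uncaging_ramp <- function(model, distance_um, n_syn = seq(0, 40, by = 2),
                          nmda_gmax = 3.56, ampa_gmax = 1.5, branch = NULL,
                          protocol = c("single_pulse", "double_pulse"),
                          onset = 5, duration = 100, dt = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(branch)) branch <- first_basal(model)
  if (is.null(dt)) dt <- model$dt
  if (protocol == "double_pulse") duration <- max(duration, 120)
  peaks <- vapply(n_syn, function(n) {
    if (n == 0) return(0)
    sites <- cluster_at_path(model, branch, distance_um, n)
    ev <- if (protocol == "single_pulse") {
      synapse_events(sites, onset = onset, nmda_gmax = nmda_gmax,
                     ampa_gmax = ampa_gmax)
    } else {
      double_pulse_events(sites, t0 = onset,
                          nmda_g1 = if (nmda_gmax > 0) 2.23 else 0,
                          ampa_gmax = ampa_gmax)
    }
    r <- simulate_cable(model$morph, model$membrane, model$channels, ev,
                        duration = duration, dt = dt)
    peak_depolarization(r)
  }, 0)
  keep <- n_syn > 0
  io_curve(n_syn[keep], peaks[keep],
           meta = list(site_um = distance_um, protocol = protocol,
                       nmda_gmax = nmda_gmax, ampa_gmax = ampa_gmax))
}
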