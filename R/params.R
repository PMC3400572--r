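#' Passive membrane parameters
#'
#' Region-resolved passive properties of the model cell. Defaults follow the
#' layer-5 pyramidal parameter set used throughout the package: specific
#' membrane resistance R_m of 10 kOhm cm^2 in dendrites, 0.05 kOhm cm^2 at
#' axon nodes and 20 kOhm cm^2 elsewhere; capacitance C_m of 2 uF/cm^2 in
#' dendrites, 0.05 uF/cm^2 in myelinated axon and 1 uF/cm^2 elsewhere; axial
#' resistivity 100 Ohm cm; leak reversal -70 mV. Spine-corrected sections get
#' their C_m and leak conductance doubled at simulation time.
#'
#' @param r_m named numeric, kOhm cm^2, regions `dend`, `axon_node`, `other`
#' @param c_m named numeric, uF/cm^2, regions `dend`, `myelin`, `other`
#' @param r_a axial resistivity, Ohm cm
#' @param e_leak leak reversal potential, mV
#' @return a `membrane_params` list
#' @export
membrane_params <- function(r_m = c(dend = 10, axon_node = 0.05, other = 20),
                            c_m = c(dend = 2, myelin = 0.05, other = 1),
                            r_a = 100, e_leak = -70) {
  stopifnot(all(r_m > 0), all(c_m > 0), r_a > 0)
  structure(list(r_m = r_m, c_m = c_m, r_a = r_a, e_leak = e_leak),
            class = "membrane_params")
}

#' Active (Hodgkin-Huxley) channel parameters
#'
#' Conductance densities per region and reversal potentials for the sodium
#' and potassium currents. Dendritic sodium density decreases linearly with
#' path distance, reaching zero at `na_taper_end` (default 200 um).
#'
#' @param gbar_na named numeric, S/cm^2: `dend`, `axon_nonmyel`, `axon_myel`, `soma`
#' @param gbar_k named numeric, S/cm^2: `dend`, `axon_nonmyel`, `soma`
#' @param e_na,e_k reversal potentials, mV
#' @param na_taper_end path distance at which dendritic Na density reaches 0, um
#' @param k_exponent potassium activation exponent (4 = classical n^4; 1 also
#'   supported)
#' @param q10_rate multiplicative temperature factor applied to all gating
#'   rates (default corresponds to Q10 = 2.3 from 6.3 to 35 degrees C)
#' @param na_shift depolarizing shift of the Na activation curve, mV. Part
#'   of the one-time spike-mechanism calibration: it places the
#'   action-potential threshold above the subthreshold synaptic summation
#'   range (as in the recordings, where somatic spiking was
#'   pharmacologically prevented when needed) while leaving the cell able to
#'   fire under strong drive plus noisy bias in the firing-rate protocols.
#' @param na_inact_shift additional depolarizing shift of the Na
#'   inactivation curve relative to activation, mV; cortical Na channels
#'   inactivate at more depolarized potentials than the classical squid
#'   constants, and without this offset the cell accommodates (inactivates
#'   without firing) under sustained depolarizing bias.
#' @return a `channel_params` list
#' @export
channel_params <- function(gbar_na = c(dend = 0.006, axon_nonmyel = 5,
                                       axon_myel = 0.006, soma = 0.25),
                           gbar_k = c(dend = 0.0003, axon_nonmyel = 0.05,
                                      soma = 0.03),
                           e_na = 60, e_k = -90, na_taper_end = 200,
                           k_exponent = 4, q10_rate = 2.3^((35 - 6.3) / 10),
                           na_shift = 12, na_inact_shift = 5) {
  stopifnot(all(gbar_na >= 0), all(gbar_k >= 0), na_taper_end > 0,
            k_exponent %in% c(1, 4))
  structure(list(gbar_na = gbar_na, gbar_k = gbar_k, e_na = e_na, e_k = e_k,
                 na_taper_end = na_taper_end, k_exponent = as.integer(k_exponent),
                 q10_rate = q10_rate, na_shift = na_shift,
                 na_inact_shift = na_inact_shift),
            class = "channel_params")
}

# map a section kind to the region key of a parameter vector
region_value <- function(v, kind) {
  key <- switch(kind,
    soma = if ("soma" %in% names(v)) "soma" else "other",
    basal = , apical = "dend",
    axon_hillock = if ("axon_nonmyel" %in% names(v)) "axon_nonmyel" else "other",
    axon_node = if ("axon_node" %in% names(v)) "axon_node"
                else if ("axon_nonmyel" %in% names(v)) "axon_nonmyel" else "other",
    axon_myelin = if ("myelin" %in% names(v)) "myelin"
                  else if ("axon_myel" %in% names(v)) "axon_myel" else "other",
    "other")
  if (!key %in% names(v)) key <- "other"
  if (!key %in% names(v)) return(0)
  unname(v[[key]])
}

#' Synapse specification
#'
#' Difference-of-exponentials conductance waveform, peak-normalized so its
#' maximum equals `g_max`. NMDA synapses additionally carry the
#' voltage-dependent magnesium block parameters of [mg_block()].
#'
#' @param kind `"AMPA"` or `"NMDA"`
#' @param g_max peak conductance, nS
#' @param tau_rise,tau_fall kinetics, ms (fall > rise > 0)
#' @param e_rev reversal potential, mV
#' @param mg_half,mg_slope magnesium-block sigmoid midpoint/slope, mV
#'   (NMDA only)
#' @return a `synapse_spec` list
#' @export
synapse_spec <- function(kind, g_max, tau_rise, tau_fall, e_rev = 0,
                         mg_half = 12, mg_slope = 10) {
  kind <- match.arg(kind, c("AMPA", "NMDA"))
  if (tau_fall <= tau_rise || tau_rise <= 0) {
    stop("require tau_fall > tau_rise > 0")
  }
  if (g_max < 0) stop("g_max must be >= 0")
  structure(list(kind = kind, g_max = g_max, tau_rise = tau_rise,
                 tau_fall = tau_fall, e_rev = e_rev,
                 mg_half = mg_half, mg_slope = mg_slope),
            class = "synapse_spec")
}

#' @rdname synapse_spec
#' @export
ampa_spec <- function(g_max = 1.5) synapse_spec("AMPA", g_max, 0.05, 0.5)

#' @rdname synapse_spec
#' @export
nmda_spec <- function(g_max = 3.56) synapse_spec("NMDA", g_max, 2.1, 18.8)
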