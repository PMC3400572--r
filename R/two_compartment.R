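#' Time-invariant two-compartment NMDA circuit parameters
#'
#' The minimal circuit reproducing proximal-distal summation asymmetry with
#' no temporal dynamics at all: two nodes (proximal, standing in for the
#' soma readout, and distal) joined by an axial conductance, each with its
#' own leak to the resting potential and a steady NMDA conductance source
#' scaled by the local magnesium block. Default conductances (arbitrary
#' units): axial 2.5, proximal leak 4, distal leak 0.25, NMDA 0.5 per
#' synapse; voltages are in absolute mV (rest -70, synaptic reversal 0) so
#' the block midpoint (-22 mV, slope 12 mV - the "softer" variant absorbing
#' unmodeled AMPA dilution) is meaningful. The final `output_scale` absorbs
#' the conductance units into a mV somatic readout.
#'
#' @param g_axial axial conductance, A.U.
#' @param g_leak_prox,g_leak_dist per-node leak conductances, A.U.
#' @param g_nmda_unit NMDA conductance per synapse, A.U.
#' @param mg_half,mg_slope magnesium-block sigmoid, mV
#' @param e_rest,e_syn resting / synaptic reversal potentials, mV
#' @param output_scale linear scale applied to (V_prox - E_rest) in
#'   [response_surface()]
#' @return a `two_comp_params` list
#' @export
two_comp_params <- function(g_axial = 2.5, g_leak_prox = 4, g_leak_dist = 0.25,
                            g_nmda_unit = 0.5, mg_half = 22, mg_slope = 12,
                            e_rest = -70, e_syn = 0, output_scale = 1) {
  stopifnot(g_axial > 0, g_leak_prox >= 0, g_leak_dist >= 0, g_nmda_unit >= 0,
            mg_slope > 0)
  structure(list(g_axial = g_axial, g_leak_prox = g_leak_prox,
                 g_leak_dist = g_leak_dist, g_nmda_unit = g_nmda_unit,
                 mg_half = mg_half, mg_slope = mg_slope,
                 e_rest = e_rest, e_syn = e_syn, output_scale = output_scale),
            class = "two_comp_params")
}

# raw Kirchhoff residuals of the 2-node system at (v_prox, v_dist), A.U.
# distal:  g_ld (Vd - E) + g_ax (Vd - Vp) - Nd g B(Vd) (Es - Vd) = 0
# proximal: g_lp (Vp - E) + g_ax (Vp - Vd) - Np g B(Vp) (Es - Vp) = 0
two_comp_residuals <- function(p, v_prox, v_dist, n_prox, n_dist) {
  B <- function(v) mg_block(v, p$mg_half, p$mg_slope)
  c(dist = p$g_leak_dist * (v_dist - p$e_rest) + p$g_axial * (v_dist - v_prox) -
      n_dist * p$g_nmda_unit * B(v_dist) * (p$e_syn - v_dist),
    prox = p$g_leak_prox * (v_prox - p$e_rest) + p$g_axial * (v_prox - v_dist) -
      n_prox * p$g_nmda_unit * B(v_prox) * (p$e_syn - v_prox))
}

# V_prox as an explicit function of V_dist from the distal node's equation
vprox_of_vdist <- function(p, v_dist, n_dist) {
  B <- mg_block(v_dist, p$mg_half, p$mg_slope)
  v_dist + (p$g_leak_dist * (v_dist - p$e_rest) -
              n_dist * p$g_nmda_unit * B * (p$e_syn - v_dist)) / p$g_axial
}

#' Solve the two-compartment circuit at steady state
#'
#' Eliminates V_prox through the distal node's Kirchhoff equation (which is
#' explicit in V_prox), scans V_dist over `[e_rest, e_syn]` for sign changes
#' of the remaining proximal-node residual, and refines each bracketed root.
#' With strong NMDA drive the system can be bistable; all roots are returned,
#' and the branch continuously connected to rest (the lowest V_dist root) is
#' the reported solution.
#'
#' @param p a [two_comp_params()]
#' @param n_prox,n_dist synapse counts at the two nodes (>= 0)
#' @param n_scan resolution of the V_dist bracketing scan
#' @return a `two_comp_state`: list with `v_prox`, `v_dist` (mV, the
#'   rest-connected root), `branch` (`"rest-connected"`, `"upper"` or
#'   `"other"`), `roots` (data.frame of all solutions), `residuals`
#' @export
solve_steady_state <- function(p, n_prox, n_dist, n_scan = 2000) {
  stopifnot(n_prox >= 0, n_dist >= 0)
  if (n_prox == 0 && n_dist == 0) {
    return(structure(list(v_prox = p$e_rest, v_dist = p$e_rest,
                          branch = "rest-connected",
                          roots = data.frame(v_prox = p$e_rest,
                                             v_dist = p$e_rest),
                          residuals = c(dist = 0, prox = 0)),
                     class = "two_comp_state"))
  }
  f <- function(vd) {
    # proximal-node residual after eliminating V_prox; fully vectorized in vd
    vp <- vprox_of_vdist(p, vd, n_dist)
    p$g_leak_prox * (vp - p$e_rest) + p$g_axial * (vp - vd) -
      n_prox * p$g_nmda_unit * mg_block(vp, p$mg_half, p$mg_slope) *
        (p$e_syn - vp)
  }
  lo <- p$e_rest - 1e-9
  hi <- p$e_syn
  grid <- seq(lo, hi, length.out = n_scan + 1)
  fg <- f(grid)
  roots <- numeric(0)
  for (i in seq_len(n_scan)) {
    if (fg[i] == 0) { roots <- c(roots, grid[i]); next }
    if (fg[i] * fg[i + 1] < 0) {
      r <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)
      roots <- c(roots, r$root)
    }
  }
  if (abs(fg[n_scan + 1]) < 1e-12) roots <- c(roots, grid[n_scan + 1])
  if (!length(roots)) {
    stop("no steady-state root found in [e_rest, e_syn]; check parameters")
  }
  roots <- sort(unique(roots))
  vp <- vapply(roots, function(vd) vprox_of_vdist(p, vd, n_dist), 0)
  tab <- data.frame(v_prox = vp, v_dist = roots)
  res <- two_comp_residuals(p, vp[1], roots[1], n_prox, n_dist)
  structure(list(v_prox = vp[1], v_dist = roots[1],
                 branch = "rest-connected", roots = tab, residuals = res),
            class = "two_comp_state")
}

#' @export
print.two_comp_state <- function(x, ...) {
  cat(sprintf("<two_comp_state> V_prox=%.3f mV V_dist=%.3f mV (%s, %d root%s)\n",
              x$v_prox, x$v_dist, x$branch, nrow(x$roots),
              if (nrow(x$roots) > 1) "s" else ""))
  invisible(x)
}

#' Steady-state response surface over a synapse-count grid
#'
#' Entry (i, j) is `output_scale * (V_prox - E_rest)` at `n_prox[i]`,
#' `n_dist[j]` activated synapses: the circuit's somatic readout. Rows and
#' columns are monotone non-decreasing in their own count.
#'
#' @param p a [two_comp_params()]
#' @param n_prox,n_dist count axes (default 0..40)
#' @return a `two_input_map` (see [map_two_input()]) with `peaks` in scaled mV
#' @export
response_surface <- function(p, n_prox = 0:40, n_dist = 0:40) {
  peaks <- matrix(NA_real_, length(n_prox), length(n_dist))
  for (i in seq_along(n_prox)) {
    for (j in seq_along(n_dist)) {
      st <- solve_steady_state(p, n_prox[i], n_dist[j])
      peaks[i, j] <- p$output_scale * (st$v_prox - p$e_rest)
    }
  }
  new_two_input_map(n_prox, n_dist, peaks,
                    meta = list(kind = "two_compartment",
                                output_scale = p$output_scale))
}

#' Fit the output scale of the two-compartment surface
#'
#' Returns the factor that makes the surface's overall peak equal
#' `target_peak` (the compartmental-model grid peak it is matched to).
#'
#' @param surface a `two_input_map` from [response_surface()]
#' @param target_peak desired overall peak, mV
#' @return scale factor (dimensionless)
#' @export
fit_output_scale <- function(surface, target_peak) {
  mx <- max(surface$peaks)
  if (mx <= 0) stop("surface is all zero; cannot scale")
  target_peak / mx
}

#' Current-to-overcome (CTO) at a node of the two-compartment circuit
#'
#' The NMDA drive minus the net passive (leak + axial) restoring current at
#' the stated node, with the opposite node relaxed to its own steady state
#' given the clamped voltage: \eqn{CTO = -(I_{passive} - I_{NMDA,drive})}.
#' Positive CTO means the drive exceeds the restoring current (the node would
#' depolarize further); CTO is zero at a steady state of the full circuit.
#'
#' @param p a [two_comp_params()]
#' @param v clamped voltage at the node of interest, mV
#' @param n_drive synapse count at that node
#' @param node `"dist"` or `"prox"`
#' @param n_other synapse count at the opposite node
#' @return CTO in A.U. current
#' @export
compute_cto <- function(p, v, n_drive, node = c("dist", "prox"), n_other = 0) {
  node <- match.arg(node)
  g_self <- if (node == "dist") p$g_leak_dist else p$g_leak_prox
  g_opp <- if (node == "dist") p$g_leak_prox else p$g_leak_dist
  # opposite node's own KCL given the clamped v (rest-connected root)
  g_kcl <- function(vo) {
    g_opp * (vo - p$e_rest) + p$g_axial * (vo - v) -
      n_other * p$g_nmda_unit * mg_block(vo, p$mg_half, p$mg_slope) *
        (p$e_syn - vo)
  }
  lo <- min(p$e_rest, v) - 1e-9
  grid <- seq(lo, p$e_syn, length.out = 1001)
  fg <- vapply(grid, g_kcl, 0)
  v_other <- NA_real_
  for (i in seq_len(1000)) {
    if (fg[i] * fg[i + 1] <= 0) {
      v_other <- uniroot(g_kcl, c(grid[i], grid[i + 1]), tol = 1e-13)$root
      break
    }
  }
  if (is.na(v_other)) stop("could not solve the opposite node's equation")
  i_passive <- g_self * (v - p$e_rest) + p$g_axial * (v - v_other)
  i_drive <- n_drive * p$g_nmda_unit * mg_block(v, p$mg_half, p$mg_slope) *
    (p$e_syn - v)
  i_drive - i_passive
}
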