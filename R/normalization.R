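#' The fiducial-point template
#'
#' Four landmark coordinates on a cell's two-input curve family, in
#' template units: the triangle (just-suprathreshold distal-alone spike,
#' defining the unit point (1, 1)), the square (just-subthreshold
#' proximal-alone peak, (0, 0.6)), the pentagon (just-suprathreshold
#' proximal-alone peak, (0, 2.4)), and the circle (just-suprathreshold distal
#' response under a just-subthreshold proximal bias, (0.6, 2.2)). The
#' template encodes the average ratios observed across cells: the proximal
#' spike is more than twice the distal spike's height, the proximal
#' just-subthreshold response is about 2/3 of the distal spike, and a
#' just-subthreshold proximal bias roughly halves the distal spike threshold.
#'
#' @return data.frame with columns `point`, `x`, `y`
#' @export
fiducial_template <- function() {
  data.frame(point = c("triangle", "square", "pentagon", "circle"),
             x = c(1, 0, 0, 0.6),
             y = c(1, 0.6, 2.4, 2.2),
             stringsAsFactors = FALSE)
}

new_fiducial_set <- function(triangle, square, pentagon, circle) {
  f <- data.frame(point = c("triangle", "square", "pentagon", "circle"),
                  x = c(triangle[1], square[1], pentagon[1], circle[1]),
                  y = c(triangle[2], square[2], pentagon[2], circle[2]),
                  stringsAsFactors = FALSE)
  if (f$y[f$point == "pentagon"] <= f$y[f$point == "square"]) {
    stop("pentagon (just-suprathreshold) must exceed square (just-subthreshold)")
  }
  structure(f, class = c("fiducial_set", "data.frame"))
}

#' Extract fiducial points from a two-input curve family pair
#'
#' Reads the four landmarks off a cell's data: the distal-alone and
#' proximal-alone input-output curves give the triangle and the
#' square/pentagon pair via local-spike threshold detection
#' ([detect_threshold()]); the circle is the just-suprathreshold point of the
#' distal-driver curve whose proximal bias is the largest level still below
#' the proximal spike threshold.
#'
#' @param fam_dist `curve_family` with distal driver (proximal modulation)
#' @param fam_prox `curve_family` with proximal driver (distal modulation);
#'   defaults to the transpose of `fam_dist`
#' @param criterion NRLE jump criterion for threshold detection
#' @return a `fiducial_set` (data.frame: point, x, y); x in driver-intensity
#'   units, y in mV
#' @export
extract_fiducials <- function(fam_dist, fam_prox = NULL, criterion = 1.3) {
  if (is.null(fam_prox)) fam_prox <- slice_family(unslice_family(fam_dist), "prox")
  need <- function(th, what) {
    if (is.null(th)) {
      stop("cannot extract fiducials: no detectable threshold for ", what)
    }
    th
  }
  # distal-alone curve: zero proximal modulation
  dist_alone <- family_curve(fam_dist, 1L)
  th_d <- need(detect_threshold(dist_alone, criterion), "distal-alone spike (triangle)")
  triangle <- c(dist_alone$x[th_d$index_supra], dist_alone$y[th_d$index_supra])

  # proximal-alone curve: zero distal modulation
  prox_alone <- family_curve(fam_prox, 1L)
  th_p <- need(detect_threshold(prox_alone, criterion),
               "proximal-alone spike (square/pentagon)")
  square <- c(0, prox_alone$y[th_p$index_sub])
  pentagon <- c(0, prox_alone$y[th_p$index_supra])

  # just-subthreshold proximal bias: the largest modulation level below the
  # proximal spike threshold at which the biased distal curve still shows a
  # detectable local-spike jump (at very strong bias the distal curve loses
  # its discontinuity on a finite stimulus grid)
  thr_count <- prox_alone$x[th_p$index_supra]
  bias <- pick_bias_level(fam_dist, thr_count, criterion)
  if (is.null(bias)) {
    stop("cannot extract fiducials: no just-subthreshold proximal bias level with a detectable distal spike (circle)")
  }
  biased <- family_curve(fam_dist, bias$index)
  circle <- c(biased$x[bias$th$index_supra], biased$y[bias$th$index_supra])

  new_fiducial_set(triangle, square, pentagon, circle)
}

#' Fit horizontal/vertical scale factors to the fiducial template
#'
#' Finds the two factors (a_x, a_y) minimizing the mean squared error between
#' the cell's scaled fiducial points and the template. The problem separates:
#' a_x is the least-squares slope over the points with nonzero x (triangle
#' and circle), a_y over all four y values. Only these two numbers are then
#' used to scale a cell's full data set, so overfitting is impossible.
#'
#' @param f a `fiducial_set`
#' @param template template points (default [fiducial_template()])
#' @return named numeric `c(a_x, a_y)`
#' @export
fit_scale_factors <- function(f, template = fiducial_template()) {
  stopifnot(all(f$point == template$point))
  nz <- f$x != 0
  if (!any(nz)) stop("all fiducial x coordinates are zero; a_x is undefined")
  a_x <- sum(f$x[nz] * template$x[nz]) / sum(f$x[nz]^2)
  a_y <- sum(f$y * template$y) / sum(f$y^2)
  c(a_x = a_x, a_y = a_y)
}

#' Apply scale factors to a cell's two-input table
#'
#' Multiplies driver intensities by `a_x` and responses by `a_y` (modulation
#' intensities share the driver's stimulus units and are scaled by `a_x`).
#'
#' @param data data.frame with columns `driver`, `modulation`, `peak`
#' @param factors `c(a_x, a_y)` from [fit_scale_factors()]
#' @return the scaled data.frame
#' @export
apply_scale_factors <- function(data, factors) {
  data$driver <- data$driver * factors[["a_x"]]
  if ("modulation" %in% names(data)) {
    data$modulation <- data$modulation * factors[["a_x"]]
  }
  data$peak <- data$peak * factors[["a_y"]]
  data
}

#' Rigid single-fiducial scaling for the orthogonal (proximal-driver) view
#'
#' The proximal-driver data is more uniform across cells, so a single
#' landmark suffices: the pentagon (the just-suprathreshold proximal-alone
#' point, here carrying its driver-intensity x coordinate) is mapped exactly
#' onto `target` (default (1, 2.4)) and the same two factors are applied to
#' all points.
#'
#' @param data data.frame with columns `driver`, `modulation`, `peak`
#' @param pentagon `c(x, y)`: the cell's proximal just-suprathreshold point
#'   in driver units / mV
#' @param target template location for the pentagon
#' @return list with `data` (scaled) and `factors` `c(a_x, a_y)`
#' @export
rigid_scale_orthogonal <- function(data, pentagon, target = c(1, 2.4)) {
  if (length(pentagon) != 2 || any(!is.finite(pentagon)) || any(pentagon == 0)) {
    stop("pentagon must be a finite (x, y) pair with nonzero coordinates")
  }
  factors <- c(a_x = target[1] / pentagon[1], a_y = target[2] / pentagon[2])
  list(data = apply_scale_factors(data, factors), factors = factors)
}

#' Normalize a cohort of two-input data sets
#'
#' Runs fiducial extraction and template scaling for each cell of a cohort
#' (e.g. from [generate_cohort()]): per cell, the two-input table is
#' reassembled into curve families, the four fiducials are located, the two
#' scale factors are fit, and the full data set is scaled.
#'
#' @param cohort a `synthetic_cohort` or a list of per-cell data.frames with
#'   columns `driver`, `modulation`, `peak`
#' @param criterion NRLE jump criterion for threshold detection
#' @return list with `factors` (data.frame: cell, a_x, a_y), `data` (list of
#'   scaled per-cell tables), `fiducials` (list of fiducial sets)
#' @export
normalize_cohort <- function(cohort, criterion = 1.3) {
  cells <- if (inherits(cohort, "synthetic_cohort")) cohort$cells else cohort
  fiducials <- list()
  scaled <- list()
  factors <- data.frame(cell = integer(0), a_x = numeric(0), a_y = numeric(0))
  for (ci in seq_along(cells)) {
    fam <- cell_table_to_family(cells[[ci]])
    fid <- extract_fiducials(fam$dist, fam$prox, criterion = criterion)
    fac <- fit_scale_factors(fid)
    fiducials[[ci]] <- fid
    scaled[[ci]] <- apply_scale_factors(cells[[ci]], fac)
    factors <- rbind(factors,
                     data.frame(cell = ci, a_x = fac[["a_x"]],
                                a_y = fac[["a_y"]]))
  }
  list(factors = factors, data = scaled, fiducials = fiducials)
}

# Largest proximal-bias modulation level of a distal-driver family that is
# below thr_count and still yields a detectable threshold on the biased
# distal curve. Levels sampled at fewer than `min_points` driver intensities
# are not usable as curves (guards against sparse filler samples in
# subsampled cell data). Returns list(index, level, th) or NULL.
pick_bias_level <- function(fam_dist, thr_count, criterion = 1.3,
                            min_points = 5L) {
  sub_levels <- which(fam_dist$modulation > 0 & fam_dist$modulation < thr_count)
  for (k in rev(sub_levels[order(fam_dist$modulation[sub_levels])])) {
    if (sum(!is.na(fam_dist$curves[k, ])) < min_points) next
    cur <- tryCatch(family_curve(fam_dist, k), error = function(e) NULL)
    if (is.null(cur)) next
    th <- detect_threshold(cur, criterion)
    if (!is.null(th) && th$index_sub >= 1) {
      return(list(index = k, level = fam_dist$modulation[k], th = th))
    }
  }
  NULL
}

# Reassemble a per-cell (driver, modulation, peak) table into the
# distal-driver and proximal-driver curve families it was sampled from.
# Rows tagged view == "prox" belong to the proximal-driver family.
cell_table_to_family <- function(tab) {
  stopifnot(all(c("driver", "modulation", "peak") %in% names(tab)))
  if (!"view" %in% names(tab)) tab$view <- "dist"
  mk <- function(sub, driver_label) {
    mods <- sort(unique(sub$modulation))
    xs <- sort(unique(sub$driver))
    curves <- matrix(NA_real_, length(mods), length(xs))
    for (k in seq_along(mods)) {
      rows <- sub[sub$modulation == mods[k], ]
      curves[k, match(rows$driver, xs)] <- rows$peak
    }
    structure(list(driver = driver_label, x = xs, modulation = mods,
                   curves = curves, mod_alone = curves[, 1], meta = list()),
              class = "curve_family")
  }
  list(dist = mk(tab[tab$view == "dist", ], "dist"),
       prox = mk(tab[tab$view == "prox", ], "prox"))
}
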