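#' Build a ball-and-stick morphology
#'
#' Constructs the reduced morphology used throughout the package: an
#' isopotential soma (sphere-equivalent cylinder, length = diameter) with
#' `n_basal` identical terminal basal dendrites attached. Terminal dendrites
#' are flagged `spine_corrected`, i.e. their membrane capacitance and leak
#' conductance are doubled during simulation to account for the membrane area
#' of unmodeled dendritic spines.
#'
#' Path distances of stimulus/recording sites are measured along the dendrite
#' from its origin at the soma, in micrometres, so a site "at 70 um" sits
#' 70 um along a branch.
#'
#' @param n_basal number of basal dendrites (>= 1)
#' @param dend_length dendrite length, um
#' @param dend_diam dendrite diameter, um
#' @param soma_diam soma diameter, um
#' @return an object of class `morphology`: a list with a `sections`
#'   data.frame (id, parent_id, kind, length, diameter, spine_corrected) and a
#'   `nseg` integer vector (one compartment per section until [discretize()]
#'   is applied).
#' @examples
#' m <- build_ball_and_stick(4, 275, 1.0, 20)
#' nrow(m$sections)
#' @export
build_ball_and_stick <- function(n_basal = 4, dend_length = 275,
                                 dend_diam = 1.0, soma_diam = 20) {
  if (n_basal < 1) stop("n_basal must be >= 1")
  if (any(c(dend_length, dend_diam, soma_diam) <= 0)) {
    stop("all dimensions must be positive")
  }
  sections <- data.frame(
    id = seq_len(n_basal + 1L),
    parent_id = c(NA_integer_, rep(1L, n_basal)),
    kind = c("soma", rep("basal", n_basal)),
    length = c(soma_diam, rep(dend_length, n_basal)),
    diameter = c(soma_diam, rep(dend_diam, n_basal)),
    spine_corrected = c(FALSE, rep(TRUE, n_basal)),
    stringsAsFactors = FALSE
  )
  new_morphology(sections)
}

new_morphology <- function(sections, nseg = NULL) {
  stopifnot(is.data.frame(sections))
  if (sum(is.na(sections$parent_id)) != 1L) {
    stop("exactly one root section (parent_id = NA) is required")
  }
  if (any(sections$length <= 0) || any(sections$diameter <= 0)) {
    stop("section lengths and diameters must be positive")
  }
  ord <- order(sections$id)
  sections <- sections[ord, , drop = FALSE]
  rownames(sections) <- NULL
  if (is.null(nseg)) nseg <- rep(1L, nrow(sections))
  structure(list(sections = sections, nseg = as.integer(nseg)),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$sections
  cat(sprintf("<morphology> %d sections, total cable %.1f um\n",
              nrow(s), sum(s$length)))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s x%d", names(table(s$kind)), table(s$kind)),
                    collapse = ", ")))
  cat(sprintf("  segments: %d\n", sum(x$nseg)))
  invisible(x)
}

#' Build a branched basal-subtree morphology
#'
#' Like [build_ball_and_stick()], but each basal "dendrite" is a subtree: a
#' short thick stem leaving the soma that bifurcates into `n_daughters` thin
#' terminal branches, the topology of reconstructed pyramidal-cell basal
#' trees. Stems are not spine-corrected; terminal daughters are. Daughter
#' lengths are set so every tip lies `dend_length` um (path distance) from
#' the soma.
#'
#' @param n_subtrees number of basal subtrees
#' @param dend_length tip path distance from the soma, um
#' @param stem_length,stem_diam stem geometry, um
#' @param daughter_diam terminal branch diameter, um
#' @param n_daughters daughters per stem
#' @param soma_diam soma diameter, um
#' @return a `morphology`
#' @export
build_basal_tree <- function(n_subtrees = 4, dend_length = 275,
                             stem_length = 40, stem_diam = 1.4,
                             daughter_diam = 0.8, n_daughters = 2,
                             soma_diam = 20) {
  if (stem_length <= 0 || stem_length >= dend_length) {
    stop("need 0 < stem_length < dend_length")
  }
  secs <- list(data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                          length = soma_diam, diameter = soma_diam,
                          spine_corrected = FALSE, stringsAsFactors = FALSE))
  nid <- 1L
  for (st in seq_len(n_subtrees)) {
    stem_id <- nid + 1L
    secs[[length(secs) + 1L]] <- data.frame(
      id = stem_id, parent_id = 1L, kind = "basal", length = stem_length,
      diameter = stem_diam, spine_corrected = FALSE)
    nid <- stem_id
    for (dd in seq_len(n_daughters)) {
      nid <- nid + 1L
      secs[[length(secs) + 1L]] <- data.frame(
        id = nid, parent_id = stem_id, kind = "basal",
        length = dend_length - stem_length, diameter = daughter_diam,
        spine_corrected = TRUE)
    }
  }
  new_morphology(do.call(rbind, secs))
}

#' Locate the section containing a path distance along a branch
#'
#' Walks from the given terminal section toward the soma and returns the
#' dendritic section (and within-section offset) whose span contains path
#' distance `path_um` from the soma. Lets protocols address stimulus sites by
#' path distance regardless of whether the morphology is branched.
#'
#' @param m a `morphology`
#' @param branch section id of the terminal branch defining the path
#' @param path_um path distance from the soma, um
#' @return list with `section`, `pos_um` (offset within that section)
#' @export
site_at_path <- function(m, branch, path_um) {
  s <- m$sections
  chain <- integer(0)
  i <- match(branch, s$id)
  if (is.na(i)) stop("unknown section id: ", branch)
  while (!is.na(i) && s$kind[i] != "soma") {
    chain <- c(i, chain)
    i <- match(s$parent_id[i], s$id)
  }
  start <- 0
  for (i in chain) {
    if (path_um <= start + s$length[i] + 1e-9) {
      return(list(section = s$id[i], pos_um = path_um - start))
    }
    start <- start + s$length[i]
  }
  stop(sprintf("path distance %.1f um exceeds branch %d (tip at %.1f um)",
               path_um, branch, start))
}

#' Path distance from the soma to a point on a section
#'
#' Sums section lengths along the unique path from the root (soma) to the
#' given section, plus the offset `pos_um` along that section. The soma itself
#' contributes zero, so path distance along a basal dendrite equals distance
#' from the dendrite's origin.
#'
#' @param m a `morphology`
#' @param section section id
#' @param pos_um position along the section from its proximal end, um
#' @return distance in um
#' @export
path_distance <- function(m, section, pos_um = m$sections$length[match(section, m$sections$id)]) {
  s <- m$sections
  i <- match(section, s$id)
  if (is.na(i)) stop("unknown section id: ", section)
  d <- pos_um
  i <- match(s$parent_id[i], s$id)
  while (!is.na(i)) {
    if (s$kind[i] != "soma") d <- d + s$length[i]
    i <- match(s$parent_id[i], s$id)
  }
  d
}

#' Frequency-dependent length constant
#'
#' \eqn{\lambda_f = \frac{1}{2}\sqrt{d / (\pi f R_a C_m)}}, the AC length
#' constant of a cylindrical cable, used by the segmentation rule at
#' f = 100 Hz.
#'
#' @param diam_um cable diameter, um
#' @param f frequency, Hz
#' @param r_a axial resistivity, Ohm cm
#' @param c_m membrane capacitance, uF/cm^2
#' @return length constant in um
#' @export
lambda_f <- function(diam_um, f = 100, r_a = 100, c_m = 1) {
  d_cm <- diam_um * 1e-4
  lam_cm <- 0.5 * sqrt(d_cm / (pi * f * r_a * c_m * 1e-6))
  lam_cm * 1e4
}

#' Discretize a morphology into electrical compartments
#'
#' Sets the per-section segment count to the smallest odd integer such that
#' each segment is no longer than one tenth of the section's length constant
#' at `f` Hz, or `cap_um` (default 10 um), whichever is smaller. Odd counts
#' guarantee a segment centre at the section midpoint, giving stable placement
#' of stimulus and recording sites.
#'
#' @param m a `morphology`
#' @param membrane a [membrane_params()] object (supplies C_m and R_a per
#'   region; spine-corrected sections use doubled C_m)
#' @param f discretization frequency, Hz
#' @param cap_um hard cap on segment length, um
#' @return the morphology with updated `nseg`
#' @export
discretize <- function(m, membrane = membrane_params(), f = 100, cap_um = 10) {
  s <- m$sections
  nseg <- integer(nrow(s))
  has_taper <- all(c("diam_prox", "diam_tip") %in% names(s))
  for (i in seq_len(nrow(s))) {
    cm <- region_value(membrane$c_m, s$kind[i])
    if (isTRUE(s$spine_corrected[i])) cm <- 2 * cm
    d <- s$diameter[i]
    if (has_taper && !is.na(s$diam_tip[i])) d <- min(d, s$diam_tip[i], s$diam_prox[i])
    lam <- lambda_f(d, f = f, r_a = membrane$r_a, c_m = cm)
    max_len <- min(lam / 10, cap_um)
    n <- ceiling(s$length[i] / max_len)
    if (n %% 2 == 0) n <- n + 1L
    nseg[i] <- max(1L, as.integer(n))
  }
  m$nseg <- nseg
  m
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent). Contiguous chains of same-type points with single children are
#' merged into sections; section length is the summed 3D point-to-point
#' distance and diameter the mean of 2*radius along the chain.
#'
#' @param path file path
#' @return a `morphology`
#' @export
load_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("SWC file contains no data rows")
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad)) {
    stop(sprintf("malformed SWC row at line %d (expected 7 columns)", rows[bad[1]]))
  }
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(tab)) {
    stop(sprintf("malformed SWC row at line %d (non-numeric field)",
                 rows[which(apply(is.na(tab), 1, any))[1]]))
  }
  pts <- data.frame(id = as.integer(tab[, 1]), type = as.integer(tab[, 2]),
                    x = tab[, 3], y = tab[, 4], z = tab[, 5],
                    r = tab[, 6], parent = as.integer(tab[, 7]))
  roots <- which(pts$parent == -1)
  if (length(roots) != 1) {
    stop(sprintf("SWC must have exactly one root (found %d)", length(roots)))
  }
  dangling <- which(pts$parent != -1 & !(pts$parent %in% pts$id))
  if (length(dangling)) {
    stop(sprintf("dangling parent reference at line %d (parent %d not present)",
                 rows[dangling[1]], pts$parent[dangling[1]]))
  }

  idx <- match(pts$parent, pts$id)           # NA for root
  n_children <- tabulate(idx[!is.na(idx)], nbins = nrow(pts))
  # A point starts a new section if it is the root, its type differs from its
  # parent's, or its parent is a branch point (>1 child).
  starts <- is.na(idx) | pts$type != pts$type[pmax(idx, 1L)] |
    n_children[pmax(idx, 1L)] > 1
  starts[is.na(starts)] <- TRUE
  sec_of <- integer(nrow(pts))
  sec_id <- 0L
  ord <- order(pts$id)
  for (i in ord) {
    if (starts[i]) { sec_id <- sec_id + 1L; sec_of[i] <- sec_id }
    else sec_of[i] <- sec_of[idx[i]]
  }
  kinds <- c("1" = "soma", "2" = "axon_hillock", "3" = "basal", "4" = "apical")
  secs <- lapply(seq_len(sec_id), function(k) {
    pi_ <- which(sec_of == k)
    pi_ <- pi_[order(pts$id[pi_])]
    first <- pi_[1]
    chain <- pi_
    # prepend the parent point for geometry (the attachment point)
    if (!is.na(idx[first])) chain <- c(idx[first], chain)
    dx <- diff(pts$x[chain]); dy <- diff(pts$y[chain]); dz <- diff(pts$z[chain])
    len <- sum(sqrt(dx^2 + dy^2 + dz^2))
    if (len <= 0) len <- 2 * mean(pts$r[pi_])  # single-point soma sphere
    parent_sec <- if (is.na(idx[first])) NA_integer_ else sec_of[idx[first]]
    data.frame(id = k, parent_id = parent_sec,
               kind = ifelse(is.na(kinds[as.character(pts$type[pi_[1]])]),
                             "basal", kinds[as.character(pts$type[pi_[1]])]),
               length = len, diameter = 2 * mean(pts$r[pi_]),
               spine_corrected = FALSE, stringsAsFactors = FALSE)
  })
  sections <- do.call(rbind, secs)
  # terminal dendritic sections get the spine correction, as in the reduced model
  is_parent <- sections$id %in% sections$parent_id
  sections$spine_corrected <- !is_parent & sections$kind %in% c("basal", "apical")
  new_morphology(sections)
}

#' Write a morphology to SWC
#'
#' Lays sections out along +x (geometry is synthetic: only lengths, diameters
#' and topology are preserved, which is all the simulator uses).
#'
#' @param m a `morphology`
#' @param path output file path
#' @param points_per_section sample points per section
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path, points_per_section = 3) {
  s <- m$sections
  type_of <- c(soma = 1, axon_hillock = 2, axon_myelin = 2, axon_node = 2,
               basal = 3, apical = 4)
  lines <- character(0)
  pid_last <- integer(nrow(s))   # swc id of last point of each section
  next_id <- 1L
  x_end <- numeric(nrow(s)); y_end <- numeric(nrow(s))
  root <- which(is.na(s$parent_id))
  ord <- topo_order(s)
  for (i in ord) {
    if (is.na(s$parent_id[i])) {
      x0 <- 0; y0 <- 0; parent_pt <- -1L
    } else {
      p <- match(s$parent_id[i], s$id)
      x0 <- x_end[p]; y0 <- y_end[p]; parent_pt <- pid_last[p]
    }
    # offset branches in y so siblings do not overlap geometrically
    yoff <- if (is.na(s$parent_id[i])) 0 else (i - root) * 1e-3
    np <- max(2L, points_per_section)
    if (is.na(s$parent_id[i])) {
      # root: emit the starting point too
      lines <- c(lines, sprintf("%d %d %.6f %.6f 0 %.6f %d", next_id,
                                type_of[[s$kind[i]]], x0, y0, s$diameter[i] / 2,
                                -1L))
      parent_pt <- next_id; next_id <- next_id + 1L
    }
    for (k in seq_len(np - 1L)) {
      xk <- x0 + s$length[i] * k / (np - 1L)
      lines <- c(lines, sprintf("%d %d %.6f %.6f 0 %.6f %d", next_id,
                                type_of[[s$kind[i]]], xk, y0 + yoff,
                                s$diameter[i] / 2, parent_pt))
      parent_pt <- next_id; next_id <- next_id + 1L
    }
    pid_last[i] <- parent_pt
    x_end[i] <- x0 + s$length[i]; y_end[i] <- y0 + yoff
  }
  writeLines(c("# SWC written by dendarith", lines), path)
  invisible(path)
}

topo_order <- function(sections) {
  done <- rep(FALSE, nrow(sections))
  ord <- integer(0)
  repeat {
    ready <- which(!done & (is.na(sections$parent_id) |
                              sections$parent_id %in% sections$id[done]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    done[ready] <- TRUE
  }
  if (!all(done)) stop("morphology contains a cycle or unreachable section")
  ord
}

#' Export a morphology summary table
#'
#' @param m a `morphology`
#' @param path optional CSV path; if `NULL` the data.frame is returned only
#' @return data.frame of sections with segment counts and tip path distances
#' @export
morphology_summary <- function(m, path = NULL) {
  s <- m$sections
  s$nseg <- m$nseg
  s$tip_path_um <- vapply(s$id, function(id) path_distance(m, id), 0)
  if (!is.null(path)) utils::write.csv(s, path, row.names = FALSE)
  s
}
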