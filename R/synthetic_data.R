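#' Synthetic slice-experiment cohort specification
#'
#' Describes a cohort of synthetic "cells" standing in for two-input slice
#' recordings: each cell is the canonical model-generated two-input map with
#' a hidden per-cell horizontal (stimulus-efficacy) and vertical
#' (response-magnitude) scale factor, subsampled to an experimentally
#' realistic number of stimulus pairs, plus additive measurement noise.
#' Scale factors are log-normal with unit median (spread `sigma_x`,
#' `sigma_y`), capturing electrode-placement and branch-diameter variability
#' while guaranteeing positive factors. Defaults mirror the experimental
#' structure this generator emulates: 6 cells with 29-56 stimulus pairs
#' each.
#'
#' @param n_cells number of cells
#' @param pairs_range integer range of stimulus pairs per cell
#' @param sigma_x,sigma_y log-normal spreads of the hidden scale factors
#' @param noise_sd additive Gaussian noise on peaks, mV
#' @param pair_counts optional explicit per-cell pair counts (overrides
#'   `pairs_range`); the "slice-like" preset uses counts summing to 294
#' @param seed RNG seed
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_cells = 6, pairs_range = c(29, 56), sigma_x = 0.3,
                        sigma_y = 0.3, noise_sd = 0.3, pair_counts = NULL,
                        seed = 1L) {
  stopifnot(sigma_x >= 0, sigma_y >= 0, noise_sd >= 0,
            pairs_range[1] <= pairs_range[2])
  if (!is.null(pair_counts)) {
    stopifnot(length(pair_counts) == n_cells,
              all(pair_counts >= pairs_range[1]),
              all(pair_counts <= pairs_range[2]))
  }
  structure(list(n_cells = n_cells, pairs_range = pairs_range,
                 sigma_x = sigma_x, sigma_y = sigma_y, noise_sd = noise_sd,
                 pair_counts = pair_counts, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The slice-like cohort preset: 6 cells, 294 stimulus pairs in total
#' @rdname cohort_spec
#' @export
cohort_spec_294 <- function(sigma_x = 0.3, sigma_y = 0.3, noise_sd = 0.3,
                            seed = 1L) {
  cohort_spec(n_cells = 6, pairs_range = c(29, 56),
              sigma_x = sigma_x, sigma_y = sigma_y, noise_sd = noise_sd,
              pair_counts = c(56, 53, 50, 47, 44, 44), seed = seed)
}

#' Generate a synthetic two-input cohort from a canonical map
#'
#' Per cell: draw hidden scale factors (x_scale, y_scale), warp the canonical
#' map's stimulus axes by `x_scale` and its responses by `y_scale`, subsample
#' the specified number of stimulus pairs, and add Gaussian noise. The
#' sampling protocol is fixed across cells (chosen once per cohort) and
#' always includes the points that define the four fiducials - the
#' distal-alone curve, the proximal-alone curve and the just-subthreshold
#' proximally biased distal curve - so that fiducial extraction cannot fail
#' for structural reasons; remaining pairs are drawn at random from the rest
#' of the grid. Ground-truth factors are stored separately from the
#' "observed" tables.
#'
#' @param spec a [cohort_spec()]
#' @param map canonical `two_input_map` from [map_two_input()] (model
#'   generated)
#' @param criterion NRLE jump criterion used to locate the proximal
#'   just-subthreshold bias level in the canonical map
#' @param max_retries regenerate a cell at most this many times if noise
#'   makes one of its fiducials undetectable
#' @return a `synthetic_cohort`: list with `cells` (per-cell data.frames:
#'   `view`, `driver`, `modulation`, `peak`), `truth` (data.frame: cell,
#'   x_scale, y_scale), `spec`, `retries`
#' @export
generate_cohort <- function(spec, map, criterion = 1.3, max_retries = 20) {
  set.seed(spec$seed)
  fam_d <- slice_family(map, "dist")
  fam_p <- slice_family(map, "prox")

  # canonical proximal spike threshold locates the biased-distal curve
  th_p <- detect_threshold(family_curve(fam_p, 1L), criterion)
  if (is.null(th_p)) stop("canonical map has no proximal-alone spike")
  thr_count <- fam_p$x[th_p$index_supra]
  bias <- pick_bias_level(fam_d, thr_count, criterion)
  if (is.null(bias)) stop("canonical map has no usable subthreshold proximal bias level")
  bias_idx <- bias$index

  # Fixed sampling protocol (chosen once per cohort, identical x positions
  # for every cell): the three fiducial-defining curves, subsampled to an
  # experimentally realistic density while always retaining the origin, the
  # two points flanking each curve's canonical spike threshold, and the top
  # of the ramp, so threshold detection lands on the same stimulus values as
  # on the full grid.
  subsample_idx <- function(x, y, criterion) {
    n <- length(x)
    th <- detect_threshold(io_curve(x, y), criterion)
    ess <- c(1L, n)
    if (!is.null(th)) {
      ess <- c(ess, max(1L, th$index_sub - 1L):min(n, th$index_supra + 1L))
    }
    ess <- sort(unique(ess))
    list(ess = ess, opt = setdiff(seq(1L, n, by = 2L), ess))
  }
  i_d <- subsample_idx(fam_d$x, fam_d$curves[1, ], criterion)
  i_p <- subsample_idx(fam_p$x, fam_p$curves[1, ], criterion)
  i_b <- subsample_idx(fam_d$x, fam_d$curves[bias_idx, ], criterion)
  mk_rows <- function(view, fam, level_idx, idx) {
    data.frame(view = view, driver = fam$x[idx],
               modulation = fam$modulation[level_idx],
               peak = fam$curves[level_idx, idx])
  }
  base_ess <- rbind(mk_rows("dist", fam_d, 1L, i_d$ess),
                    mk_rows("prox", fam_p, 1L, i_p$ess),
                    mk_rows("dist", fam_d, bias_idx, i_b$ess))
  base_opt <- rbind(mk_rows("dist", fam_d, 1L, i_d$opt),
                    mk_rows("prox", fam_p, 1L, i_p$opt),
                    mk_rows("dist", fam_d, bias_idx, i_b$opt))
  # candidate filler pairs: all other grid combinations in the distal view
  other_idx <- setdiff(seq_along(fam_d$modulation), c(1L, bias_idx))
  filler <- do.call(rbind, lapply(other_idx, function(k) {
    data.frame(view = "dist", driver = fam_d$x,
               modulation = fam_d$modulation[k], peak = fam_d$curves[k, ])
  }))

  counts <- if (!is.null(spec$pair_counts)) spec$pair_counts else {
    sample(seq(spec$pairs_range[1], spec$pairs_range[2]), spec$n_cells,
           replace = TRUE)
  }

  cells <- vector("list", spec$n_cells)
  truth <- data.frame(cell = seq_len(spec$n_cells), x_scale = NA_real_,
                      y_scale = NA_real_)
  retries <- 0L
  for (ci in seq_len(spec$n_cells)) {
    n_pairs <- max(counts[ci], nrow(base_ess))
    # fill the protocol up to the requested pair count: first the optional
    # density points (evenly thinned if the budget is tight), then random
    # grid pairs from the rest of the map
    n_opt <- min(n_pairs - nrow(base_ess), nrow(base_opt))
    opt_rows <- if (n_opt > 0) {
      base_opt[unique(round(seq(1, nrow(base_opt), length.out = n_opt))), ,
               drop = FALSE]
    } else base_opt[0, , drop = FALSE]
    base <- rbind(base_ess, opt_rows)
    n_extra <- min(n_pairs - nrow(base), nrow(filler))
    ok <- FALSE
    for (try in seq_len(max_retries + 1L)) {
      xs <- rlnorm(1, 0, spec$sigma_x)
      ys <- rlnorm(1, 0, spec$sigma_y)
      extra <- filler[sample.int(nrow(filler), n_extra), , drop = FALSE]
      tab <- rbind(base, extra)
      tab$driver <- tab$driver * xs
      tab$modulation <- tab$modulation * xs
      tab$peak <- tab$peak * ys
      if (spec$noise_sd > 0) {
        tab$peak <- tab$peak + rnorm(nrow(tab), 0, spec$noise_sd)
        # zero stimulus gives zero depolarization by construction
        tab$peak[tab$driver == 0 & tab$modulation == 0] <- 0
      }
      rownames(tab) <- NULL
      fid <- tryCatch({
        fam <- cell_table_to_family(tab)
        extract_fiducials(fam$dist, fam$prox, criterion = criterion)
      }, error = function(e) NULL)
      if (!is.null(fid)) {
        cells[[ci]] <- tab
        truth$x_scale[ci] <- xs
        truth$y_scale[ci] <- ys
        ok <- TRUE
        break
      }
      retries <- retries + 1L
    }
    if (!ok) {
      stop(sprintf("cell %d: fiducials undetectable after %d retries (noise too large?)",
                   ci, max_retries))
    }
  }
  structure(list(cells = cells, truth = truth, spec = spec,
                 retries = retries),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cells, %s stimulus pairs (total %d)\n",
              length(x$cells),
              paste(range(vapply(x$cells, nrow, 0L)), collapse = "-"),
              sum(vapply(x$cells, nrow, 0L))))
  invisible(x)
}

#' Write / read a synthetic cohort as CSV + JSON manifest
#'
#' One CSV per cell (`cell<k>.csv`, the dialect [normalize_cohort()] reads)
#' plus `manifest.json` holding the spec, seed and ground-truth factors.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ci in seq_along(cohort$cells)) {
    utils::write.csv(cohort$cells[[ci]],
                     file.path(dir, sprintf("cell%d.csv", ci)),
                     row.names = FALSE)
  }
  manifest <- list(spec = unclass(cohort$spec), truth = cohort$truth,
                   n_cells = length(cohort$cells))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cells <- lapply(seq_len(manifest$n_cells), function(ci) {
    utils::read.csv(file.path(dir, sprintf("cell%d.csv", ci)),
                    stringsAsFactors = FALSE)
  })
  spec <- do.call(cohort_spec, manifest$spec[c("n_cells", "pairs_range",
                                              "sigma_x", "sigma_y",
                                              "noise_sd", "pair_counts",
                                              "seed")])
  structure(list(cells = cells, truth = manifest$truth, spec = spec,
                 retries = NA_integer_),
            class = "synthetic_cohort")
}
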