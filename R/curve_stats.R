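#' Input-output curve container
#'
#' A stimulus-response curve: stimulus intensity (synapse count, laser or
#' electrode intensity) against peak somatic depolarization.
#'
#' @param x stimulus intensities, strictly increasing
#' @param y peak responses, mV, finite, same length as `x`
#' @param meta optional named list (site distance, protocol, cell id, ...)
#' @return an `io_curve`
#' @export
io_curve <- function(x, y, meta = list()) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (!all(is.finite(y))) stop("y must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y), meta = meta),
            class = "io_curve")
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("<io_curve> %d points, x in [%g, %g], peak %.3g mV\n",
              length(x$x), min(x$x), max(x$x), max(x$y)))
  invisible(x)
}

#' Nonlinearity Relative to Linear Extrapolation (NRLE)
#'
#' For each point from the second onward, an ordinary least-squares line is
#' fit to all preceding data points and extrapolated to the point's abscissa;
#' the ratio of the actual to the extrapolated response is computed, and the
#' maximum of this ratio along the curve is the NRLE. Values above 1 indicate
#' a supralinear (local-spike-like) upturn; a saturating curve scores below 1.
#'
#' With `anchor_origin = TRUE` (default) the physically forced point (0, 0)
#' (zero stimulus gives zero depolarization) joins the fit, which makes the
#' first evaluated fit well-posed, so evaluation starts at the second data
#' point. The origin is only added when the curve does not already start at
#' x = 0 (curve families with a modulator-alone intercept carry a meaningful
#' nonzero response at x = 0). Without anchoring, evaluation starts at the
#' third point.
#'
#' Indices where the extrapolated value is not positive are skipped with a
#' warning (the ratio is meaningless there).
#'
#' @param c an `io_curve`
#' @param anchor_origin add (0, 0) to every fit (see Details)
#' @return list with `nrle` (the maximum ratio), `index` (its position in the
#'   curve, ties toward the smaller index), and `ratio` (per-point ratios, NA
#'   where not evaluated)
#' @export
compute_nrle <- function(c, anchor_origin = TRUE) {
  x <- c$x; y <- c$y
  n <- length(x)
  add_origin <- anchor_origin && x[1] > 0
  start <- if (add_origin) 2L else 3L
  ratio <- rep(NA_real_, n)
  skipped <- 0L
  for (i in start:n) {
    xf <- x[seq_len(i - 1L)]; yf <- y[seq_len(i - 1L)]
    if (add_origin) { xf <- c(0, xf); yf <- c(0, yf) }
    fit <- stats::lm.fit(cbind(1, xf), yf)
    y_extrap <- sum(fit$coefficients * c(1, x[i]))
    if (!is.finite(y_extrap) || y_extrap <= 0) { skipped <- skipped + 1L; next }
    ratio[i] <- y[i] / y_extrap
  }
  if (skipped > 0) {
    warning(sprintf("%d index(es) skipped: non-positive linear extrapolation",
                    skipped))
  }
  if (all(is.na(ratio))) {
    return(list(nrle = NA_real_, index = NA_integer_, ratio = ratio))
  }
  idx <- which.max(ratio)   # NA-safe; ties toward smaller index
  list(nrle = ratio[idx], index = idx, ratio = ratio)
}

#' Detect the local-spike threshold on an input-output curve
#'
#' The just-suprathreshold index is the NRLE-maximizing point (the curve's
#' largest/sharpest upturn); the just-subthreshold index is the point before
#' it. Returns `NULL` when the curve's NRLE does not reach `criterion`
#' (default 1.3), i.e. when no discontinuous jump is present.
#'
#' On noisy curves, points with near-zero responses can produce spuriously
#' large extrapolation ratios; since a local spike is by construction a
#' substantial fraction of the curve's range, candidate indices must carry a
#' response of at least `min_frac` of the curve maximum (set `min_frac = 0`
#' to disable the guard).
#'
#' @param c an `io_curve`
#' @param criterion minimum NRLE counted as a spike jump
#' @param anchor_origin passed to [compute_nrle()]
#' @param min_frac minimum response at the candidate index, as a fraction of
#'   the curve maximum
#' @return `NULL`, or a list with `index_sub`, `index_supra`, `nrle`
#' @export
detect_threshold <- function(c, criterion = 1.3, anchor_origin = TRUE,
                             min_frac = 0.2) {
  r <- suppressWarnings(compute_nrle(c, anchor_origin = anchor_origin))
  ratio <- r$ratio
  ratio[!is.na(ratio) & c$y < min_frac * max(c$y)] <- NA
  if (all(is.na(ratio))) return(NULL)
  idx <- which.max(ratio)
  if (ratio[idx] < criterion) return(NULL)
  list(index_sub = idx - 1L, index_supra = idx, nrle = ratio[idx])
}

#' Read/write input-output curves as CSV
#'
#' Two columns `x`, `y`; metadata serialized as `# key: value` header lines.
#'
#' @param c an `io_curve`
#' @param path file path
#' @return `write_io_curve`: `path`, invisibly; `read_io_curve`: an `io_curve`
#' @export
write_io_curve <- function(c, path) {
  hdr <- sprintf("# %s: %s", names(c$meta), vapply(c$meta, format, ""))
  writeLines(c(hdr, "x,y",
               sprintf("%.10g,%.10g", c$x, c$y)), path)
  invisible(path)
}

#' @rdname write_io_curve
#' @export
read_io_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv); v <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (is.na(num)) v else num
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  io_curve(tab$x, tab$y, meta = meta)
}
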