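# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the 2-D Newton solver works on the raw
# Kirchhoff system without the V_prox elimination; the NRLE oracle fits with
# lm(); the rank-sum p-value is enumerated exhaustively.

# Damped Newton on the full two-node Kirchhoff system from random starts.
# Returns the data.frame of distinct roots found (v_prox, v_dist).
newton_two_comp <- function(p, n_prox, n_dist, n_starts = 100, seed = 1,
                            tol = 1e-12) {
  set.seed(seed)
  B <- function(v) 1 / (1 + exp(-(v + p$mg_half) / p$mg_slope))
  Bp <- function(v) B(v) * (1 - B(v)) / p$mg_slope
  F <- function(v) {
    vp <- v[1]; vd <- v[2]
    c(p$g_leak_prox * (vp - p$e_rest) + p$g_axial * (vp - vd) -
        n_prox * p$g_nmda_unit * B(vp) * (p$e_syn - vp),
      p$g_leak_dist * (vd - p$e_rest) + p$g_axial * (vd - vp) -
        n_dist * p$g_nmda_unit * B(vd) * (p$e_syn - vd))
  }
  J <- function(v) {
    vp <- v[1]; vd <- v[2]
    dp <- p$g_leak_prox + p$g_axial -
      n_prox * p$g_nmda_unit * (Bp(vp) * (p$e_syn - vp) - B(vp))
    dd <- p$g_leak_dist + p$g_axial -
      n_dist * p$g_nmda_unit * (Bp(vd) * (p$e_syn - vd) - B(vd))
    matrix(c(dp, -p$g_axial, -p$g_axial, dd), 2, 2, byrow = TRUE)
  }
  roots <- list()
  starts <- rbind(c(p$e_rest + 1e-3, p$e_rest + 1e-3),   # rest-connected
                  c(p$e_syn - 10, p$e_syn - 10),          # upper branch
                  c(p$e_rest + 30, p$e_rest + 30))
  n_random <- max(0, n_starts - nrow(starts))
  starts <- rbind(starts,
                  matrix(runif(2 * n_random, p$e_rest, p$e_syn), ncol = 2))
  for (s in seq_len(nrow(starts))) {
    v <- starts[s, ]
    for (it in 1:200) {
      fv <- F(v)
      if (max(abs(fv)) < tol) break
      step <- tryCatch(solve(J(v), fv), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        v_new <- v - lambda * step
        if (max(abs(F(v_new))) < max(abs(fv)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      v <- v_new
    }
    if (max(abs(F(v))) < 1e-9 && v[2] >= p$e_rest - 1e-6 && v[2] <= p$e_syn + 1e-6) {
      roots[[length(roots) + 1]] <- v
    }
  }
  if (!length(roots)) return(data.frame(v_prox = numeric(0), v_dist = numeric(0)))
  m <- do.call(rbind, roots)
  keep <- !duplicated(round(m[, 2], 6))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 2]), , drop = FALSE]
  data.frame(v_prox = m[, 1], v_dist = m[, 2])
}

# Brute-force NRLE via lm() fits at every index.
nrle_oracle <- function(x, y, anchor_origin = TRUE) {
  add0 <- anchor_origin && x[1] > 0
  start <- if (add0) 2L else 3L
  best <- -Inf
  for (i in start:length(x)) {
    xf <- x[seq_len(i - 1)]; yf <- y[seq_len(i - 1)]
    if (add0) { xf <- c(0, xf); yf <- c(0, yf) }
    fit <- lm(yf ~ xf)
    pred <- unname(predict(fit, data.frame(xf = x[i])))
    if (is.finite(pred) && pred > 0) best <- max(best, y[i] / pred)
  }
  best
}

# Exact one-sided rank-sum p-value by exhaustive enumeration of labelings.
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  w_obs <- sum(rank(pooled)[seq_along(a)])
  w_all <- apply(idx, 2, function(k) sum(rank(pooled)[k]))
  mean(w_all <= w_obs)
}
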