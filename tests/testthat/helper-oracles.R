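# Independent reference implementations used as oracles.  These are kept
# deliberately naive and share no code with the package internals.

# Brute-force gromos reference: recompute every neighbor count from
# scratch each round, no incremental bookkeeping.
gromos_bruteforce <- function(m, cutoff) {
  n <- nrow(m)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned) > 0) {
    best_center <- NA_integer_
    best_count <- -1L
    for (i in unassigned) {
      cnt <- 0L
      for (j in unassigned) if (m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best_center <- i }
    }
    members <- unassigned[m[best_center, unassigned] <= cutoff]
    clusters[[length(clusters) + 1L]] <- list(center = best_center,
                                              members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  clusters[order(-sizes, centers)]
}

# random symmetric RMSD-like matrix (zero diagonal, non-negative)
random_rmsd_matrix <- function(n, scale = 2) {
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Grid-scan oracle for the CFT-ML root: locate the minimizer of the
# residual magnitude by dense scanning plus golden-section refinement.
cft_gridscan <- function(ws) {
  beta <- 1 / (cdbind::KB_KCAL * ws$temperature)
  resid <- function(dG) {
    M <- log(length(ws$forward_works) / length(ws$reverse_works))
    sum(1 / (1 + exp(pmin(700, M + beta * (ws$forward_works - dG))))) -
      sum(1 / (1 + exp(pmin(700, -M + beta * (dG + ws$reverse_works)))))
  }
  allw <- c(ws$forward_works, -ws$reverse_works)
  lo <- min(allw) - 30; hi <- max(allw) + 30
  grid <- seq(lo, hi, length.out = 4001)
  vals <- vapply(grid, function(g) abs(resid(g)), numeric(1))
  i <- which.min(vals)
  a <- grid[max(1, i - 1)]; b <- grid[min(length(grid), i + 1)]
  stats::optimize(function(g) abs(resid(g)), c(a, b), tol = 1e-10)$minimum
}

# Brute-force superposition RMSD: coarse Euler-angle grid followed by
# Nelder-Mead refinement; independent of the SVD solution.
rmsd_bruteforce <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((b %*% rotmat(ang) - a)^2)))
  step <- pi / 18   # 10 degree grid
  best <- c(0, 0, 0); best_val <- obj(best)
  for (az in seq(-pi, pi, by = step))
    for (ay in seq(-pi / 2, pi / 2, by = step))
      for (ax in seq(-pi, pi, by = step)) {
        v <- obj(c(az, ay, ax))
        if (v < best_val) { best_val <- v; best <- c(az, ay, ax) }
      }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  res$value
}

# 1:2 sequential-binding enhancement isotherm (for stoichiometry checks):
# two bound species with stepwise constants K1, K2 and distinct molar
# enhancements.
two_site_isotherm <- function(conc, K1, K2, dF1, dF2) {
  denom <- 1 + K1 * conc + K1 * K2 * conc^2
  (dF1 * K1 * conc + dF2 * K1 * K2 * conc^2) / denom
}

# shared small-scale Crooks recovery study; returns per-seed estimates,
# bootstrap SEs and truth
crooks_recovery_study <- function(dg_true = -1.40, sigma_w = 1.0, n = 2000,
                                  n_seeds = 20, n_boot = 100) {
  res <- lapply(seq_len(n_seeds), function(s) {
    ws <- gen_crooks_work(dg_true, sigma_w, n, n, seed = 1000 + s)
    est <- cft_ml_estimate(ws)$value
    se <- bootstrap_uncertainty(ws, cft_ml_estimate, n_boot = n_boot,
                                seed = 2000 + s)
    c(est = est, se = se)
  })
  m <- do.call(rbind, res)
  list(est = m[, "est"], se = m[, "se"], dg_true = dg_true)
}
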