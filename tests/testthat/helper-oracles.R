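# Independent oracles: brute-force or closed-form routes kept separate
# from the implementation paths they check.

# weighted least squares of by on bx through the origin,
# weights 1/sy^2 — the algebraic twin of fixed-effects IVW with
# first-order ratio SEs
oracle_wls_origin <- function(bx, by, sy) {
  w <- 1 / sy^2
  list(theta = sum(w * bx * by) / sum(w * bx^2),
       se = 1 / sqrt(sum(w * bx^2)))
}

# closed-form weighted normal equations for intercept + slope with
# residual-variance-scaled covariance (the Egger regression model)
oracle_egger_wls <- function(bx, by, sy) {
  flip <- bx < 0
  bx <- ifelse(flip, -bx, bx)
  by <- ifelse(flip, -by, by)
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * by))
  r <- by - X %*% coef
  sigma2 <- sum(w * r^2) / (length(bx) - 2)
  ses <- sqrt(diag(sigma2 * solve(XtWX)))
  list(intercept = unname(coef[1]), slope = unname(coef[2]),
       intercept_se = unname(ses[1]), slope_se = unname(ses[2]))
}

# dense-grid argmax of the inverse-variance-weighted Gaussian kernel
# density over per-SNP ratios (same kernel and bandwidth rule as the
# estimator; the argmax route is independent)
oracle_mode_grid <- function(ratio, w, h, n_grid = 200001L) {
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h,
              length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / h)),
                 numeric(1))
  list(mode = grid[which.max(dens)], resolution = diff(grid[1:2]))
}

# leave-one-out IVW by the downdate identity on the full-set sums
oracle_loo_downdate <- function(bx, by, sy) {
  r <- by / bx
  se <- sy / abs(bx)
  w <- 1 / se^2
  Sw <- sum(w)
  Swr <- sum(w * r)
  t(vapply(seq_along(bx), function(j) {
    c(theta = (Swr - w[j] * r[j]) / (Sw - w[j]),
      se = 1 / sqrt(Sw - w[j]))
  }, c(theta = 0, se = 0)))
}

# grid-search maximizer of the written profile likelihood
oracle_mle_grid <- function(bx, by, sx, sy, lo = -2, hi = 2,
                            step = 1e-5) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(th)
    -0.5 * sum((by - th * bx)^2 / (sy^2 + th^2 * sx^2)), numeric(1))
  grid[which.max(ll)]
}

# brute-force significance filter count
oracle_filter_count <- function(p, threshold) {
  n <- 0L
  for (pi in p) if (pi <= threshold) n <- n + 1L
  n
}

# verify the two posted clumping properties directly: the accepted set
# is pairwise below threshold, and every rejected SNP conflicts with an
# accepted SNP ranked above it
oracle_clump_check <- function(v_all, v_kept, r2, threshold) {
  kept <- v_kept$snp_id
  r2k <- r2[kept, kept, drop = FALSE]
  pairwise_ok <- all(r2k[upper.tri(r2k)] < threshold)
  rank_key <- function(v) order(-abs(v$beta), v$pvalue, v$snp_id)
  ranked_ids <- v_all$snp_id[rank_key(v_all)]
  rejected <- setdiff(v_all$snp_id, kept)
  rejected_ok <- all(vapply(rejected, function(id) {
    conflicts <- kept[r2[id, kept] >= threshold]
    length(conflicts) > 0 &&
      min(match(conflicts, ranked_ids)) < match(id, ranked_ids)
  }, logical(1)))
  pairwise_ok && rejected_ok
}
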