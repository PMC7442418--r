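# Causal-effect estimators on harmonized instrument sets: Wald ratio,
# fixed-effects IVW, profile maximum likelihood, weighted median, weighted
# mode, and MR-Egger regression. All effects are log odds of the outcome
# per SD unit of the genetically predicted exposure.

# pull the kept rows of a HarmonizedInstruments (or accept a plain
# data.frame with the same columns, used internally by the bootstrap)
.inst_data <- function(insts) {
  if (methods::is(insts, "HarmonizedInstruments"))
    return(keptInstruments(insts))
  stopifnot(is.data.frame(insts))
  insts
}

# per-SNP Wald ratios with first- or second-order delta-method SEs
.ratio_stats <- function(d, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(d$beta_exposure == 0))
    stop("beta_exposure = 0 for SNP(s) ",
         paste(d$snp_id[d$beta_exposure == 0], collapse = ", "),
         ": Wald ratio undefined")
  r <- d$beta_outcome / d$beta_exposure
  se <- if (se_order == "first") {
    d$se_outcome / abs(d$beta_exposure)
  } else {
    sqrt(d$se_outcome^2 / d$beta_exposure^2 +
           d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  }
  list(ratio = r, se = se)
}

#' Transform a log-scale effect to the odds-ratio scale
#'
#' @param theta Log odds ratio per SD of exposure.
#' @param se Positive standard error of \code{theta}.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector: \code{or_sd} = exp(theta), \code{ci_low}
#'   and \code{ci_high} = exp(theta -/+ z * se), and the two-sided normal
#'   \code{pvalue}.
#' @export
toORScale <- function(theta, se, level = 0.95) {
  stopifnot(is.finite(se), se > 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(or_sd = exp(theta),
    ci_low = exp(theta - z * se),
    ci_high = exp(theta + z * se),
    pvalue = 2 * stats::pnorm(-abs(theta / se)))
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure
#' effect. The default first-order standard error is
#' \code{se_outcome / |beta_exposure|}; the second-order option adds the
#' exposure-uncertainty term of the delta method,
#' \eqn{\sqrt{se_y^2/\beta_x^2 + \beta_y^2 se_x^2/\beta_x^4}}.
#'
#' @param inst A \code{\linkS4class{HarmonizedInstruments}} with exactly
#'   one kept instrument (or a one-row instrument data frame).
#' @param se_order \code{"first"} (default) or \code{"second"}.
#' @param level Confidence level.
#' @return An \code{\linkS4class{MREstimate}} with method \code{wald}.
#' @export
waldRatio <- function(inst, se_order = "first", level = 0.95) {
  d <- .inst_data(inst)
  if (nrow(d) != 1L)
    stop("waldRatio needs exactly one instrument, got ", nrow(d))
  rs <- .ratio_stats(d, se_order)
  .mr_estimate("wald", rs$ratio, rs$se, 1L, level)
}

#' Fixed-effects inverse-variance-weighted estimate
#'
#' Meta-analysis of the per-SNP Wald ratios with weights equal to the
#' inverse squared ratio standard errors: \eqn{\hat\theta = \sum w_j
#' \theta_j / \sum w_j}, \eqn{se = (\sum w_j)^{-1/2}}. Fixed effects: no
#' overdispersion scaling is applied. With first-order ratio SEs this is
#' algebraically identical to weighted least squares of the outcome
#' effects on the exposure effects through the origin with weights
#' \code{1/se_outcome^2}.
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least one kept instrument.
#' @param se_order Ratio SE order, \code{"first"} (default) or
#'   \code{"second"}.
#' @param level Confidence level.
#' @return An \code{\linkS4class{MREstimate}} with method \code{ivw_fe}.
#' @export
ivwFE <- function(insts, se_order = "first", level = 0.95) {
  d <- .inst_data(insts)
  if (!nrow(d)) stop("ivwFE needs at least one instrument")
  rs <- .ratio_stats(d, se_order)
  w <- 1 / rs$se^2
  .mr_estimate("ivw_fe", sum(w * rs$ratio) / sum(w), 1 / sqrt(sum(w)),
               nrow(d), level)
}

# profile log-likelihood of theta: per SNP the observed (beta_x, beta_y)
# are independent normals around (gamma_j, theta * gamma_j) with known
# SEs; profiling out gamma_j leaves
#   l(theta) = -1/2 * sum (beta_y - theta beta_x)^2 /
#                         (se_y^2 + theta^2 se_x^2)
.mle_profile_ll <- function(theta, bx, by, sx2, sy2) {
  r <- by - theta * bx
  v <- sy2 + theta^2 * sx2
  -0.5 * sum(r^2 / v)
}

#' Profile maximum-likelihood estimate
#'
#' Bivariate-normal measurement model with independent errors
#' (non-overlapping samples, zero cross-trait correlation): per SNP the
#' observed effects are normal around \eqn{(\gamma_j, \theta\gamma_j)}
#' with their reported SEs. The nuisance \eqn{\gamma_j} are profiled out
#' in closed form and \eqn{\theta} maximizes the profile likelihood by a
#' safeguarded Newton iteration started at the IVW estimate. The standard
#' error comes from the observed information (numerical curvature of the
#' profile log-likelihood at the maximum).
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least two kept instruments.
#' @param tol Convergence tolerance on the Newton step (default 1e-8).
#' @param max_iter Iteration cap (default 200); non-convergence is an
#'   error carrying the iteration trace.
#' @param level Confidence level.
#' @return An \code{\linkS4class{MREstimate}} with method \code{mle}.
#' @export
maxLikelihood <- function(insts, tol = 1e-8, max_iter = 200L,
                          level = 0.95) {
  d <- .inst_data(insts)
  if (nrow(d) < 2L) stop("maxLikelihood needs at least two instruments")
  bx <- d$beta_exposure; by <- d$beta_outcome
  sx2 <- d$se_exposure^2; sy2 <- d$se_outcome^2
  ll <- function(th) .mle_profile_ll(th, bx, by, sx2, sy2)
  # analytic first derivative of the profile log-likelihood
  grad <- function(th) {
    r <- by - th * bx
    v <- sy2 + th^2 * sx2
    sum(r * bx / v + th * sx2 * r^2 / v^2)
  }
  hess <- function(th) {
    h <- max(1e-6, 1e-6 * abs(th))
    (grad(th + h) - grad(th - h)) / (2 * h)
  }
  theta <- theta(ivwFE(insts, se_order = "first"))
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- grad(theta)
    H <- hess(theta)
    step <- if (is.finite(H) && H < 0) -g / H else g * 1e-2
    # halve until the likelihood does not decrease (safeguard)
    l0 <- ll(theta)
    for (k in 0:30) {
      cand <- theta + step / 2^k
      if (is.finite(ll(cand)) && ll(cand) >= l0 - 1e-12) break
    }
    theta_new <- theta + step / 2^k
    trace <- c(trace, theta_new)
    if (abs(theta_new - theta) < tol && abs(g) < 1e-6) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  if (!converged) {
    err <- simpleError(paste0("profile MLE did not converge after ",
                              max_iter, " iterations"))
    err$trace <- trace
    stop(err)
  }
  h <- max(1e-6, 1e-6 * abs(theta))
  info <- -(ll(theta + h) - 2 * ll(theta) + ll(theta - h)) / h^2
  if (!is.finite(info) || info <= 0)
    stop("observed information not positive at the MLE")
  .mr_estimate("mle", theta, 1 / sqrt(info), nrow(d), level)
}

# weighted-median point estimate on ratio estimates with weights w:
# order ratios, standardized cumulative weight p_j = (S_j - w_j/2)/S_tot,
# linear interpolation to p = 0.5
.weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE shared by the median and mode estimators.
# The data are sign-oriented by the point estimate before resampling so
# that negating every outcome effect leaves the bootstrap (and hence the
# SE) exactly invariant under the same seed.
.bootstrap_se <- function(d, point, n_boot, seed, se_order, statistic) {
  s <- if (point < 0) -1 else 1
  by0 <- s * d$beta_outcome
  est <- numeric(n_boot)
  .with_seed(seed, {
    for (b in seq_len(n_boot)) {
      db <- d
      db$beta_exposure <- stats::rnorm(nrow(d), d$beta_exposure,
                                       d$se_exposure)
      db$beta_outcome <- stats::rnorm(nrow(d), by0, d$se_outcome)
      est[b] <- statistic(db)
    }
  })
  stats::sd(est)
}

#' Weighted median estimate
#'
#' Consistent when instruments carrying at least half of the weight are
#' valid. Per-SNP Wald ratios are ordered, inverse-variance weights
#' standardized to cumulative probabilities \eqn{p_j = (S_j - w_j/2) /
#' S_{total}}, and the estimate interpolates linearly to p = 0.5. The
#' standard error is a seeded parametric bootstrap: exposure and outcome
#' effects are resampled from normals with their reported SEs and the
#' median recomputed.
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least three kept instruments.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory; identical inputs
#'   and seed give bit-identical SEs).
#' @param se_order Ratio SE order used for the weights.
#' @param level Confidence level.
#' @return An \code{\linkS4class{MREstimate}} with method
#'   \code{weighted_median}.
#' @export
weightedMedian <- function(insts, n_boot = 1000L, seed = 1L,
                           se_order = "first", level = 0.95) {
  d <- .inst_data(insts)
  if (nrow(d) < 3L) stop("weightedMedian needs at least three instruments")
  point_of <- function(dd) {
    rs <- .ratio_stats(dd, se_order)
    .weighted_median_point(rs$ratio, 1 / rs$se^2)
  }
  point <- point_of(d)
  se <- .bootstrap_se(d, point, n_boot, seed, se_order,
                      function(db) point_of(db))
  .mr_estimate("weighted_median", point, se, nrow(d), level)
}

# rule-of-thumb bandwidth on the ratio spread (modified Silverman on the
# smaller of SD and scaled MAD)
.mode_bandwidth <- function(ratio, phi) {
  spread <- min(stats::sd(ratio), stats::mad(ratio))
  if (!is.finite(spread) || spread <= 0)
    spread <- max(stats::sd(ratio), 0)
  phi * 0.9 * spread * length(ratio)^(-1 / 5)
}

# argmax of the weighted Gaussian-kernel density over the ratios:
# coarse grid bracket, then golden-section refinement
.weighted_mode_point <- function(ratio, w, h) {
  if (h <= 0 || max(ratio) - min(ratio) < .Machine$double.eps)
    return(ratio[which.max(w)])
  dens <- function(x)
    as.vector(stats::dnorm(outer(x, ratio, "-") / h) %*% w)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)$maximum
}

#' Weighted mode estimate
#'
#' Anchors the causal effect on the most common per-SNP ratio: the
#' estimate maximizes an inverse-variance-weighted Gaussian kernel
#' density over the Wald ratios, with bandwidth \code{phi} times a
#' rule-of-thumb bandwidth (0.9 min(SD, MAD) n^(-1/5) of the ratios).
#' Robust when the largest cluster of instruments is valid. Standard
#' error by the same seeded parametric bootstrap as the weighted median.
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least three kept instruments.
#' @param phi Bandwidth multiplier, > 0 (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param se_order Ratio SE order used for the weights.
#' @param level Confidence level.
#' @return An \code{\linkS4class{MREstimate}} with method
#'   \code{weighted_mode}.
#' @export
weightedMode <- function(insts, phi = 1, n_boot = 1000L, seed = 1L,
                         se_order = "first", level = 0.95) {
  d <- .inst_data(insts)
  if (nrow(d) < 3L) stop("weightedMode needs at least three instruments")
  stopifnot(phi > 0)
  point_of <- function(dd) {
    rs <- .ratio_stats(dd, se_order)
    w <- 1 / rs$se^2
    .weighted_mode_point(rs$ratio, w / sum(w),
                         .mode_bandwidth(rs$ratio, phi))
  }
  point <- point_of(d)
  se <- .bootstrap_se(d, point, n_boot, seed, se_order,
                      function(db) point_of(db))
  .mr_estimate("weighted_mode", point, se, nrow(d), level)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects \emph{with} an intercept, weights \code{1/se_outcome^2}, after
#' orienting every SNP so its exposure effect is positive (both betas
#' negated where needed; the caller's object is never mutated). The slope
#' estimates the causal effect under the InSIDE assumption; an intercept
#' deviating from zero indicates directional horizontal pleiotropy.
#' Standard errors are the weighted-least-squares ones scaled by the
#' residual standard deviation, with two-sided normal p-values.
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least three kept instruments.
#' @param level Confidence level.
#' @return An \code{\linkS4class{EggerResult}}.
#' @export
eggerRegression <- function(insts, level = 0.95) {
  d <- .inst_data(insts)
  if (nrow(d) < 3L) stop("eggerRegression needs at least three instruments")
  flip <- d$beta_exposure < 0
  bx <- ifelse(flip, -d$beta_exposure, d$beta_exposure)
  by <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  if (max(bx) - min(bx) < .Machine$double.eps * max(abs(bx)))
    stop("all exposure effects equal after orientation: ",
         "Egger design is singular")
  w <- 1 / d$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  # an exact fit has zero residual variance; floor the SEs so the
  # estimate object stays well-formed
  slope <- .mr_estimate("egger_slope", cf["bx", "Estimate"],
                        max(cf["bx", "Std. Error"], 1e-12), nrow(d),
                        level)
  intercept <- cf["(Intercept)", "Estimate"]
  intercept_se <- max(cf["(Intercept)", "Std. Error"], 1e-12)
  methods::new("EggerResult", slope = slope, intercept = intercept,
               interceptSE = intercept_se,
               interceptPvalue =
                 2 * stats::pnorm(-abs(intercept / intercept_se)))
}
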