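# A priori power for two-sample MR with a binary outcome (normal
# approximation).

#' A priori power for a binary-outcome MR study
#'
#' Normal-approximation power of the two-sided Wald test of the causal
#' log odds ratio. The test statistic is approximately normal with unit
#' variance and mean
#' \eqn{\mu = |\theta| \sqrt{n \, R^2 \, \phi (1-\phi)}}, where \eqn{R^2}
#' is the variance of the exposure explained by the instruments, \eqn{n}
#' the outcome study size and \eqn{\phi} its case fraction. Power is the
#' two-sided tail mass
#' \eqn{\Phi(-z_{1-\alpha/2} + \mu) + \Phi(-z_{1-\alpha/2} - \mu)}, which
#' equals \eqn{\alpha} exactly at \eqn{\theta = 0} and is monotone in
#' \eqn{|\theta|}, \eqn{R^2} and \eqn{n}. Outputs are approximate by
#' construction and labelled as such in run manifests.
#'
#' @param r2_exposure Variance of the exposure explained by the
#'   instruments, in [0, 1). Zero gives the degenerate power
#'   \code{alpha} and a warning.
#' @param n_total Outcome study size (cases + controls).
#' @param case_fraction Case fraction in (0, 1).
#' @param theta Hypothesized causal log odds ratio per SD.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in [0, 1].
#' @export
powerBinaryOutcome <- function(r2_exposure, n_total, case_fraction,
                               theta, alpha = 0.05) {
  stopifnot(r2_exposure >= 0, r2_exposure < 1, n_total > 0,
            case_fraction > 0, case_fraction < 1, alpha > 0, alpha < 1)
  if (r2_exposure == 0)
    warning("r2_exposure = 0: power degenerates to the test size alpha")
  z <- stats::qnorm(1 - alpha / 2)
  mu <- abs(theta) * sqrt(n_total * r2_exposure * case_fraction *
                            (1 - case_fraction))
  stats::pnorm(-z + mu) + stats::pnorm(-z - mu)
}

#' Smallest detectable odds ratio at a target power
#'
#' Inverts \code{powerBinaryOutcome()} over \eqn{|\theta|} by monotone
#' root finding and returns the corresponding odds ratio per SD,
#' \eqn{\exp(\theta^*)}.
#'
#' @param r2_exposure,n_total,case_fraction,alpha As in
#'   \code{powerBinaryOutcome()}; \code{r2_exposure} must be positive
#'   here.
#' @param target_power Desired power in (\code{alpha}, 1), default 0.8.
#' @return The detectable OR per SD (> 1 by convention).
#' @export
detectableOR <- function(r2_exposure, n_total, case_fraction,
                         target_power = 0.8, alpha = 0.05) {
  stopifnot(r2_exposure > 0, target_power > alpha, target_power < 1)
  f <- function(th)
    powerBinaryOutcome(r2_exposure, n_total, case_fraction, th, alpha) -
    target_power
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  exp(stats::uniroot(f, c(0, upper), tol = 1e-12)$root)
}
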