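# Sensitivity analyses: leave-one-out driver-SNP detection and
# cross-method concordance.

.ESTIMATOR_FUNS <- list(
  ivw_fe = function(insts, opts)
    ivwFE(insts, se_order = opts$se_order),
  mle = function(insts, opts)
    maxLikelihood(insts),
  weighted_median = function(insts, opts)
    weightedMedian(insts, n_boot = opts$n_boot, seed = opts$seed,
                   se_order = opts$se_order),
  weighted_mode = function(insts, opts)
    weightedMode(insts, phi = opts$phi, n_boot = opts$n_boot,
                 seed = opts$seed, se_order = opts$se_order)
)

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each instrument excluded in turn
#' and flags SNPs whose removal flips a significant full-set association
#' (p below \code{alpha}) to non-significance. Flips are split in two
#' disjoint classes: \emph{drivers}, where the excluded-set p-value
#' clears \code{alpha + near_window} — the association rested on that
#' single variant — and \emph{near-drivers}, where it lands only just
#' above the level, in [\code{alpha}, \code{alpha + near_window}), the
#' borderline pattern that deserves reporting but not outright
#' dismissal. Defaults to the IVW-FE estimator; bootstrap-based
#' estimators are deterministic given their seed.
#'
#' @param insts A \code{\linkS4class{HarmonizedInstruments}} with at
#'   least two kept instruments.
#' @param method One of \code{ivw_fe} (default), \code{mle},
#'   \code{weighted_median}, \code{weighted_mode}. Methods with minimum
#'   instrument counts above n-1 are an error.
#' @param alpha Significance level of the driver rule (default 0.05).
#' @param near_window Width of the near-driver band above \code{alpha}
#'   (default 0.01).
#' @param se_order,n_boot,seed,phi Estimator options forwarded to the
#'   selected method.
#' @return A \code{\linkS4class{LeaveOneOutReport}}.
#' @export
leaveOneOut <- function(insts, method = "ivw_fe", alpha = 0.05,
                        near_window = 0.01, se_order = "first",
                        n_boot = 1000L, seed = 1L, phi = 1) {
  d <- .inst_data(insts)
  if (nrow(d) < 2L)
    stop("leave-one-out needs at least two instruments")
  if (!method %in% names(.ESTIMATOR_FUNS))
    stop("unknown method: ", method)
  stopifnot(alpha > 0, alpha < 1, near_window >= 0)
  opts <- list(se_order = se_order, n_boot = n_boot, seed = seed,
               phi = phi)
  fit <- .ESTIMATOR_FUNS[[method]]
  full <- fit(d, opts)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    e <- fit(d[-i, , drop = FALSE], opts)
    data.frame(snp_id = d$snp_id[i], theta = theta(e), se = stdErr(e),
               or_sd = orSD(e), ci_low = confInt(e)[["low"]],
               ci_high = confInt(e)[["high"]], pvalue = pvalue(e),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  drivers <- character()
  near <- character()
  if (pvalue(full) < alpha) {
    flips <- per$pvalue >= alpha
    near <- per$snp_id[flips & per$pvalue < alpha + near_window]
    drivers <- per$snp_id[flips & per$pvalue >= alpha + near_window]
  }
  methods::new("LeaveOneOutReport", fullEstimate = full,
               perExclusion = per, driverSnps = drivers,
               nearDriverSnps = near, alpha = alpha,
               nearWindow = near_window)
}

#' Cross-method concordance of causal estimates
#'
#' An association is considered stable when the four multi-SNP
#' estimators — IVW-FE, MLE, weighted median and weighted mode — agree in
#' effect direction and all reach p below \code{alpha}. The flag is a
#' pure function of the supplied estimates.
#'
#' @param estimates Named list of \code{\linkS4class{MREstimate}}
#'   objects; names must include \code{ivw_fe}, \code{mle},
#'   \code{weighted_median}, \code{weighted_mode}. A missing method is an
#'   error naming it.
#' @param alpha Significance level (default 0.05).
#' @return A \code{\linkS4class{ConcordanceReport}}.
#' @export
concordance <- function(estimates, alpha = 0.05) {
  required <- c("ivw_fe", "mle", "weighted_median", "weighted_mode")
  missing <- setdiff(required, names(estimates))
  if (length(missing))
    stop("missing estimate(s) for method(s): ",
         paste(missing, collapse = ", "))
  est <- estimates[required]
  stopifnot(all(vapply(est, methods::is, logical(1), "MREstimate")))
  thetas <- vapply(est, theta, numeric(1))
  ps <- vapply(est, pvalue, numeric(1))
  consistent <- (all(thetas > 0) || all(thetas < 0)) && all(ps < alpha)
  methods::new("ConcordanceReport", estimates = est,
               consistent = consistent, alpha = alpha)
}
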