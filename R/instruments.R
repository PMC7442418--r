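# Instrument selection: significance filtering, greedy LD clumping and
# F-statistic screening.

#' Filter associations at a significance threshold
#'
#' Retains exactly the variants with p-value at or below the threshold
#' (boundary inclusive), preserving input order. The conventional
#' genome-wide threshold 5e-8 is the default.
#'
#' @param assocs A \code{\linkS4class{GwasSummaryStats}}.
#' @param p_threshold Inclusion threshold in (0, 1).
#' @return A \code{\linkS4class{GwasSummaryStats}} with the surviving
#'   rows; an empty result triggers a warning (downstream estimators
#'   refuse empty sets).
#' @export
filterSignificant <- function(assocs, p_threshold = 5e-8) {
  stopifnot(methods::is(assocs, "GwasSummaryStats"),
            p_threshold > 0, p_threshold < 1)
  v <- assocs@variants
  keep <- v$pvalue <= p_threshold
  if (!any(keep))
    warning("no variants pass p <= ", format(p_threshold), " for trait '",
            assocs@trait, "'")
  GwasSummaryStats(v[keep, , drop = FALSE], trait = assocs@trait)
}

# total ordering used by the clumping ranking: |beta| desc, p asc, id asc
.clump_order <- function(v) order(-abs(v$beta), v$pvalue, v$snp_id)

#' Greedy LD clumping
#'
#' Prunes correlated variants so the retained set is approximately
#' independent: variants are ranked by absolute effect size (ties broken
#' by smaller p-value, then lexicographic SNP id), and the procedure
#' repeatedly accepts the top-ranked remaining variant and discards every
#' remaining variant with squared correlation at or above
#' \code{r2_threshold} against it. The accepted set is therefore pairwise
#' below threshold and, because the ranking is total, independent of
#' input order.
#'
#' @param assocs A \code{\linkS4class{GwasSummaryStats}}.
#' @param ld An \code{\linkS4class{LDMatrix}} covering every variant in
#'   \code{assocs}; a variant without LD information is an error, never
#'   assumed independent.
#' @param r2_threshold Exclusion threshold in (0, 1]; default 0.01.
#' @return A \code{\linkS4class{GwasSummaryStats}} of retained variants,
#'   in input order.
#' @export
ldClump <- function(assocs, ld, r2_threshold = 0.01) {
  stopifnot(methods::is(assocs, "GwasSummaryStats"),
            methods::is(ld, "LDMatrix"),
            r2_threshold > 0, r2_threshold <= 1)
  v <- assocs@variants
  if (!nrow(v)) return(assocs)
  absent <- setdiff(v$snp_id, ld@snpIds)
  if (length(absent))
    stop("variant(s) missing from the LD matrix: ",
         paste(absent, collapse = ", "))
  r2 <- ld@r2[v$snp_id, v$snp_id, drop = FALSE]
  ranking <- .clump_order(v)
  alive <- rep(TRUE, nrow(v))
  accepted <- logical(nrow(v))
  for (i in ranking) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    alive[i] <- FALSE
    conflict <- alive & r2[i, ] >= r2_threshold
    alive[conflict] <- FALSE
  }
  GwasSummaryStats(v[accepted, , drop = FALSE], trait = assocs@trait)
}

#' Per-variant F-statistic
#'
#' Instrument-strength measure \eqn{F = (\beta / se)^2}; the conventional
#' weak-instrument screen is F > 10.
#'
#' @param beta,se Per-allele effect and positive standard error
#'   (vectorized).
#' @return Numeric vector of F-statistics.
#' @export
fStatistic <- function(beta, se) {
  stopifnot(all(is.finite(se) & se > 0))
  (beta / se)^2
}

#' Instrument-strength summary for a harmonized set
#'
#' Computes the per-SNP F-statistics from the exposure effects of the
#' kept instruments, their mean, and a weak-instrument flag raised when
#' the mean is at or below 10.
#'
#' @param instruments A \code{\linkS4class{HarmonizedInstruments}}.
#' @return A list with \code{per_snp} (named numeric vector),
#'   \code{mean_f} and \code{weak_instruments} (logical).
#' @export
setFStatistics <- function(instruments) {
  stopifnot(methods::is(instruments, "HarmonizedInstruments"))
  d <- keptInstruments(instruments)
  if (!nrow(d)) stop("no kept instruments to screen")
  f <- fStatistic(d$beta_exposure, d$se_exposure)
  names(f) <- d$snp_id
  list(per_snp = f, mean_f = mean(f), weak_instruments = mean(f) <= 10)
}

#' Build a screened instrument set for one exposure/outcome pair
#'
#' Convenience wrapper chaining the selection pipeline: significance
#' filtering of the exposure associations, optional greedy LD clumping,
#' harmonization against the outcome, and F-statistic screening. The
#' thresholds and the strength summary are attached as attributes of the
#' returned object's data.
#'
#' @param exposure,outcome \code{\linkS4class{GwasSummaryStats}} objects.
#' @param ld Optional \code{\linkS4class{LDMatrix}} (clumping is skipped
#'   when \code{NULL}; supply one whenever instruments may be correlated).
#' @param p_threshold,r2_threshold Selection thresholds.
#' @param palindrome_policy,eaf_window Passed to \code{harmonize()}.
#' @return A \code{\linkS4class{HarmonizedInstruments}}; its
#'   \code{instrumentData()} carries attributes \code{p_threshold},
#'   \code{r2_threshold} and \code{f_statistics}.
#' @export
buildInstrumentSet <- function(exposure, outcome, ld = NULL,
                               p_threshold = 5e-8, r2_threshold = 0.01,
                               palindrome_policy = "drop",
                               eaf_window = 0.08) {
  sel <- filterSignificant(exposure, p_threshold)
  if (!is.null(ld) && nSnps(sel) > 0)
    sel <- ldClump(sel, ld, r2_threshold)
  if (nSnps(sel) == 0)
    stop("no instruments survive selection for trait '", exposure@trait,
         "'")
  h <- harmonize(sel, outcome, palindrome_policy = palindrome_policy,
                 eaf_window = eaf_window)
  attr(h@data, "p_threshold") <- p_threshold
  attr(h@data, "r2_threshold") <- if (is.null(ld)) NA_real_ else
    r2_threshold
  attr(h@data, "f_statistics") <- if (nSnps(h) > 0) setFStatistics(h)
  h
}
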