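# Accessor methods for the S4 classes; users never touch slots directly.

#' @rdname accessors
setMethod("theta", "MREstimate", function(x) x@theta)

#' @rdname accessors
setMethod("stdErr", "MREstimate", function(x) x@se)

#' @rdname accessors
setMethod("orSD", "MREstimate", function(x) x@orSD)

#' @rdname accessors
setMethod("confInt", "MREstimate",
          function(x) c(low = x@ciLow, high = x@ciHigh))

#' @rdname accessors
setMethod("pvalue", "MREstimate", function(x) x@pvalue)

#' @rdname accessors
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' @rdname accessors
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @rdname accessors
setMethod("trait", "GwasSummaryStats", function(x) x@trait)

#' @rdname accessors
setMethod("variants", "GwasSummaryStats", function(x) x@variants)

#' @rdname accessors
setMethod("nSnps", "GwasSummaryStats", function(x) nrow(x@variants))

#' @rdname accessors
setMethod("instrumentData", "HarmonizedInstruments", function(x) x@data)

#' @rdname accessors
setMethod("keptInstruments", "HarmonizedInstruments", function(x) {
  d <- x@data[x@data$orientation_action %in% .KEPT_ACTIONS, , drop = FALSE]
  rownames(d) <- NULL
  d
})

#' @rdname accessors
setMethod("nSnps", "HarmonizedInstruments",
          function(x) sum(x@data$orientation_action %in% .KEPT_ACTIONS))

#' @rdname accessors
setMethod("snpIds", "LDMatrix", function(x) x@snpIds)

#' @rdname accessors
setMethod("r2Matrix", "LDMatrix", function(x) x@r2)

#' @rdname accessors
setMethod("driverSnps", "LeaveOneOutReport", function(x) x@driverSnps)

#' @rdname accessors
setMethod("perExclusion", "LeaveOneOutReport", function(x) x@perExclusion)

#' @rdname accessors
setMethod("fullEstimate", "LeaveOneOutReport", function(x) x@fullEstimate)

#' Near-driver SNPs of a leave-one-out report
#'
#' SNPs whose exclusion moves the p-value just above the significance
#' level, into [alpha, alpha + nearWindow).
#' @param x A \code{\linkS4class{LeaveOneOutReport}}.
#' @return Character vector of SNP ids.
#' @export
nearDriverSnps <- function(x) {
  stopifnot(methods::is(x, "LeaveOneOutReport"))
  x@nearDriverSnps
}

#' Intercept summary of an MR-Egger fit
#'
#' @param x An \code{\linkS4class{EggerResult}}.
#' @return Named numeric vector with \code{intercept}, \code{se},
#'   \code{pvalue}.
#' @export
eggerIntercept <- function(x) {
  stopifnot(methods::is(x, "EggerResult"))
  c(intercept = x@intercept, se = x@interceptSE,
    pvalue = x@interceptPvalue)
}

#' Slope estimate of an MR-Egger fit
#' @param x An \code{\linkS4class{EggerResult}}.
#' @return The slope \code{\linkS4class{MREstimate}}.
#' @export
eggerSlope <- function(x) {
  stopifnot(methods::is(x, "EggerResult"))
  x@slope
}

#' Tabulate one or more MR estimates
#'
#' Flattens \code{MREstimate} objects into the tidy one-row-per-method
#' table used by the report writers.
#'
#' @param estimates An \code{MREstimate} or a (optionally named) list of
#'   them.
#' @param exposure,outcome Labels to attach to every row.
#' @return A \code{data.frame} with columns \code{exposure},
#'   \code{outcome}, \code{method}, \code{theta}, \code{se}, \code{or_sd},
#'   \code{ci_low}, \code{ci_high}, \code{pvalue}, \code{n_snps}.
#' @export
estimatesTable <- function(estimates, exposure = "exposure",
                           outcome = "outcome") {
  if (methods::is(estimates, "MREstimate")) estimates <- list(estimates)
  stopifnot(all(vapply(estimates, methods::is, logical(1), "MREstimate")))
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e@method,
               theta = e@theta, se = e@se, or_sd = e@orSD,
               ci_low = e@ciLow, ci_high = e@ciHigh, pvalue = e@pvalue,
               n_snps = e@nSnps, stringsAsFactors = FALSE)
  }))
}
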