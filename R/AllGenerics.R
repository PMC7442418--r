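#' Accessor generics
#'
#' Small family of accessor generics used across the result classes:
#' \code{theta()} returns the causal log odds ratio per SD of exposure,
#' \code{stdErr()} its standard error, \code{orSD()} the odds ratio per SD,
#' \code{confInt()} the 95\% (or configured) confidence interval on the OR
#' scale, \code{pvalue()} the two-sided normal p-value, \code{nSnps()} the
#' number of instruments used, and \code{mrMethod()} the estimator label.
#'
#' @param x An object of one of the package's S4 classes.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
#' @aliases theta stdErr orSD confInt pvalue nSnps mrMethod
#' @examples
#' est <- ivwFE(HarmonizedInstruments(
#'   snp_id = c("rs1", "rs2", "rs3"),
#'   beta_exposure = c(0.1, 0.12, 0.09), se_exposure = rep(0.01, 3),
#'   beta_outcome = c(0.02, 0.03, 0.018), se_outcome = rep(0.01, 3)))
#' theta(est); orSD(est); pvalue(est)
NULL

#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname accessors
#' @export
setGeneric("stdErr", function(x) standardGeneric("stdErr"))

#' @rdname accessors
#' @export
setGeneric("orSD", function(x) standardGeneric("orSD"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("instrumentData", function(x) standardGeneric("instrumentData"))

#' @rdname accessors
#' @export
setGeneric("keptInstruments", function(x) standardGeneric("keptInstruments"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("r2Matrix", function(x) standardGeneric("r2Matrix"))

#' @rdname accessors
#' @export
setGeneric("driverSnps", function(x) standardGeneric("driverSnps"))

#' @rdname accessors
#' @export
setGeneric("perExclusion", function(x) standardGeneric("perExclusion"))

#' @rdname accessors
#' @export
setGeneric("fullEstimate", function(x) standardGeneric("fullEstimate"))
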