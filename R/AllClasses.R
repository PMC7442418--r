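# Central S4 classes: summary statistics, harmonized instruments, estimates,
# sensitivity reports and simulation configuration.

.VALID_ACTIONS <- c("unchanged", "flipped", "dropped_palindromic",
                    "dropped_incompatible")
.KEPT_ACTIONS <- c("unchanged", "flipped")
.MR_METHODS <- c("wald", "ivw_fe", "mle", "weighted_median", "weighted_mode",
                 "egger_slope")

.SUMMARY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

.check_alleles <- function(a) a %in% c("A", "C", "G", "T")

#' GWAS summary statistics for one trait
#'
#' Per-variant association summary statistics: one row per SNP with its
#' identifier, position, allele pair, effect-allele frequency, per-allele
#' effect (SD units of the trait for a continuous exposure, log-odds for a
#' binary outcome), standard error, two-sided p-value and sample size.
#'
#' @slot trait Character label of the trait the statistics refer to.
#' @slot variants A \code{data.frame} with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pvalue}, \code{n}.
#'
#' @export
setClass("GwasSummaryStats",
         representation(trait = "character", variants = "data.frame"))

setValidity("GwasSummaryStats", function(object) {
  v <- object@variants
  msgs <- character()
  missing <- setdiff(.SUMMARY_COLS, names(v))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(v)) {
    if (anyDuplicated(v$snp_id))
      msgs <- c(msgs, "duplicated snp_id values")
    if (!all(.check_alleles(v$effect_allele)) ||
        !all(.check_alleles(v$other_allele)))
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    if (any(v$effect_allele == v$other_allele))
      msgs <- c(msgs, "effect and other allele must differ")
    if (any(!is.finite(v$se) | v$se <= 0))
      msgs <- c(msgs, "se must be positive and finite")
    if (any(v$pvalue <= 0 | v$pvalue > 1, na.rm = TRUE))
      msgs <- c(msgs, "pvalue must lie in (0, 1]")
    if (any(v$eaf < 0 | v$eaf > 1, na.rm = TRUE))
      msgs <- c(msgs, "eaf must lie in [0, 1]")
    if (any(v$pos < 0, na.rm = TRUE))
      msgs <- c(msgs, "pos must be non-negative")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GwasSummaryStats object
#'
#' @param variants Data frame of per-variant statistics (see class slots);
#'   missing optional columns (\code{chrom}, \code{pos}, \code{eaf},
#'   \code{n}) are filled with \code{NA}.
#' @param trait Trait label.
#' @return A \code{\linkS4class{GwasSummaryStats}} object.
#' @export
GwasSummaryStats <- function(variants, trait = "trait") {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "n"))
    if (is.null(variants[[col]]))
      variants[[col]] <- if (col == "chrom") NA_character_ else NA_real_
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  variants$snp_id <- as.character(variants$snp_id)
  variants$chrom <- as.character(variants$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    variants[[col]] <- as.numeric(variants[[col]])
  variants <- variants[, .SUMMARY_COLS, drop = FALSE]
  rownames(variants) <- NULL
  methods::new("GwasSummaryStats", trait = trait, variants = variants)
}

#' Harmonized exposure/outcome instruments
#'
#' Exposure and outcome summary effects for a set of SNPs expressed on a
#' common effect-allele orientation, together with the harmonization action
#' taken per SNP. Rows with action \code{unchanged} or \code{flipped} enter
#' estimation; rows with a \code{dropped_*} action are retained for audit
#' but excluded by \code{keptInstruments()}.
#'
#' @slot exposure,outcome Trait labels.
#' @slot data A \code{data.frame} with columns \code{snp_id},
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}, \code{eaf}, \code{orientation_action}.
#' @slot missingInOutcome SNP ids present in the exposure but absent from
#'   the outcome statistics (reported, never silently lost).
#'
#' @export
setClass("HarmonizedInstruments",
         representation(exposure = "character", outcome = "character",
                        data = "data.frame",
                        missingInOutcome = "character"))

setValidity("HarmonizedInstruments", function(object) {
  d <- object@data
  req <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
           "se_outcome", "eaf", "orientation_action")
  missing <- setdiff(req, names(d))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (!all(d$orientation_action %in% .VALID_ACTIONS))
    return("invalid orientation_action value")
  kept <- d[d$orientation_action %in% .KEPT_ACTIONS, , drop = FALSE]
  if (nrow(kept)) {
    if (any(!is.finite(kept$se_exposure) | kept$se_exposure <= 0) ||
        any(!is.finite(kept$se_outcome) | kept$se_outcome <= 0))
      return("kept instruments must have positive finite standard errors")
  }
  TRUE
})

#' Construct a HarmonizedInstruments object from vectors
#'
#' Convenience constructor used when the per-SNP effects are already on a
#' shared orientation (e.g. simulated data); \code{harmonize()} builds the
#' same object from two \code{GwasSummaryStats}.
#'
#' @param snp_id Character vector of SNP identifiers.
#' @param beta_exposure,se_exposure Per-allele exposure effect (SD units)
#'   and its standard error.
#' @param beta_outcome,se_outcome Per-allele outcome effect (log-odds) and
#'   its standard error.
#' @param eaf Effect-allele frequency (optional).
#' @param orientation_action Per-SNP harmonization action; defaults to
#'   \code{"unchanged"}.
#' @param exposure,outcome Trait labels.
#' @param missingInOutcome SNP ids dropped because the outcome lacked them.
#' @return A \code{\linkS4class{HarmonizedInstruments}} object.
#' @export
HarmonizedInstruments <- function(snp_id, beta_exposure, se_exposure,
                                  beta_outcome, se_outcome,
                                  eaf = NA_real_,
                                  orientation_action = "unchanged",
                                  exposure = "exposure",
                                  outcome = "outcome",
                                  missingInOutcome = character()) {
  d <- data.frame(snp_id = as.character(snp_id),
                  beta_exposure = as.numeric(beta_exposure),
                  se_exposure = as.numeric(se_exposure),
                  beta_outcome = as.numeric(beta_outcome),
                  se_outcome = as.numeric(se_outcome),
                  eaf = as.numeric(eaf),
                  orientation_action = as.character(orientation_action),
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  methods::new("HarmonizedInstruments", exposure = exposure,
               outcome = outcome, data = d,
               missingInOutcome = missingInOutcome)
}

#' Linkage-disequilibrium matrix
#'
#' Squared-correlation (\eqn{r^2}) matrix between variants, used by
#' \code{ldClump()}. Symmetric with a unit diagonal and values in [0, 1].
#'
#' @slot snpIds SNP identifiers, in matrix order.
#' @slot r2 Numeric matrix of squared correlations.
#' @export
setClass("LDMatrix", representation(snpIds = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != length(object@snpIds) || ncol(m) != length(object@snpIds))
    return("r2 dimensions must match snpIds length")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    return("r2 values must lie in [0, 1]")
  if (any(abs(diag(m) - 1) > 1e-12))
    return("r2 diagonal must be exactly 1")
  if (max(abs(m - t(m))) > 1e-8)
    return("r2 must be symmetric")
  TRUE
})

#' Construct an LDMatrix
#' @param snp_ids SNP identifiers in matrix order.
#' @param r2 Symmetric matrix of squared correlations with unit diagonal.
#' @return An \code{\linkS4class{LDMatrix}} object.
#' @export
LDMatrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(snp_ids, snp_ids)
  methods::new("LDMatrix", snpIds = as.character(snp_ids), r2 = r2)
}

#' A single causal-effect estimate
#'
#' The result of one estimator: log odds ratio of the outcome per SD unit
#' increase in the genetically predicted exposure (\code{theta}), its
#' standard error, the odds-ratio transform with confidence interval, a
#' two-sided normal p-value, and the number of SNPs used.
#'
#' @slot method One of \code{wald}, \code{ivw_fe}, \code{mle},
#'   \code{weighted_median}, \code{weighted_mode}, \code{egger_slope}.
#' @slot theta,se Log-scale effect and standard error.
#' @slot orSD,ciLow,ciHigh Odds ratio per SD and its confidence bounds.
#' @slot pvalue Two-sided normal p-value.
#' @slot nSnps Number of instruments.
#' @slot level Confidence level used for the interval.
#' @export
setClass("MREstimate",
         representation(method = "character", theta = "numeric",
                        se = "numeric", orSD = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", pvalue = "numeric",
                        nSnps = "integer", level = "numeric"))

setValidity("MREstimate", function(object) {
  if (!object@method %in% .MR_METHODS)
    return(paste("unknown method:", object@method))
  if (!is.finite(object@se) || object@se <= 0)
    return("se must be positive")
  if (object@nSnps < 1L) return("nSnps must be positive")
  if (abs(object@orSD - exp(object@theta)) >
      1e-12 * max(1, abs(object@orSD)))
    return("orSD must equal exp(theta)")
  if (!(object@ciLow < object@orSD && object@orSD < object@ciHigh))
    return("confidence bounds must bracket orSD")
  p <- 2 * stats::pnorm(-abs(object@theta / object@se))
  if (abs(object@pvalue - p) > 1e-12)
    return("pvalue must equal 2*pnorm(-|theta/se|)")
  TRUE
})

# internal constructor: derives OR scale fields from (theta, se)
.mr_estimate <- function(method, theta, se, n_snps, level = 0.95) {
  sc <- toORScale(theta, se, level)
  methods::new("MREstimate", method = method, theta = theta, se = se,
               orSD = sc[["or_sd"]], ciLow = sc[["ci_low"]],
               ciHigh = sc[["ci_high"]], pvalue = sc[["pvalue"]],
               nSnps = as.integer(n_snps), level = level)
}

#' MR-Egger regression result
#'
#' Slope (causal effect, as an \code{MREstimate}) plus the intercept, whose
#' deviation from zero measures directional horizontal pleiotropy.
#'
#' @slot slope \code{\linkS4class{MREstimate}} with method
#'   \code{egger_slope}.
#' @slot intercept,interceptSE Intercept (log-odds units) and its SE.
#' @slot interceptPvalue Two-sided normal p-value for the intercept.
#' @export
setClass("EggerResult",
         representation(slope = "MREstimate", intercept = "numeric",
                        interceptSE = "numeric", interceptPvalue = "numeric"))

setValidity("EggerResult", function(object) {
  if (!is.finite(object@interceptSE) || object@interceptSE <= 0)
    return("interceptSE must be positive")
  p <- 2 * stats::pnorm(-abs(object@intercept / object@interceptSE))
  if (abs(object@interceptPvalue - p) > 1e-12)
    return("interceptPvalue must equal 2*pnorm(-|intercept/interceptSE|)")
  TRUE
})

#' Leave-one-out sensitivity report
#'
#' Re-estimates of the causal effect with each SNP excluded in turn, plus
#' the instruments whose removal flips the association from significant
#' (full-set p below \code{alpha}) to non-significant. Drastic flips
#' (excluded-set p at or above \code{alpha + nearWindow}) are drivers;
#' borderline flips (p in [\code{alpha}, \code{alpha + nearWindow})) are
#' near-drivers. The two lists are disjoint.
#'
#' @slot fullEstimate Estimate on the full instrument set.
#' @slot perExclusion Data frame with one row per excluded SNP.
#' @slot driverSnps,nearDriverSnps Character vectors of flagged SNPs.
#' @slot alpha,nearWindow Significance level of the driver rule and the
#'   width of the near-driver band.
#' @export
setClass("LeaveOneOutReport",
         representation(fullEstimate = "MREstimate",
                        perExclusion = "data.frame",
                        driverSnps = "character",
                        nearDriverSnps = "character",
                        alpha = "numeric", nearWindow = "numeric"))

setValidity("LeaveOneOutReport", function(object) {
  if (!all(object@driverSnps %in% object@perExclusion$snp_id))
    return("driverSnps must be excluded snp_ids")
  if (nrow(object@perExclusion) != object@fullEstimate@nSnps)
    return("perExclusion must have one row per instrument")
  TRUE
})

#' Cross-method concordance report
#'
#' Records whether the four multi-SNP estimators (IVW-FE, MLE, weighted
#' median, weighted mode) agree: same effect direction and all p-values
#' below \code{alpha}.
#'
#' @slot estimates Named list of \code{MREstimate} objects.
#' @slot consistent Logical concordance flag.
#' @slot alpha Significance level of the rule.
#' @export
setClass("ConcordanceReport",
         representation(estimates = "list", consistent = "logical",
                        alpha = "numeric"))

#' Configuration of the synthetic summary-statistic generator
#'
#' Generative parameters for a two-sample MR study with known truth: SNP
#' count, true causal effect (log OR per SD), distribution of SNP-exposure
#' effects, GWAS sample sizes, case fraction of the outcome study, invalid
#' instrument fraction and pleiotropy model, an optional injected outlier,
#' the minor-allele-frequency range and the seed.
#'
#' @slot nSnps Number of instruments.
#' @slot thetaTrue True causal log OR per SD.
#' @slot gammaMean,gammaSD Mean and SD of true SNP-exposure effects (SD
#'   units per allele).
#' @slot nExposure,nOutcome Sample sizes of the two GWAS.
#' @slot caseFraction Case fraction of the outcome study.
#' @slot invalidFraction Fraction of instruments given pleiotropic effects.
#' @slot pleiotropy \code{"none"}, \code{"balanced"} or
#'   \code{"directional"}.
#' @slot pleiotropyScale Magnitude parameter of the pleiotropy model
#'   (log-odds units).
#' @slot outlierIndex,outlierEffect Optional injected driver SNP: index and
#'   additive log-odds shift of its outcome effect (NA disables).
#' @slot mafLow,mafHigh Uniform range of minor allele frequencies.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
         representation(nSnps = "integer", thetaTrue = "numeric",
                        gammaMean = "numeric", gammaSD = "numeric",
                        nExposure = "integer", nOutcome = "integer",
                        caseFraction = "numeric",
                        invalidFraction = "numeric",
                        pleiotropy = "character",
                        pleiotropyScale = "numeric",
                        outlierIndex = "integer",
                        outlierEffect = "numeric",
                        mafLow = "numeric", mafHigh = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (object@gammaSD < 0) msgs <- c(msgs, "gammaSD must be >= 0")
  if (object@nExposure < 1L || object@nOutcome < 1L)
    msgs <- c(msgs, "sample sizes must be positive")
  if (object@caseFraction <= 0 || object@caseFraction >= 1)
    msgs <- c(msgs, "caseFraction must lie in (0, 1)")
  if (object@invalidFraction < 0 || object@invalidFraction >= 1)
    msgs <- c(msgs, "invalidFraction must lie in [0, 1)")
  if (!object@pleiotropy %in% c("none", "balanced", "directional"))
    msgs <- c(msgs, "pleiotropy must be none/balanced/directional")
  if (object@pleiotropy != "none" && object@pleiotropyScale <= 0)
    msgs <- c(msgs, "pleiotropyScale must be > 0 under a pleiotropy model")
  if (!is.na(object@outlierIndex) &&
      (object@outlierIndex < 1L || object@outlierIndex > object@nSnps))
    msgs <- c(msgs, "outlierIndex out of range")
  if (object@mafLow <= 0 || object@mafHigh > 0.5 ||
      object@mafLow > object@mafHigh)
    msgs <- c(msgs, "maf range must satisfy 0 < low <= high <= 0.5")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate a well-powered modern setting: 30 independent
#' instruments discovered in an exposure GWAS of 100,000 individuals, an
#' outcome case-control study of 30,657 with case fraction 0.407 (12,488
#' cases, 18,169 controls), SNP-exposure effects of mean 0.07 SD per
#' allele with a wide spread (SD 0.045, matching the heavy spread of
#' per-variant effect sizes in real instrument sets), and minor allele
#' frequencies uniform on [0.1, 0.5].
#'
#' @param n_snps,theta_true,gamma_mean,gamma_sd,n_exposure,n_outcome
#'   Generative parameters; see the class slots.
#' @param case_fraction,invalid_fraction,pleiotropy,pleiotropy_scale,outlier
#'   Further parameters; \code{outlier} is \code{NULL} or
#'   \code{list(index=, effect=)}.
#' @param maf_range Length-2 numeric, uniform MAF range.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A validated \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(n_snps = 30L, theta_true = 0,
                             gamma_mean = 0.07, gamma_sd = 0.045,
                             n_exposure = 100000L, n_outcome = 30657L,
                             case_fraction = 12488 / 30657,
                             invalid_fraction = 0,
                             pleiotropy = c("none", "balanced",
                                            "directional"),
                             pleiotropy_scale = 0.05,
                             outlier = NULL,
                             maf_range = c(0.1, 0.5), seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  oi <- if (is.null(outlier)) NA_integer_ else as.integer(outlier$index)
  oe <- if (is.null(outlier)) NA_real_ else as.numeric(outlier$effect)
  methods::new("SimulationConfig", nSnps = as.integer(n_snps),
               thetaTrue = as.numeric(theta_true),
               gammaMean = as.numeric(gamma_mean),
               gammaSD = as.numeric(gamma_sd),
               nExposure = as.integer(n_exposure),
               nOutcome = as.integer(n_outcome),
               caseFraction = as.numeric(case_fraction),
               invalidFraction = as.numeric(invalid_fraction),
               pleiotropy = pleiotropy,
               pleiotropyScale = as.numeric(pleiotropy_scale),
               outlierIndex = oi, outlierEffect = oe,
               mafLow = maf_range[1], mafHigh = maf_range[2],
               seed = as.integer(seed))
}

# ---- show methods -------------------------------------------------------

setMethod("show", "GwasSummaryStats", function(object) {
  cat("GwasSummaryStats:", object@trait, "—", nrow(object@variants),
      "variants\n")
  if (nrow(object@variants))
    print(utils::head(object@variants, 5))
})

setMethod("show", "HarmonizedInstruments", function(object) {
  d <- object@data
  kept <- sum(d$orientation_action %in% .KEPT_ACTIONS)
  cat(sprintf("HarmonizedInstruments: %s ~ %s (%d kept / %d records",
              object@exposure, object@outcome, kept, nrow(d)))
  if (length(object@missingInOutcome))
    cat(sprintf(", %d absent from outcome", length(object@missingInOutcome)))
  cat(")\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf(
    "MREstimate [%s]: OR_SD = %.3f (%.0f%% CI %.3f-%.3f), p = %.3g, %d SNP%s\n",
    object@method, object@orSD, 100 * object@level, object@ciLow,
    object@ciHigh, object@pvalue, object@nSnps,
    if (object@nSnps == 1L) "" else "s"))
})

setMethod("show", "EggerResult", function(object) {
  show(object@slope)
  cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
              object@intercept, object@interceptSE, object@interceptPvalue))
})

setMethod("show", "LeaveOneOutReport", function(object) {
  cat("LeaveOneOutReport on", object@fullEstimate@nSnps, "instruments\n")
  cat("  full: "); show(object@fullEstimate)
  cat(sprintf("  drivers: %s\n",
              if (length(object@driverSnps))
                paste(object@driverSnps, collapse = ", ") else "none"))
  if (length(object@nearDriverSnps))
    cat(sprintf("  near-drivers: %s\n",
                paste(object@nearDriverSnps, collapse = ", ")))
})

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf("ConcordanceReport: %s (alpha = %g)\n",
              if (object@consistent) "consistent" else "not consistent",
              object@alpha))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d SNPs, theta = %g, pleiotropy = %s (%.0f%% invalid), seed %d\n",
    object@nSnps, object@thetaTrue, object@pleiotropy,
    100 * object@invalidFraction, object@seed))
})
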