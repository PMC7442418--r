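# Synthetic two-sample GWAS summary statistics with known causal
# structure: the test harness for every stage of the pipeline.

# non-palindromic allele pairs assigned to simulated variants
.ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"),
                       c("C", "A"), c("T", "G"), c("T", "C"),
                       c("G", "T"), c("C", "T"))

#' Simulate a two-sample summary-statistic pair
#'
#' Generates exposure and outcome GWAS summary statistics for
#' \code{nSnps} independent variants under a known causal effect. Per
#' SNP j: MAF ~ Uniform(low, high); true SNP-exposure effect
#' \eqn{\gamma_j} ~ Normal(gammaMean, gammaSD); pleiotropic effect
#' \eqn{\alpha_j = 0} for valid instruments and, for the invalid
#' fraction, drawn Normal(0, scale) under the balanced model or
#' Normal(scale, scale/4) under the directional model (a concentrated
#' same-direction cluster, e.g. invalid instruments acting through one
#' shared confounding pathway); true outcome
#' effect \eqn{\theta \gamma_j + \alpha_j}. Observed effects are normal
#' around the truths with the standard GWAS standard errors
#' \eqn{se_x = 1/\sqrt{2 f (1-f) n_x}} and
#' \eqn{se_y = 1/\sqrt{2 f (1-f) n_y \phi (1-\phi)}} (\eqn{f} the MAF,
#' \eqn{\phi} the case fraction); p-values are two-sided normal. An
#' optional outlier is injected last by adding a fixed log-odds shift to
#' one SNP's true and observed outcome effect (the driver-SNP scenario).
#' Exposure and outcome noise are independent (non-overlapping samples)
#' and pleiotropic effects are drawn independently of \eqn{\gamma_j}
#' (the InSIDE assumption holds by construction). Fully reproducible
#' from the config seed; the caller's RNG state is left untouched.
#'
#' @param cfg A \code{\linkS4class{SimulationConfig}}.
#' @return A list with \code{exposure} and \code{outcome}
#'   (\code{\linkS4class{GwasSummaryStats}}) and \code{truth}, a data
#'   frame of every latent quantity (MAF, gamma, alpha, true outcome
#'   effect, validity flag, outlier flag) with the config echoed in
#'   \code{attr(truth, "config")}.
#' @export
simulatePair <- function(cfg) {
  stopifnot(methods::is(cfg, "SimulationConfig"))
  methods::validObject(cfg)
  n <- cfg@nSnps
  out <- .with_seed(cfg@seed, {
    maf <- stats::runif(n, cfg@mafLow, cfg@mafHigh)
    gamma <- stats::rnorm(n, cfg@gammaMean, cfg@gammaSD)
    n_invalid <- round(cfg@invalidFraction * n)
    invalid <- rep(FALSE, n)
    if (n_invalid > 0) invalid[sample.int(n, n_invalid)] <- TRUE
    alpha <- numeric(n)
    if (any(invalid)) {
      alpha[invalid] <- switch(
        cfg@pleiotropy,
        none = 0,
        balanced = stats::rnorm(sum(invalid), 0, cfg@pleiotropyScale),
        directional = stats::rnorm(sum(invalid), cfg@pleiotropyScale,
                                   cfg@pleiotropyScale / 4))
    }
    beta_out_true <- cfg@thetaTrue * gamma + alpha
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg@nExposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg@nOutcome *
                       cfg@caseFraction * (1 - cfg@caseFraction))
    bx <- stats::rnorm(n, gamma, se_x)
    by <- stats::rnorm(n, beta_out_true, se_y)
    is_outlier <- rep(FALSE, n)
    if (!is.na(cfg@outlierIndex)) {
      i <- cfg@outlierIndex
      beta_out_true[i] <- beta_out_true[i] + cfg@outlierEffect
      by[i] <- by[i] + cfg@outlierEffect
      is_outlier[i] <- TRUE
    }
    pair_idx <- sample.int(nrow(.ALLELE_PAIRS), n, replace = TRUE)
    list(maf = maf, gamma = gamma, invalid = invalid, alpha = alpha,
         beta_out_true = beta_out_true, se_x = se_x, se_y = se_y,
         bx = bx, by = by, is_outlier = is_outlier, pair_idx = pair_idx)
  })

  snp_id <- sprintf("rs%07d", seq_len(n))
  ea <- .ALLELE_PAIRS[out$pair_idx, 1]
  oa <- .ALLELE_PAIRS[out$pair_idx, 2]
  base <- data.frame(snp_id = snp_id,
                     chrom = as.character(1 + (seq_len(n) - 1) %% 22),
                     pos = 1e6 + 1e4 * seq_len(n),
                     effect_allele = ea, other_allele = oa,
                     eaf = out$maf, stringsAsFactors = FALSE)
  pv <- function(b, s) 2 * stats::pnorm(-abs(b / s))
  exposure <- GwasSummaryStats(
    cbind(base, data.frame(beta = out$bx, se = out$se_x,
                           pvalue = pmax(pv(out$bx, out$se_x),
                                         .Machine$double.xmin),
                           n = cfg@nExposure)),
    trait = "simulated_exposure")
  outcome <- GwasSummaryStats(
    cbind(base, data.frame(beta = out$by, se = out$se_y,
                           pvalue = pmax(pv(out$by, out$se_y),
                                         .Machine$double.xmin),
                           n = cfg@nOutcome)),
    trait = "simulated_outcome")
  truth <- data.frame(snp_id = snp_id, maf = out$maf,
                      gamma = out$gamma, alpha = out$alpha,
                      beta_outcome_true = out$beta_out_true,
                      invalid = out$invalid,
                      is_outlier = out$is_outlier,
                      stringsAsFactors = FALSE)
  attr(truth, "config") <- cfg
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Harmonized instruments straight from a simulated pair
#'
#' Simulated exposure and outcome tables share allele orientation by
#' construction, so this shortcut builds the
#' \code{\linkS4class{HarmonizedInstruments}} directly (identical to
#' running \code{harmonize()} on the pair).
#'
#' @param pair The list returned by \code{simulatePair()}.
#' @return A \code{\linkS4class{HarmonizedInstruments}}.
#' @export
simulatedInstruments <- function(pair) {
  ex <- variants(pair$exposure)
  ou <- variants(pair$outcome)
  HarmonizedInstruments(snp_id = ex$snp_id,
                        beta_exposure = ex$beta, se_exposure = ex$se,
                        beta_outcome = ou$beta, se_outcome = ou$se,
                        eaf = ex$eaf,
                        exposure = trait(pair$exposure),
                        outcome = trait(pair$outcome))
}

#' Documented simulation scenario presets
#'
#' Versioned parameter sets for the standard test scenarios:
#' \describe{
#'   \item{all_valid}{30 valid instruments, causal effect 0.2 — the
#'     clean parameter-recovery setting.}
#'   \item{balanced_40}{150 instruments, 40\% invalid with balanced
#'     (zero-mean) pleiotropy of scale 0.1 log-odds, causal effect
#'     0.2.}
#'   \item{directional_40}{150 instruments, 40\% invalid with
#'     directional pleiotropy (mean 0.1 log-odds), causal effect 0.2 —
#'     the robustness-separation setting. The large instrument count
#'     reflects the many-instrument regime MR-Egger needs for a
#'     usefully powered intercept test.}
#'   \item{driver_snp}{11 instruments, null causal effect, with a
#'     0.7 log-odds outlier (ten times the mean SNP-exposure effect)
#'     injected at SNP 1, so the full-set IVW association is
#'     significant by construction and rests entirely on that single
#'     variant — the dismissed-association scenario.}
#'   \item{null_screen_37}{Base config for one of 37 null exposures
#'     (causal effect 0) against a single outcome — the multiplicity
#'     simulation; callers vary the seed per exposure.}
#' }
#' All presets use an exposure GWAS of 100,000, an outcome study of
#' 30,657 with case fraction 0.407, SNP-exposure effects of mean 0.07
#' (SD 0.045) SD-units per allele and MAF uniform on [0.1, 0.5].
#'
#' @param name Preset name; an unknown name is an error listing the
#'   available presets.
#' @param seed Seed stored in the returned config (default 1).
#' @return A \code{\linkS4class{SimulationConfig}}.
#' @export
scenarioPresets <- function(name, seed = 1L) {
  presets <- list(
    all_valid = function(s)
      simulationConfig(n_snps = 30L, theta_true = 0.2,
                       invalid_fraction = 0, pleiotropy = "none",
                       seed = s),
    balanced_40 = function(s)
      simulationConfig(n_snps = 150L, theta_true = 0.2,
                       invalid_fraction = 0.4, pleiotropy = "balanced",
                       pleiotropy_scale = 0.1, seed = s),
    directional_40 = function(s)
      simulationConfig(n_snps = 150L, theta_true = 0.2,
                       invalid_fraction = 0.4,
                       pleiotropy = "directional",
                       pleiotropy_scale = 0.1, seed = s),
    driver_snp = function(s)
      simulationConfig(n_snps = 11L, theta_true = 0,
                       invalid_fraction = 0, pleiotropy = "none",
                       outlier = list(index = 1L, effect = 0.7),
                       seed = s),
    null_screen_37 = function(s)
      simulationConfig(n_snps = 30L, theta_true = 0,
                       invalid_fraction = 0, pleiotropy = "none",
                       seed = s))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]](as.integer(seed))
}

#' Write a simulated pair to disk
#'
#' Emits the exposure and outcome tables in the exact TSV dialect
#' \code{readSummaryStats()} reads, plus the truth record as JSON
#' (full-precision doubles, so the record round-trips bit-exactly via
#' \code{readTruth()}).
#'
#' @param pair The list returned by \code{simulatePair()}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths (exposure, outcome, truth).
#' @export
writeSimulation <- function(pair, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_exposure.tsv",
                                           "_outcome.tsv",
                                           "_truth.json")))
  writeSummaryStats(pair$exposure, paths[1])
  writeSummaryStats(pair$outcome, paths[2])
  writeTruth(pair$truth, paths[3])
  invisible(paths)
}

#' Serialize / restore a truth record
#'
#' @param truth Truth data frame from \code{simulatePair()}.
#' @param path JSON file path.
#' @return \code{writeTruth()} returns \code{path} invisibly;
#'   \code{readTruth()} the restored data frame (without the config
#'   attribute).
#' @export
writeTruth <- function(truth, path) {
  json <- jsonlite::toJSON(truth, digits = I(17), auto_unbox = FALSE,
                           dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(lst, stringsAsFactors = FALSE)
}
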