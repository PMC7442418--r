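# Study orchestration: multiplicity thresholds, classification, and the
# full exposures-by-outcomes screen with report tables and a manifest.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests corrected for (>= 1).
#' @return \code{alpha / n_tests}; e.g. 0.05 over 37 exposures gives
#'   1.35e-3 (3 significant figures).
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Classify an association p-value
#'
#' Three-way classification against a Bonferroni-corrected and a nominal
#' threshold: \code{significant} if p is strictly below
#' \code{threshold_sig}; \code{suggestive} if
#' \code{threshold_sig <= p < threshold_sug}; otherwise \code{null}.
#' Both boundaries are strict on the significant side, so a p-value
#' equal to a threshold falls in the weaker class.
#'
#' @param pvalue P-value(s) to classify (vectorized).
#' @param threshold_sig Corrected significance threshold.
#' @param threshold_sug Nominal (suggestive) threshold; must exceed
#'   \code{threshold_sig}.
#' @return Character vector in \{\code{significant}, \code{suggestive},
#'   \code{null}\}.
#' @export
classifyAssociation <- function(pvalue, threshold_sig,
                                threshold_sug = 0.05) {
  stopifnot(threshold_sig > 0, threshold_sig < threshold_sug,
            threshold_sug < 1)
  ifelse(pvalue < threshold_sig, "significant",
         ifelse(pvalue < threshold_sug, "suggestive", "null"))
}

#' Read a whitespace-free LD matrix TSV
#'
#' Square table with SNP ids as header and first column.
#' @param path File path.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @export
readLDMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  LDMatrix(rownames(m), m)
}

#' Study configuration
#'
#' Bundle of everything one screening run needs: the exposure and
#' outcome summary-statistic files, the multiplicity denominator
#' (decoupled from the number of exposures actually run, so partial
#' runs keep the full correction), selection thresholds, per-method
#' seeds and estimator options.
#'
#' @slot exposures,outcomes Data frames with columns \code{label},
#'   \code{path} (exposures may add an optional \code{ld_path}).
#' @slot nTests Bonferroni denominator.
#' @slot alpha Nominal significance level.
#' @slot pInstrument Instrument inclusion p-value threshold.
#' @slot r2Threshold LD clumping threshold.
#' @slot seeds Named integer vector of per-method seeds.
#' @slot nBoot Bootstrap resamples for median/mode estimators.
#' @slot phi Mode bandwidth multiplier.
#' @slot seOrder Wald-ratio SE order.
#' @slot palindromePolicy,eafWindow Harmonization options.
#' @export
setClass("StudyConfig",
         representation(exposures = "data.frame", outcomes = "data.frame",
                        nTests = "integer", alpha = "numeric",
                        pInstrument = "numeric", r2Threshold = "numeric",
                        seeds = "integer", nBoot = "integer",
                        phi = "numeric", seOrder = "character",
                        palindromePolicy = "character",
                        eafWindow = "numeric"))

setValidity("StudyConfig", function(object) {
  msgs <- character()
  for (slot in c("exposures", "outcomes")) {
    d <- methods::slot(object, slot)
    if (!all(c("label", "path") %in% names(d)))
      msgs <- c(msgs, paste(slot, "needs columns label, path"))
  }
  if (object@nTests < nrow(object@exposures))
    msgs <- c(msgs, "nTests must be >= number of exposures")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  need <- c("weighted_median", "weighted_mode")
  if (!all(need %in% names(object@seeds)))
    msgs <- c(msgs, "seeds must name weighted_median and weighted_mode")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a StudyConfig
#'
#' @param exposures,outcomes Data frames (or lists of lists) with
#'   \code{label} and \code{path}.
#' @param n_tests Bonferroni denominator (defaults to the exposure
#'   count).
#' @param alpha,p_instrument,r2_threshold Thresholds.
#' @param seeds Named per-method seeds.
#' @param n_boot,phi,se_order,palindrome_policy,eaf_window Estimator and
#'   harmonization options.
#' @return A validated \code{\linkS4class{StudyConfig}}.
#' @export
studyConfig <- function(exposures, outcomes, n_tests = NULL,
                        alpha = 0.05, p_instrument = 5e-8,
                        r2_threshold = 0.01,
                        seeds = c(weighted_median = 1L,
                                  weighted_mode = 2L),
                        n_boot = 1000L, phi = 1, se_order = "first",
                        palindrome_policy = "drop", eaf_window = 0.08) {
  as_tbl <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(e)
      data.frame(label = e$label, path = e$path,
                 stringsAsFactors = FALSE)))
  }
  exposures <- as_tbl(exposures)
  outcomes <- as_tbl(outcomes)
  if (is.null(n_tests)) n_tests <- nrow(exposures)
  methods::new("StudyConfig", exposures = exposures, outcomes = outcomes,
               nTests = as.integer(n_tests), alpha = alpha,
               pInstrument = p_instrument, r2Threshold = r2_threshold,
               seeds = stats::setNames(as.integer(seeds), names(seeds)),
               nBoot = as.integer(n_boot), phi = phi,
               seOrder = se_order, palindromePolicy = palindrome_policy,
               eafWindow = eaf_window)
}

#' Read a study configuration from YAML
#'
#' The document mirrors \code{studyConfig()}'s arguments (keys
#' \code{exposures}, \code{outcomes}, \code{n_tests}, \code{alpha},
#' \code{p_instrument}, \code{r2_threshold}, \code{seeds},
#' \code{n_boot}, \code{phi}, \code{se_order}, \code{palindrome_policy},
#' \code{eaf_window}). Relative paths are resolved against the config
#' file's directory and must exist at load.
#'
#' @param path YAML file path.
#' @return A validated \code{\linkS4class{StudyConfig}}.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(entries) {
    d <- do.call(rbind, lapply(entries, function(e)
      data.frame(label = e$label, path = e$path,
                 stringsAsFactors = FALSE)))
    d$path <- ifelse(grepl("^/", d$path), d$path,
                     file.path(base, d$path))
    bad <- !file.exists(d$path)
    if (any(bad))
      stop("summary-statistic file(s) not found: ",
           paste(d$path[bad], collapse = ", "))
    d
  }
  args <- list(exposures = resolve(y$exposures),
               outcomes = resolve(y$outcomes))
  for (key in c("n_tests", "alpha", "p_instrument", "r2_threshold",
                "n_boot", "phi", "se_order", "palindrome_policy",
                "eaf_window"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$seeds)) args$seeds <- unlist(y$seeds)
  do.call(studyConfig, args)
}

# estimate one exposure/outcome pair; returns the pieces runStudy
# assembles (NULL estimates where a method is not applicable)
.estimate_pair <- function(insts, config) {
  n <- nSnps(insts)
  est <- list()
  if (n == 1L) {
    est$wald <- waldRatio(insts, se_order = config@seOrder)
  } else {
    est$ivw_fe <- ivwFE(insts, se_order = config@seOrder)
    if (n >= 3L) {
      est$mle <- maxLikelihood(insts)
      est$weighted_median <- weightedMedian(
        insts, n_boot = config@nBoot,
        seed = config@seeds[["weighted_median"]],
        se_order = config@seOrder)
      est$weighted_mode <- weightedMode(
        insts, phi = config@phi, n_boot = config@nBoot,
        seed = config@seeds[["weighted_mode"]],
        se_order = config@seOrder)
    } else if (n == 2L) {
      est$mle <- maxLikelihood(insts)
    }
  }
  egger <- if (n >= 3L) eggerRegression(insts) else NULL
  loo <- if (n >= 2L)
    leaveOneOut(insts, method = "ivw_fe", alpha = config@alpha,
                se_order = config@seOrder) else NULL
  conc <- if (n >= 3L) concordance(est[c("ivw_fe", "mle",
                                         "weighted_median",
                                         "weighted_mode")],
                                   alpha = config@alpha) else NULL
  list(estimates = est, egger = egger, loo = loo, concordance = conc)
}

#' Run the full exposure-by-outcome screen
#'
#' For every exposure/outcome pair: instrument selection (significance
#' filter, optional LD clumping when the exposure row carries an
#' \code{ld_path}), harmonization, every applicable estimator (Wald
#' ratio alone when a single instrument survives; IVW-FE from two; MLE
#' from two; weighted median, weighted mode and MR-Egger from three),
#' leave-one-out with driver flags, cross-method concordance, and
#' classification of the primary (IVW or Wald) p-value at both the
#' Bonferroni and the nominal threshold. Exposures with zero surviving
#' instruments are recorded as skipped with a reason and the run
#' continues. Deterministic given the config seeds.
#'
#' @param config A \code{\linkS4class{StudyConfig}}.
#' @param out_dir Optional directory; when given, the report tables are
#'   written as TSV and the manifest as JSON.
#' @return A list with \code{estimates}, \code{egger}, \code{loo},
#'   \code{concordance}, \code{classification}, \code{skipped} (data
#'   frames) and \code{manifest} (list: config hash, seeds, thresholds,
#'   power-formula label, package version, row-count reconciliation).
#' @export
runStudy <- function(config, out_dir = NULL) {
  stopifnot(methods::is(config, "StudyConfig"))
  methods::validObject(config)
  sig <- bonferroniThreshold(config@alpha, config@nTests)
  est_rows <- list(); egger_rows <- list(); loo_rows <- list()
  conc_rows <- list(); class_rows <- list(); skipped <- list()

  outcomes <- lapply(seq_len(nrow(config@outcomes)), function(i)
    readSummaryStats(config@outcomes$path[i],
                     trait_label = config@outcomes$label[i]))
  names(outcomes) <- config@outcomes$label

  for (i in seq_len(nrow(config@exposures))) {
    ex_label <- config@exposures$label[i]
    exposure <- readSummaryStats(config@exposures$path[i],
                                 trait_label = ex_label)
    ld <- NULL
    if ("ld_path" %in% names(config@exposures) &&
        !is.na(config@exposures$ld_path[i]) &&
        nzchar(config@exposures$ld_path[i]))
      ld <- readLDMatrix(config@exposures$ld_path[i])
    for (ou_label in names(outcomes)) {
      key <- paste(ex_label, ou_label, sep = " ~ ")
      insts <- tryCatch(
        suppressWarnings(buildInstrumentSet(
          exposure, outcomes[[ou_label]], ld = ld,
          p_threshold = config@pInstrument,
          r2_threshold = config@r2Threshold,
          palindrome_policy = config@palindromePolicy,
          eaf_window = config@eafWindow)),
        error = function(e) e)
      if (inherits(insts, "error") || nSnps(insts) == 0L) {
        reason <- if (inherits(insts, "error"))
          conditionMessage(insts) else "no instruments after harmonization"
        skipped[[key]] <- data.frame(exposure = ex_label,
                                     outcome = ou_label, reason = reason,
                                     stringsAsFactors = FALSE)
        next
      }
      res <- .estimate_pair(insts, config)
      est_rows[[key]] <- estimatesTable(res$estimates, ex_label, ou_label)
      primary <- if (!is.null(res$estimates$ivw_fe))
        res$estimates$ivw_fe else res$estimates$wald
      class_rows[[key]] <- data.frame(
        exposure = ex_label, outcome = ou_label,
        method = mrMethod(primary), pvalue = pvalue(primary),
        class = classifyAssociation(pvalue(primary), sig, config@alpha),
        n_snps = nSnps(primary), stringsAsFactors = FALSE)
      if (!is.null(res$egger)) {
        ic <- eggerIntercept(res$egger)
        egger_rows[[key]] <- cbind(
          estimatesTable(eggerSlope(res$egger), ex_label, ou_label),
          data.frame(intercept = ic[["intercept"]],
                     intercept_se = ic[["se"]],
                     intercept_pvalue = ic[["pvalue"]]))
      }
      if (!is.null(res$loo)) {
        per <- perExclusion(res$loo)
        loo_rows[[key]] <- data.frame(
          exposure = ex_label, outcome = ou_label,
          excluded_snp = per$snp_id, theta = per$theta, se = per$se,
          or_sd = per$or_sd, ci_low = per$ci_low, ci_high = per$ci_high,
          pvalue = per$pvalue,
          is_driver = per$snp_id %in% driverSnps(res$loo),
          is_near_driver = per$snp_id %in% nearDriverSnps(res$loo),
          stringsAsFactors = FALSE)
      }
      if (!is.null(res$concordance))
        conc_rows[[key]] <- data.frame(
          exposure = ex_label, outcome = ou_label,
          consistent = res$concordance@consistent,
          stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst) if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else data.frame()
  report <- list(estimates = bind(est_rows), egger = bind(egger_rows),
                 loo = bind(loo_rows), concordance = bind(conc_rows),
                 classification = bind(class_rows),
                 skipped = bind(skipped))
  cfg_list <- list(exposures = config@exposures,
                   outcomes = config@outcomes, n_tests = config@nTests,
                   alpha = config@alpha, p_instrument = config@pInstrument,
                   r2_threshold = config@r2Threshold,
                   seeds = as.list(config@seeds), n_boot = config@nBoot,
                   phi = config@phi, se_order = config@seOrder,
                   palindrome_policy = config@palindromePolicy,
                   eaf_window = config@eafWindow)
  report$manifest <- list(
    config = cfg_list,
    config_hash = .config_hash(cfg_list),
    bonferroni_threshold = sig,
    power_formula = "two-sided normal approximation (approximate)",
    package_version = as.character(utils::packageVersion("mrscreen")),
    n_estimate_rows = nrow(report$estimates),
    n_pairs_run = nrow(report$classification),
    n_pairs_skipped = nrow(report$skipped))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("estimates", "egger", "loo", "concordance",
                 "classification", "skipped")) {
      tbl <- report[[nm]]
      if (nrow(tbl) == 0 && nm != "estimates") next
      utils::write.table(tbl, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
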