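# Reading, writing and harmonizing GWAS summary-statistic tables.

.CANONICAL_REQUIRED <- c("snp_id", "effect_allele", "other_allele",
                         "beta", "se", "pvalue")
.CANONICAL_OPTIONAL <- c("chrom", "pos", "eaf", "n")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# detect the field separator from the header line: tab wins over comma
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited table (auto-detected from the header
#' line) of per-variant summary statistics into a
#' \code{\linkS4class{GwasSummaryStats}} object. File columns are mapped
#' onto the canonical fields through \code{column_map}; rows violating the
#' per-variant invariants (non-positive SE, p-value outside (0,1], allele
#' not a single A/C/G/T base, identical alleles, frequency outside [0,1],
#' unparseable numerics) are rejected with a warning listing row numbers.
#' P-values grossly inconsistent with |beta/se| under the two-sided normal
#' approximation (off by more than a factor of 2 on the log scale of the
#' implied z) raise a warn-only consistency notice.
#'
#' @param path Path to the delimited file (header required).
#' @param column_map Named character vector mapping canonical names
#'   (\code{snp_id}, \code{effect_allele}, \code{other_allele},
#'   \code{beta}, \code{se}, \code{pvalue}, and optionally \code{chrom},
#'   \code{pos}, \code{eaf}, \code{n}) to the file's column names.
#'   \code{NULL} assumes the file already uses canonical names.
#' @param trait_label Trait label stored in the returned object.
#' @return A \code{\linkS4class{GwasSummaryStats}}; the number of rejected
#'   rows is available as \code{attr(variants(x), "n_rejected")}.
#' @export
readSummaryStats <- function(path, column_map = NULL,
                             trait_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  cmap <- stats::setNames(as.list(c(.CANONICAL_REQUIRED,
                                    .CANONICAL_OPTIONAL)),
                          c(.CANONICAL_REQUIRED, .CANONICAL_OPTIONAL))
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_req <- .CANONICAL_REQUIRED[!unlist(cmap[.CANONICAL_REQUIRED])
                                     %in% names(raw)]
  if (length(missing_req))
    stop("required column(s) not found in ", path, ": ",
         paste(unlist(cmap[missing_req]), collapse = ", "),
         " (check column_map)")

  pick <- function(canon, numeric = FALSE) {
    col <- cmap[[canon]]
    if (!col %in% names(raw))
      return(rep(if (numeric) NA_real_ else NA_character_, nrow(raw)))
    x <- raw[[col]]
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }
  v <- data.frame(snp_id = pick("snp_id"),
                  chrom = pick("chrom"),
                  pos = pick("pos", numeric = TRUE),
                  effect_allele = toupper(pick("effect_allele")),
                  other_allele = toupper(pick("other_allele")),
                  eaf = pick("eaf", numeric = TRUE),
                  beta = pick("beta", numeric = TRUE),
                  se = pick("se", numeric = TRUE),
                  pvalue = pick("pvalue", numeric = TRUE),
                  n = pick("n", numeric = TRUE),
                  stringsAsFactors = FALSE)

  # row-level screening: required numerics parse, invariants hold
  raw_num <- function(canon) {
    col <- cmap[[canon]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  unparseable <- (is.na(v$beta) & nzchar(raw_num("beta"))) |
    (is.na(v$se) & nzchar(raw_num("se"))) |
    (is.na(v$pvalue) & nzchar(raw_num("pvalue")))
  bad <- is.na(v$beta) | is.na(v$se) | is.na(v$pvalue) |
    !is.finite(v$se) | v$se <= 0 |
    v$pvalue <= 0 | v$pvalue > 1 |
    !.check_alleles(v$effect_allele) | !.check_alleles(v$other_allele) |
    v$effect_allele == v$other_allele |
    (!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)) |
    (!is.na(v$pos) & v$pos < 0)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected in ", basename(path), " (rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", "; ",
            sum(unparseable, na.rm = TRUE), " with unparseable numerics)")
    v <- v[!bad, , drop = FALSE]
  }

  # warn-only: p-value vs normal approximation from |beta/se|
  if (nrow(v)) {
    z_p <- stats::qnorm(pmax(v$pvalue, .Machine$double.xmin) / 2,
                        lower.tail = FALSE)
    z_b <- abs(v$beta / v$se)
    comparable <- is.finite(z_p) & z_b > 0 & v$pvalue > 1e-300
    off <- comparable & (z_p / z_b > 2 | z_b / z_p > 2)
    if (any(off))
      warning(sum(off), " row(s) in ", basename(path),
              " have p-values inconsistent with |beta/se| ",
              "(> factor-2 disagreement in implied z); kept as read")
  }
  rownames(v) <- NULL
  out <- GwasSummaryStats(v, trait = trait_label)
  attr(out@variants, "n_rejected") <- sum(bad)
  out
}

#' Write summary statistics as TSV
#'
#' Writes the canonical ten-column table as tab-delimited text. Numeric
#' fields are printed with 17 significant digits so that write followed by
#' read reproduces the doubles bit-exactly.
#'
#' @param x A \code{\linkS4class{GwasSummaryStats}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(methods::is(x, "GwasSummaryStats"))
  v <- x@variants
  out <- v
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    out[[col]] <- .format_full(v[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# full-precision numeric formatting (%.17g round-trips IEEE doubles)
.format_full <- function(x) {
  s <- sprintf("%.17g", x)
  s[is.na(x)] <- NA_character_
  s
}

#' Harmonize exposure and outcome associations
#'
#' Puts the outcome effects on the exposure's effect-allele orientation,
#' SNP by SNP. When the outcome's allele pair equals the exposure's, the
#' record passes \code{unchanged}; when the alleles are swapped, the
#' outcome beta is negated and its frequency complemented
#' (\code{flipped}); strand flips (complementary base pairs) are attempted
#' before either comparison. Palindromic variants (A/T or C/G) are dropped
#' under \code{palindrome_policy = "drop"}; under
#' \code{"keep_if_eaf_informative"} they are kept only when, after label
#' alignment, both effect-allele frequencies fall on the same side of 0.5
#' and outside 0.5 +/- \code{eaf_window} (missing frequencies drop the
#' variant). Allele pairs irreconcilable by swap or strand flip are marked
#' \code{dropped_incompatible} — never silently passed. Exposure SNPs
#' absent from the outcome are dropped and reported in the
#' \code{missingInOutcome} slot. Output order follows the exposure.
#'
#' @param exposure,outcome \code{\linkS4class{GwasSummaryStats}} objects.
#' @param palindrome_policy \code{"drop"} (default) or
#'   \code{"keep_if_eaf_informative"}.
#' @param eaf_window Half-width of the frequency exclusion zone around 0.5
#'   used by the permissive palindrome policy (default 0.08).
#' @return A \code{\linkS4class{HarmonizedInstruments}} object carrying
#'   every intersected SNP with its \code{orientation_action}.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop",
                                            "keep_if_eaf_informative"),
                      eaf_window = 0.08) {
  stopifnot(methods::is(exposure, "GwasSummaryStats"),
            methods::is(outcome, "GwasSummaryStats"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- exposure@variants
  ou <- outcome@variants
  common <- ex$snp_id[ex$snp_id %in% ou$snp_id]
  if (!length(common))
    stop("no SNPs shared between exposure and outcome statistics")
  missing_out <- setdiff(ex$snp_id, ou$snp_id)
  if (length(missing_out))
    message(length(missing_out),
            " exposure SNP(s) absent from the outcome and dropped")
  ex <- ex[match(common, ex$snp_id), , drop = FALSE]
  ou <- ou[match(common, ou$snp_id), , drop = FALSE]

  n <- length(common)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  comp <- function(a) unname(.COMPLEMENT[a])

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- .is_palindromic(ea_x, oa_x)
    # align outcome labels to the exposure pair, trying strand flip second
    if (ea_y == ea_x && oa_y == oa_x) {
      act <- "unchanged"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      act <- "flipped"
    } else if (!pal && comp(ea_y) == ea_x && comp(oa_y) == oa_x) {
      act <- "unchanged"
    } else if (!pal && comp(ea_y) == oa_x && comp(oa_y) == ea_x) {
      act <- "flipped"
    } else {
      act <- "dropped_incompatible"
    }
    if (pal && act != "dropped_incompatible") {
      if (palindrome_policy == "drop") {
        act <- "dropped_palindromic"
      } else {
        f_x <- ex$eaf[i]
        f_y <- if (act == "flipped") 1 - eaf_out[i] else eaf_out[i]
        informative <- !is.na(f_x) && !is.na(f_y) &&
          abs(f_x - 0.5) > eaf_window && abs(f_y - 0.5) > eaf_window &&
          sign(f_x - 0.5) == sign(f_y - 0.5)
        if (!informative) act <- "dropped_palindromic"
      }
    }
    if (act == "flipped") {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    }
    action[i] <- act
  }

  HarmonizedInstruments(snp_id = common,
                        beta_exposure = ex$beta, se_exposure = ex$se,
                        beta_outcome = beta_out, se_outcome = ou$se,
                        eaf = ex$eaf, orientation_action = action,
                        exposure = exposure@trait, outcome = outcome@trait,
                        missingInOutcome = missing_out)
}

#' Write harmonized instruments as TSV
#'
#' Seven-column tab-delimited table including the
#' \code{orientation_action} audit column; numerics carry 17 significant
#' digits so the table round-trips bit-exactly through
#' \code{readHarmonized()}.
#'
#' @param x A \code{\linkS4class{HarmonizedInstruments}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeHarmonized <- function(x, path) {
  stopifnot(methods::is(x, "HarmonizedInstruments"))
  d <- x@data
  out <- d
  for (col in c("beta_exposure", "se_exposure", "beta_outcome",
                "se_outcome", "eaf"))
    out[[col]] <- .format_full(d[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read harmonized instruments from TSV
#'
#' @param path File written by \code{writeHarmonized()}.
#' @param exposure,outcome Trait labels for the returned object.
#' @return A \code{\linkS4class{HarmonizedInstruments}}.
#' @export
readHarmonized <- function(path, exposure = "exposure",
                           outcome = "outcome") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  HarmonizedInstruments(snp_id = d$snp_id,
                        beta_exposure = d$beta_exposure,
                        se_exposure = d$se_exposure,
                        beta_outcome = d$beta_outcome,
                        se_outcome = d$se_outcome, eaf = d$eaf,
                        orientation_action = d$orientation_action,
                        exposure = exposure, outcome = outcome)
}
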