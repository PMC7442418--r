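# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# quick harmonized instrument set from effect vectors
make_insts <- function(bx, sx, by, sy, ids = NULL,
                       exposure = "x", outcome = "y") {
  n <- length(bx)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(n))
  HarmonizedInstruments(snp_id = ids, beta_exposure = bx,
                        se_exposure = sx, beta_outcome = by,
                        se_outcome = sy, exposure = exposure,
                        outcome = outcome)
}

# quick summary-stat object; defaults give a clean strong association
make_stats <- function(n = 3, beta = NULL, se = NULL, pvalue = NULL,
                       eaf = NULL, effect_allele = "A",
                       other_allele = "G", ids = NULL, trait = "trait") {
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(n))
  if (is.null(beta)) beta <- rep(0.1, n)
  if (is.null(se)) se <- rep(0.01, n)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  pvalue <- pmax(pvalue, .Machine$double.xmin)
  if (is.null(eaf)) eaf <- rep(0.3, n)
  GwasSummaryStats(data.frame(
    snp_id = ids, chrom = "1", pos = seq_len(n) * 1000,
    effect_allele = rep_len(effect_allele, n),
    other_allele = rep_len(other_allele, n),
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = 10000,
    stringsAsFactors = FALSE), trait = trait)
}

# write a summary-stat table to a temp file, with optional renamed
# header and separator
write_stats_file <- function(df, sep = "\t", rename = NULL) {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  out <- df
  if (!is.null(rename))
    names(out)[match(names(rename), names(out))] <- unname(rename)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# canonical small raw table used by the io tests
raw_stats_df <- function() {
  data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = c("1", "2", "3"),
             pos = c(100L, 200L, 300L),
             effect_allele = c("A", "C", "T"),
             other_allele = c("G", "T", "G"),
             eaf = c(0.2, 0.4, 0.25),
             beta = c(0.05, -0.03, 0.08),
             se = c(0.01, 0.012, 0.02),
             pvalue = c(5.7e-7, 0.012, 6.3e-5),
             n = c(50000L, 50000L, 50000L),
             stringsAsFactors = FALSE)
}
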