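# Reading, writing and harmonizing summary-statistic tables.

test_that("well-formed tables parse to one record per row", {
  df <- raw_stats_df()
  path <- write_stats_file(df)
  x <- readSummaryStats(path, trait_label = "t")
  expect_s4_class(x, "GwasSummaryStats")
  expect_equal(nSnps(x), 3L)
  expect_equal(attr(variants(x), "n_rejected"), 0L)
  expect_equal(variants(x)$beta, df$beta)
  expect_equal(variants(x)$snp_id, df$snp_id)

  # comma-delimited dialect auto-detected from the header
  xc <- readSummaryStats(write_stats_file(df, sep = ","))
  expect_equal(variants(xc)$se, df$se)

  # lower-case alleles are upper-cased
  df2 <- df
  df2$effect_allele <- tolower(df2$effect_allele)
  x2 <- readSummaryStats(write_stats_file(df2))
  expect_equal(variants(x2)$effect_allele, df$effect_allele)
})

test_that("column aliases via column_map give identical records", {
  df <- raw_stats_df()
  canonical <- readSummaryStats(write_stats_file(df))
  aliased_path <- write_stats_file(
    df, rename = c(beta = "b", se = "std_err", pvalue = "p",
                   snp_id = "rsid"))
  aliased <- readSummaryStats(
    aliased_path,
    column_map = c(beta = "b", se = "std_err", pvalue = "p",
                   snp_id = "rsid"))
  expect_identical(variants(aliased), variants(canonical))
})

test_that("invalid rows are rejected with a counted warning", {
  df <- raw_stats_df()
  df$se[2] <- 0
  path <- write_stats_file(df)
  expect_warning(readSummaryStats(path), "1 row\\(s\\) rejected")
  x <- suppressWarnings(readSummaryStats(path))
  expect_equal(nSnps(x), 2L)
  expect_equal(attr(variants(x), "n_rejected"), 1L)

  df2 <- raw_stats_df()
  df2$beta[1] <- "not_a_number"
  path2 <- write_stats_file(df2)
  expect_warning(readSummaryStats(path2), "unparseable")
  x2 <- suppressWarnings(readSummaryStats(path2))
  expect_equal(nSnps(x2), 2L)

  # missing required column is a configuration error, not a row error
  df3 <- raw_stats_df()
  df3$pvalue <- NULL
  expect_error(readSummaryStats(write_stats_file(df3)),
               "required column")
})

test_that("p-values inconsistent with beta/se trigger a warn-only check", {
  df <- raw_stats_df()
  df$pvalue[1] <- 0.9  # |z| from beta/se is 5, implied z from p ~ 0.13
  expect_warning(readSummaryStats(write_stats_file(df)),
                 "inconsistent with \\|beta/se\\|")
})

test_that("summary tables round-trip bit-exactly through write/read", {
  set.seed(42)
  n <- 25
  df <- data.frame(
    snp_id = sprintf("rs%d", 1:n), chrom = "7", pos = 1:n,
    effect_allele = "A", other_allele = "C",
    eaf = runif(n), beta = rnorm(n) / 7, se = exp(rnorm(n) - 4),
    pvalue = NA, n = 1e5, stringsAsFactors = FALSE)
  df$pvalue <- pmax(2 * pnorm(-abs(df$beta / df$se)),
                    .Machine$double.xmin)
  x <- GwasSummaryStats(df, trait = "t")
  path <- tempfile(fileext = ".tsv")
  writeSummaryStats(x, path)
  y <- readSummaryStats(path, trait_label = "t")
  v1 <- variants(x); v2 <- variants(y)
  attr(v2, "n_rejected") <- NULL
  for (col in names(v1)) expect_identical(v2[[col]], v1[[col]], label = col)
})

test_that("harmonization aligns, flips, strand-flips and drops", {
  ex <- make_stats(5, beta = c(0.1, 0.2, 0.15, 0.12, 0.11),
                   effect_allele = c("A", "C", "A", "G", "A"),
                   other_allele = c("G", "T", "T", "A", "C"),
                   eaf = c(0.2, 0.3, 0.49, 0.25, 0.3))
  ov <- variants(ex)
  ov$beta <- c(0.03, 0.03, 0.05, 0.02, 0.04)
  ov$se <- rep(0.01, 5)
  ov$pvalue <- 2 * pnorm(-abs(ov$beta / ov$se))
  # rs002: alleles swapped; rs003: palindromic A/T; rs004: strand
  # complement (G/A -> C/T); rs005: irreconcilable pair
  ov$effect_allele <- c("A", "T", "A", "C", "A")
  ov$other_allele <- c("G", "C", "T", "T", "T")
  ou <- GwasSummaryStats(ov, trait = "out")

  h <- harmonize(ex, ou, palindrome_policy = "drop")
  d <- instrumentData(h)
  expect_equal(d$orientation_action,
               c("unchanged", "flipped", "dropped_palindromic",
                 "unchanged", "dropped_incompatible"))
  expect_equal(d$beta_outcome[1], 0.03)
  expect_equal(d$beta_outcome[2], -0.03)  # swap negates
  expect_equal(d$beta_outcome[4], 0.02)   # strand flip, same orientation
  expect_equal(nSnps(h), 3L)
  # no record lost without a logged action
  expect_equal(nrow(d), 5L)
})

test_that("palindromic variants obey the eaf-informative policy", {
  ex <- make_stats(3, effect_allele = "A", other_allele = "T",
                   eaf = c(0.2, 0.49, 0.2))
  ov <- variants(ex)
  ov$eaf <- c(0.22, 0.48, 0.8)  # informative / near 0.5 / opposite side
  ou <- GwasSummaryStats(ov, trait = "out")

  drop_all <- harmonize(ex, ou, palindrome_policy = "drop")
  expect_equal(nSnps(drop_all), 0L)
  expect_true(all(instrumentData(drop_all)$orientation_action ==
                    "dropped_palindromic"))

  h <- harmonize(ex, ou, palindrome_policy = "keep_if_eaf_informative",
                 eaf_window = 0.08)
  acts <- instrumentData(h)$orientation_action
  expect_equal(acts, c("unchanged", "dropped_palindromic",
                       "dropped_palindromic"))

  # missing frequency cannot adjudicate orientation -> dropped
  ov2 <- variants(ex)
  ov2$eaf <- NA_real_
  h2 <- harmonize(ex, GwasSummaryStats(ov2, trait = "out"),
                  palindrome_policy = "keep_if_eaf_informative")
  expect_equal(nSnps(h2), 0L)
})

test_that("harmonizing against an allele-swapped copy negates betas", {
  ex <- make_stats(8, beta = rnorm(8, 0.1, 0.03),
                   effect_allele = c("A", "C", "G", "T", "A", "C", "G",
                                     "T"),
                   other_allele = c("G", "A", "T", "C", "C", "T", "A",
                                    "G"))
  sv <- variants(ex)
  swapped <- sv
  swapped$effect_allele <- sv$other_allele
  swapped$other_allele <- sv$effect_allele
  swapped$eaf <- 1 - sv$eaf
  h <- harmonize(ex, GwasSummaryStats(swapped, trait = "out"))
  d <- keptInstruments(h)
  expect_equal(nrow(d), 8L)
  expect_true(all(d$orientation_action == "flipped"))
  expect_equal(d$beta_outcome, -d$beta_exposure)
})

test_that("harmonization is idempotent on already-harmonized pairs", {
  ex <- make_stats(6, beta = rnorm(6, 0.1, 0.02),
                   effect_allele = c("A", "C", "G", "T", "A", "G"),
                   other_allele = c("G", "A", "T", "C", "C", "T"))
  ov <- variants(ex)
  ov$beta <- rnorm(6, 0.02, 0.01)
  ou <- GwasSummaryStats(ov, trait = "out")
  h1 <- harmonize(ex, ou)
  d1 <- keptInstruments(h1)
  # rebuild an outcome table from the harmonized records
  ov2 <- ov
  ov2$beta <- d1$beta_outcome
  h2 <- harmonize(ex, GwasSummaryStats(ov2, trait = "out"))
  expect_true(all(instrumentData(h2)$orientation_action == "unchanged"))
  expect_identical(keptInstruments(h2), d1)
})

test_that("exposure SNPs absent from the outcome are reported", {
  ex <- make_stats(4)
  ov <- variants(ex)[1:2, ]
  expect_message(
    h <- harmonize(ex, GwasSummaryStats(ov, trait = "out")),
    "absent from the outcome")
  expect_equal(sort(h@missingInOutcome), c("rs003", "rs004"))
  expect_equal(nrow(instrumentData(h)), 2L)
  # disjoint pair is an error, not an empty result
  ov3 <- variants(make_stats(2, ids = c("rsX", "rsY")))
  expect_error(harmonize(ex, GwasSummaryStats(ov3, trait = "o")),
               "no SNPs shared")
})

test_that("harmonized tables round-trip bit-exactly", {
  set.seed(7)
  h <- make_insts(rnorm(9, 0.1, 0.02), exp(rnorm(9) - 5),
                  rnorm(9, 0.02, 0.01), exp(rnorm(9) - 4))
  path <- tempfile(fileext = ".tsv")
  writeHarmonized(h, path)
  h2 <- readHarmonized(path, exposure = "x", outcome = "y")
  expect_identical(instrumentData(h2), instrumentData(h))
})
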