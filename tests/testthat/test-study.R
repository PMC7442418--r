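# Multiplicity thresholds, classification, power and the full screen.

test_that("Bonferroni threshold and classification boundaries", {
  expect_equal(signif(bonferroniThreshold(0.05, 37), 3), 1.35e-3)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 4), 0.0025)

  sig <- bonferroniThreshold(0.05, 37)
  expect_equal(classifyAssociation(5e-4, sig), "significant")
  expect_equal(classifyAssociation(0.01, sig), "suggestive")
  expect_equal(classifyAssociation(0.05, sig), "null")  # strict boundary
  expect_equal(classifyAssociation(sig - 1e-9, sig), "significant")
  expect_equal(classifyAssociation(sig, sig), "suggestive")
  expect_equal(classifyAssociation(c(1e-4, 0.02, 0.9), sig),
               c("significant", "suggestive", "null"))
})

test_that("power is alpha at the null and monotone in its drivers", {
  expect_equal(powerBinaryOutcome(0.02, 30657, 0.407, theta = 0), 0.05)
  expect_warning(p0 <- powerBinaryOutcome(0, 30657, 0.407, theta = 0.3),
                 "degenerates")
  expect_equal(p0, 0.05)

  # grid kept below saturation so monotonicity is strict in doubles
  set.seed(55)
  for (i in 1:20) {
    r2 <- runif(1, 0.002, 0.02); n <- runif(1, 2000, 20000)
    cf <- runif(1, 0.2, 0.8); th <- runif(1, 0.03, 0.15)
    base <- powerBinaryOutcome(r2, n, cf, th)
    expect_gt(powerBinaryOutcome(r2 * 1.5, n, cf, th), base)
    expect_gt(powerBinaryOutcome(r2, n * 1.5, cf, th), base)
    expect_gt(powerBinaryOutcome(r2, n, cf, th * 1.5), base)
  }
})

test_that("detectable OR round-trips through the power function", {
  or <- detectableOR(0.019, 30657, 12488 / 30657, target_power = 0.8)
  expect_gt(or, 1)
  back <- powerBinaryOutcome(0.019, 30657, 12488 / 30657, log(or))
  expect_equal(back, 0.800, tolerance = 1e-6)
})

# build a small on-disk study: 2 simulated exposures with disjoint
# instruments against one combined outcome table
make_study_dir <- function(theta = c(0.25, 0), n_snps = 15L) {
  dir <- tempfile("study")
  dir.create(dir)
  outcome_rows <- list()
  for (i in seq_along(theta)) {
    pair <- simulatePair(simulationConfig(n_snps = n_snps,
                                          theta_true = theta[i],
                                          seed = 600L + i))
    ids <- sprintf("rs%d%06d", i, seq_len(n_snps))
    ev <- variants(pair$exposure); ev$snp_id <- ids
    ov <- variants(pair$outcome); ov$snp_id <- ids
    writeSummaryStats(GwasSummaryStats(ev, trait(pair$exposure)),
                      file.path(dir, sprintf("exposure%d.tsv", i)))
    outcome_rows[[i]] <- ov
  }
  writeSummaryStats(GwasSummaryStats(do.call(rbind, outcome_rows),
                                     "glioma"),
                    file.path(dir, "outcome.tsv"))
  writeLines(c(
    "exposures:",
    sprintf("  - label: trait%d\n    path: exposure%d.tsv", 1:2, 1:2),
    "outcomes:",
    "  - label: glioma\n    path: outcome.tsv",
    "n_tests: 37",
    "alpha: 0.05",
    "seeds:",
    "  weighted_median: 11",
    "  weighted_mode: 12",
    "n_boot: 200"),
    file.path(dir, "config.yaml"))
  dir
}

test_that("runStudy produces the full report bundle", {
  dir <- make_study_dir()
  config <- readStudyConfig(file.path(dir, "config.yaml"))
  expect_s4_class(config, "StudyConfig")
  expect_equal(config@nTests, 37L)

  out_dir <- file.path(dir, "out")
  report <- suppressMessages(runStudy(config, out_dir = out_dir))

  est <- report$estimates
  expect_true(all(c("trait1", "trait2") %in% est$exposure))
  # every multi-SNP method present for both exposures
  for (m in c("ivw_fe", "mle", "weighted_median", "weighted_mode"))
    expect_equal(sum(est$method == m), 2, label = m)
  expect_equal(nrow(report$classification), 2)
  expect_equal(nrow(report$concordance), 2)
  expect_true(all(file.exists(file.path(out_dir,
                                        c("estimates.tsv", "loo.tsv",
                                          "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$n_estimate_rows, nrow(est))
  expect_equal(manifest$bonferroni_threshold, 0.05 / 37)
  expect_match(manifest$config_hash, "^[0-9a-f]{8}$")
  # row-count reconciliation: estimates + skipped cover all pairs
  expect_equal(manifest$n_pairs_run + manifest$n_pairs_skipped,
               2 * 1)
})

test_that("runStudy is deterministic given config seeds", {
  dir <- make_study_dir()
  config <- readStudyConfig(file.path(dir, "config.yaml"))
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  suppressMessages(runStudy(config, out_dir = out1))
  suppressMessages(runStudy(config, out_dir = out2))
  for (f in c("estimates.tsv", "loo.tsv", "classification.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
})

test_that("an exposure with no surviving instruments is skipped", {
  dir <- tempfile("studyskip")
  dir.create(dir)
  pair <- simulatePair(simulationConfig(n_snps = 10L, theta_true = 0,
                                        seed = 61L))
  # weaken one exposure so nothing reaches genome-wide significance
  weak <- variants(pair$exposure)
  weak$beta <- weak$beta / 20
  weak$pvalue <- 2 * pnorm(-abs(weak$beta / weak$se))
  writeSummaryStats(GwasSummaryStats(weak, "weak"),
                    file.path(dir, "weak.tsv"))
  writeSummaryStats(pair$exposure, file.path(dir, "strong.tsv"))
  writeSummaryStats(pair$outcome, file.path(dir, "outcome.tsv"))
  config <- studyConfig(
    exposures = data.frame(label = c("weak", "strong"),
                           path = file.path(dir, c("weak.tsv",
                                                   "strong.tsv"))),
    outcomes = data.frame(label = "glioma",
                          path = file.path(dir, "outcome.tsv")),
    n_tests = 37, n_boot = 100)
  report <- suppressMessages(runStudy(config))
  expect_equal(report$skipped$exposure, "weak")
  expect_match(report$skipped$reason, "no instruments")
  expect_true(all(report$estimates$exposure == "strong"))
})

test_that("study config validation catches bad input", {
  expect_error(suppressWarnings(readStudyConfig(tempfile())),
               "cannot open|No such file", ignore.case = TRUE)
  dir <- tempfile("cfg"); dir.create(dir)
  writeLines(c("exposures:",
               "  - label: a\n    path: missing.tsv",
               "outcomes:",
               "  - label: b\n    path: also_missing.tsv"),
             file.path(dir, "bad.yaml"))
  expect_error(readStudyConfig(file.path(dir, "bad.yaml")),
               "not found")
})
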