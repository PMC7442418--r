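# The five estimators, MR-Egger regression and the OR-scale transform.

test_that("Wald ratio follows the delta-method formulas", {
  one <- make_insts(0.2, 0.01, 0.05, 0.02)
  est <- waldRatio(one, se_order = "first")
  expect_equal(theta(est), 0.25)
  expect_equal(stdErr(est), 0.10)
  expect_equal(orSD(est), exp(0.25), tolerance = 1e-12)
  expect_equal(round(orSD(est), 3), 1.284)

  second <- waldRatio(one, se_order = "second")
  expect_equal(stdErr(second),
               sqrt(0.02^2 / 0.2^2 + 0.05^2 * 0.01^2 / 0.2^4))

  null <- waldRatio(make_insts(0.2, 0.01, 0, 0.02))
  expect_equal(theta(null), 0)
  expect_equal(orSD(null), 1)
  expect_equal(pvalue(null), 1)

  expect_error(waldRatio(make_insts(0, 0.01, 0.05, 0.02)),
               "Wald ratio undefined")
})

test_that("IVW-FE reduces to Wald at n = 1 and matches the hand mean", {
  one <- make_insts(0.2, 0.01, 0.05, 0.02)
  w <- waldRatio(one); i <- ivwFE(one)
  expect_equal(theta(i), theta(w))
  expect_equal(stdErr(i), stdErr(w))
  expect_equal(pvalue(i), pvalue(w))

  # ratio estimates 0.2 (se 0.1) and 0.4 (se 0.2):
  # theta = (0.2*100 + 0.4*25)/125, se = 1/sqrt(125)
  two <- make_insts(c(1, 1), c(0.01, 0.01), c(0.2, 0.4), c(0.1, 0.2))
  est <- ivwFE(two)
  expect_equal(theta(est), 0.24)
  expect_equal(stdErr(est), 1 / sqrt(125))
})

test_that("IVW-FE equals weighted least squares through the origin", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:40, 1)
    bx <- rnorm(n, 0.1, 0.05); bx[abs(bx) < 0.01] <- 0.01
    by <- rnorm(n, 0.02, 0.02)
    sy <- exp(rnorm(n) - 4)
    est <- ivwFE(make_insts(bx, rep(0.01, n), by, sy))
    wls <- oracle_wls_origin(bx, by, sy)
    expect_equal(theta(est), wls$theta, tolerance = 1e-10)
    expect_equal(stdErr(est), wls$se, tolerance = 1e-10)
  }
})

test_that("profile MLE recovers a noiseless effect and matches a grid", {
  # exact proportionality: the maximizer is the generating slope
  bx <- c(0.08, 0.12, 0.1, 0.15)
  ins <- make_insts(bx, rep(0.01, 4), 0.3 * bx, rep(0.01, 4))
  expect_equal(theta(maxLikelihood(ins)), 0.3, tolerance = 1e-6)

  # two hand-set instruments vs a brute-force grid maximizer
  bx2 <- c(0.1, 0.2); by2 <- c(0.04, 0.05)
  sx2 <- c(0.02, 0.03); sy2 <- c(0.015, 0.02)
  est <- maxLikelihood(make_insts(bx2, sx2, by2, sy2))
  grid <- oracle_mle_grid(bx2, by2, sx2, sy2)
  expect_equal(theta(est), grid, tolerance = 1e-4)
})

test_that("MLE and IVW estimate the same quantity without heterogeneity", {
  agree <- vapply(1:200, function(s) {
    pair <- simulatePair(scenarioPresets("all_valid", seed = 5000 + s))
    insts <- simulatedInstruments(pair)
    i <- ivwFE(insts); m <- maxLikelihood(insts)
    abs(theta(m) - theta(i)) <=
      2 * sqrt(stdErr(m)^2 + stdErr(i)^2)
  }, logical(1))
  expect_true(all(agree))
})

test_that("weighted median interpolates the standardized cumulative weights", {
  # equal weights, ratios {0.1, 0.2, 0.9}: cumulative standardized
  # weights {1/6, 1/2, 5/6} put the median exactly at 0.2
  ins <- make_insts(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.9),
                    rep(0.05, 3))
  est <- weightedMedian(ins, n_boot = 200, seed = 9)
  expect_equal(theta(est), 0.2)

  # all ratios equal: the median is that value regardless of weights
  ins2 <- make_insts(c(0.1, 0.2, 0.4), rep(0.01, 3),
                     0.3 * c(0.1, 0.2, 0.4), c(0.01, 0.03, 0.02))
  expect_equal(theta(weightedMedian(ins2, n_boot = 100, seed = 1)), 0.3)

  # seeded determinism of the bootstrap SE
  a <- weightedMedian(ins, n_boot = 300, seed = 42)
  b <- weightedMedian(ins, n_boot = 300, seed = 42)
  expect_identical(stdErr(a), stdErr(b))
  expect_error(weightedMedian(make_insts(c(1, 1), c(0.01, 0.01),
                                         c(0.1, 0.2), c(0.05, 0.05))),
               "at least three")
})

test_that("weighted mode maximizes its kernel density", {
  # 5 ratios clustered near 0.3, 2 outliers near 1.5, equal weights
  ratios <- c(0.28, 0.29, 0.30, 0.31, 0.33, 1.45, 1.55)
  ins <- make_insts(rep(1, 7), rep(0.01, 7), ratios, rep(0.05, 7))
  est <- weightedMode(ins, n_boot = 100, seed = 3)
  expect_lt(abs(theta(est) - 0.3), 0.05)

  rs <- ratios  # weights equal -> normalized weights 1/7
  h <- 1 * 0.9 * min(sd(rs), mad(rs)) * 7^(-1 / 5)
  grid <- oracle_mode_grid(rs, rep(1 / 7, 7), h)
  expect_lt(abs(theta(est) - grid$mode), grid$resolution)

  # degenerate spread: all ratios identical
  ins2 <- make_insts(c(0.1, 0.2, 0.4), rep(0.01, 3),
                     0.25 * c(0.1, 0.2, 0.4), rep(0.02, 3))
  expect_equal(theta(weightedMode(ins2, n_boot = 100, seed = 5)), 0.25,
               tolerance = 1e-9)

  a <- weightedMode(ins, n_boot = 150, seed = 8)
  b <- weightedMode(ins, n_boot = 150, seed = 8)
  expect_identical(stdErr(a), stdErr(b))
})

test_that("Egger regression matches the closed-form weighted fit", {
  # exact line: zero residuals recover intercept and slope exactly
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  ins <- make_insts(bx, rep(0.01, 5), 0.01 + 0.3 * bx, rep(0.02, 5))
  egger <- eggerRegression(ins)
  expect_equal(theta(eggerSlope(egger)), 0.3, tolerance = 1e-10)
  expect_equal(eggerIntercept(egger)[["intercept"]], 0.01,
               tolerance = 1e-10)

  # with no intercept and no noise the slope equals IVW on the same
  # oriented data
  ins0 <- make_insts(bx, rep(0.01, 5), 0.3 * bx, rep(0.02, 5))
  expect_equal(theta(eggerSlope(eggerRegression(ins0))),
               theta(ivwFE(ins0)), tolerance = 1e-10)

  # 4-point hand dataset vs the weighted normal equations
  bx4 <- c(0.06, 0.11, 0.21, 0.32)
  by4 <- c(0.02, 0.01, 0.06, 0.09)
  sy4 <- c(0.01, 0.02, 0.015, 0.03)
  e4 <- eggerRegression(make_insts(bx4, rep(0.01, 4), by4, sy4))
  oracle <- oracle_egger_wls(bx4, by4, sy4)
  expect_equal(theta(eggerSlope(e4)), oracle$slope, tolerance = 1e-12)
  expect_equal(stdErr(eggerSlope(e4)), oracle$slope_se,
               tolerance = 1e-12)
  expect_equal(eggerIntercept(e4)[["intercept"]], oracle$intercept,
               tolerance = 1e-12)
  expect_equal(eggerIntercept(e4)[["se"]], oracle$intercept_se,
               tolerance = 1e-12)

  expect_error(eggerRegression(make_insts(rep(0.1, 3), rep(0.01, 3),
                                          c(0.01, 0.02, 0.03),
                                          rep(0.02, 3))),
               "singular")
})

test_that("the OR-scale transform and its monotonicity hold", {
  flat <- toORScale(0, 0.1)
  expect_equal(unname(flat["or_sd"]), 1)
  expect_equal(unname(flat["pvalue"]), 1)
  expect_equal(unname(flat["ci_low"] * flat["ci_high"]), 1,
               tolerance = 1e-12)  # symmetric in log scale

  sc <- toORScale(0.25, 0.10)
  expect_equal(unname(sc["or_sd"]), exp(0.25))
  expect_equal(unname(sc["ci_low"]), exp(0.25 - qnorm(0.975) * 0.1))
  expect_equal(round(unname(sc["ci_low"]), 2), 1.06)
  expect_equal(round(unname(sc["ci_high"]), 3), 1.562)

  thetas <- seq(0.05, 1, by = 0.05)
  ors <- vapply(thetas, function(t) toORScale(t, 0.1)[["or_sd"]],
                numeric(1))
  ps <- vapply(thetas, function(t) toORScale(t, 0.1)[["pvalue"]],
               numeric(1))
  expect_true(all(diff(ors) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("estimators are sign-equivariant in the outcome", {
  set.seed(21)
  bx <- rnorm(8, 0.12, 0.03); sx <- rep(0.012, 8)
  by <- rnorm(8, 0.035, 0.015); sy <- rep(0.02, 8)
  pos <- make_insts(bx, sx, by, sy)
  neg <- make_insts(bx, sx, -by, sy)

  for (fit in list(function(x) ivwFE(x),
                   function(x) maxLikelihood(x),
                   function(x) weightedMedian(x, n_boot = 200, seed = 4),
                   function(x) weightedMode(x, n_boot = 200, seed = 4),
                   function(x) eggerSlope(eggerRegression(x)))) {
    ep <- fit(pos); en <- fit(neg)
    expect_equal(theta(en), -theta(ep), tolerance = 1e-6)
    expect_equal(stdErr(en), stdErr(ep), tolerance = 1e-8)
  }
  # single-instrument Wald as well
  wp <- waldRatio(make_insts(bx[1], sx[1], by[1], sy[1]))
  wn <- waldRatio(make_insts(bx[1], sx[1], -by[1], sy[1]))
  expect_equal(theta(wn), -theta(wp))
  expect_identical(stdErr(wn), stdErr(wp))
})

test_that("estimators are scale-equivariant in the exposure", {
  set.seed(22)
  bx <- rnorm(8, 0.12, 0.03); sx <- rep(0.012, 8)
  by <- rnorm(8, 0.035, 0.015); sy <- rep(0.02, 8)
  cc <- 3.7
  base <- make_insts(bx, sx, by, sy)
  scaled <- make_insts(cc * bx, cc * sx, by, sy)
  for (fit in list(function(x) ivwFE(x),
                   function(x) maxLikelihood(x),
                   function(x) eggerSlope(eggerRegression(x)))) {
    eb <- fit(base); es <- fit(scaled)
    expect_equal(theta(es), theta(eb) / cc, tolerance = 1e-6)
    expect_equal(stdErr(es), stdErr(eb) / cc, tolerance = 1e-6)
  }
  w1 <- waldRatio(make_insts(bx[1], sx[1], by[1], sy[1]))
  w2 <- waldRatio(make_insts(cc * bx[1], cc * sx[1], by[1], sy[1]))
  expect_equal(theta(w2), theta(w1) / cc)
  expect_equal(stdErr(w2), stdErr(w1) / cc)
})
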