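test_that("score statistic matches the worked single-isoform case", {
  y <- iso_counts(matrix(c(1, 3, 2, 6), 4, 1))
  fit <- fit_null(y, "poisson")
  s <- score_statistic(y, fit, c(0, 0, 1, 1))
  expect_equal(s$quadratic_term, 4)
  expect_equal(s$trace_term, 6)
  expect_equal(s$U, -1)
  # all-zero design annihilates both terms
  expect_equal(score_statistic(y, fit, rep(0, 4))$U, 0)
})

test_that("simplified score equals the dense matrix expression on random instances", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    for (fam in c("poisson", "nb")) {
      fit <- suppressWarnings(fit_null(inst$y, fam))
      s <- score_statistic(inst$y, fit, inst$x)
      expect_equal(s$U,
                   dense_U(fit$counts, fit$gamma, inst$x, fam, fit$phi_hat),
                   tolerance = 1e-10)
      expect_equal(s$U, (s$quadratic_term - s$trace_term) / 2)
      expect_gte(s$quadratic_term, 0)
    }
  }
})

test_that("NB score converges to the Poisson score as dispersion vanishes", {
  set.seed(5)
  y <- matrix(rpois(80, 7), 40, 2)
  g <- matrix(colMeans(y), 40, 2, byrow = TRUE)
  x <- rep(c(0, 1), each = 20)
  Up <- score_statistic(y, known_fit(y, g, "poisson"), x)$U
  Un <- score_statistic(y, known_fit(y, g, "nb", phi = 1e-10), x)$U
  expect_lt(abs(Un - Up), 1e-6)
})

test_that("cumulant relations hold for both families", {
  expect_equal(unlist(cumulants("poisson", 2)), c(kappa2 = 2, kappa3 = 2, kappa4 = 2))
  expect_equal(unlist(cumulants("nb", 1, 1)), c(kappa2 = 2, kappa3 = 6, kappa4 = 26))
  expect_equal(unlist(cumulants("nb", 3, 0)), unlist(cumulants("poisson", 3)))
  # sample cumulants of NB draws agree (k-statistics at large n)
  set.seed(9)
  z <- rnbinom(4e5, size = 1, mu = 1)       # gamma = 1, phi = 1
  m <- mean(z); d <- z - m
  k2 <- mean(d^2); k3 <- mean(d^3); k4 <- mean(d^4) - 3 * k2^2
  expect_equal(k2, 2, tolerance = 0.05)
  expect_equal(k3, 6, tolerance = 0.08)
  expect_equal(k4, 26, tolerance = 0.15)
})

test_that("R and C element generators reduce correctly", {
  # Poisson closed forms
  fw <- family_weights(known_fit(matrix(2, 1, 1), matrix(2, 1, 1), "poisson"))
  rc <- isovct:::rc_elements(fw, cumulants("poisson", matrix(2, 1, 1)))
  expect_equal(rc$r_diag[1, 1], 10)  # gamma + 2 gamma^2
  expect_equal(rc$c_diag[1, 1], 2)   # gamma
  # NB general form at the spec point
  fwn <- family_weights(known_fit(matrix(1, 1, 1), matrix(1, 1, 1), "nb", phi = 1))
  rcn <- isovct:::rc_elements(fwn, cumulants("nb", matrix(1, 1, 1), 1))
  expect_equal(rcn$c_diag[1, 1], 0.5)
  # continuity at phi -> 0
  fw0 <- family_weights(known_fit(matrix(2, 1, 1), matrix(2, 1, 1), "nb", phi = 1e-8))
  rc0 <- isovct:::rc_elements(fw0, cumulants("nb", matrix(2, 1, 1), 1e-8))
  expect_lt(abs(rc0$r_diag[1, 1] - 10), 1e-5)
  expect_lt(abs(rc0$c_diag[1, 1] - 2), 1e-6)
})

test_that("NB C diagonal matches a Monte-Carlo covariance of score components", {
  # c_ii is the covariance between the mean-score of one observation and twice
  # its contribution to U (x = 1 for the single sample involved)
  set.seed(13)
  gam <- 1; phi <- 1
  z <- rnbinom(1e6, size = 1 / phi, mu = gam)
  resid <- z - gam
  score_mean <- resid / (1 + phi * gam)               # (w/delta) * (y - gamma)
  w <- gam / (1 + phi * gam); e <- phi * gam / (1 + phi * gam)^2
  u_contrib <- (resid / (1 + phi * gam))^2 - (w + e * resid)
  expect_equal(mean(score_mean * u_contrib), 0.5, tolerance = 0.05)
})

test_that("theoretical p-value modes behave as defined", {
  expect_equal(theoretical_pvalue(0, 4), 1)
  expect_equal(theoretical_pvalue(sqrt(3.841 * 4), 4), 0.05, tolerance = 1e-3)
  # large negative score: chi-square mode small, one-sided mode > 0.5
  expect_lt(theoretical_pvalue(-20, 4), 0.01)
  expect_gt(theoretical_pvalue(-20, 4, mode = "one_sided"), 0.5)
  expect_error(theoretical_pvalue(1, 0), "positive")
})

test_that("permutation p-value conventions and reproducibility", {
  # identical samples: every permuted U equals the observed -> p = 1
  y <- iso_counts(matrix(rep(c(3, 5), each = 6), 6, 2), gene_id = "g")
  fit <- fit_null(y, "poisson")
  pp <- permutation_pvalue(y, fit, c(1, 1, 1, 0, 0, 0), B = 99, seed = 1)
  expect_equal(pp$p, 1)
  # add-one convention when the observed U tops every permuted value
  set.seed(17)
  yb <- iso_counts(cbind(c(rpois(10, 2), rpois(10, 40)), rpois(20, 5)))
  xb <- rep(c(0, 1), each = 10)
  fitb <- fit_null(yb, "poisson")
  ppb <- permutation_pvalue(yb, fitb, xb, B = 999, seed = 2)
  expect_equal(ppb$p, (1 + sum(ppb$U_perm >= ppb$U_obs)) / 1000)
  expect_equal(ppb$p, 0.001)
  # same seed, same result
  pp1 <- permutation_pvalue(yb, fitb, xb, B = 200, seed = 42)
  pp2 <- permutation_pvalue(yb, fitb, xb, B = 200, seed = 42)
  expect_identical(pp1$U_perm, pp2$U_perm)
})

test_that("permuted score mean matches the finite-population closed form", {
  set.seed(23)
  for (fam in c("poisson", "nb")) {
    sc <- vct_scenario(N = 40, p = 2, s = 0.04, l = 0, exp_M = 5,
                       phi = if (fam == "nb") 0.5 else 0, family = fam)
    sim <- simulate_gene(sc, seed = 99)
    fit <- suppressWarnings(fit_null(sim$counts, fam))
    pp <- permutation_pvalue(sim$counts, fit, sim$x, B = 5000, seed = 3)
    fw <- family_weights(fit)
    z <- (fit$counts - fit$gamma) * fw$phi_diag
    tvec <- rowSums(if (fam == "poisson") fw$w else fw$w0)
    expected <- perm_mean_U(z, tvec, sim$x)
    se <- sd(pp$U_perm) / sqrt(5000)
    expect_lt(abs(mean(pp$U_perm) - expected), 3 * se)
  }
})

test_that("permutation p-values are invariant to relabelling samples", {
  set.seed(31)
  y <- matrix(rpois(60, 6), 20, 3)
  x <- rep(c(0, 1), each = 10)
  perm <- sample(20)
  f1 <- fit_null(iso_counts(y), "poisson")
  f2 <- fit_null(iso_counts(y[perm, ]), "poisson")
  p1 <- permutation_pvalue(iso_counts(y), f1, x, B = 2000, seed = 8)$p
  p2 <- permutation_pvalue(iso_counts(y[perm, ]), f2, x[perm], B = 2000, seed = 8)$p
  expect_lt(abs(p1 - p2), 0.05)
  # observed statistic is exactly invariant
  expect_equal(score_statistic(iso_counts(y), f1, x)$U,
               score_statistic(iso_counts(y[perm, ]), f2, x[perm])$U)
})
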