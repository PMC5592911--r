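test_that("fixed-mode fitted means are the per-isoform sample means", {
  y <- iso_counts(cbind(c(2, 4, 6, 8), c(3, 3, 3, 3)), gene_id = "g")
  for (fam in c("poisson", "nb")) {
    fit <- fit_null(y, family = fam, mode = "fixed")
    expect_equal(unname(fit$gamma[, 1]), rep(5, 4))
    expect_equal(unname(fit$gamma[, 2]), rep(3, 4))
  }
  # constant column is under-dispersed: dispersion at the lower bound
  fit <- fit_null(y, family = "nb")
  expect_lte(fit$phi_hat, 1e-8)
})

test_that("intercept/offset split is sum-to-zero and reproduces column means", {
  y <- iso_counts(matrix(c(2, 3, 2, 3, 7, 8, 7, 8), 4, 2), gene_id = "g")
  fit <- fit_null(y, "poisson")
  expect_equal(sum(fit$alpha_hat), 0)
  expect_equal(unname(exp(fit$mu_hat + fit$alpha_hat)), unname(colMeans(y)))
})

test_that("degenerate and zero-count isoforms are handled", {
  allz <- matrix(0, 4, 2)
  expect_error(fit_null(iso_counts(allz)), "degenerate gene")
  y <- iso_counts(cbind(c(1, 2, 3, 4), c(0, 0, 0, 0)), gene_id = "g")
  expect_warning(fit <- fit_null(y, "poisson"), "zero total count")
  expect_equal(length(fit$alpha_hat), 1L)
  expect_equal(unname(fit$gamma[1, 1]), 2.5)
})

test_that("dispersion MLE agrees with an exhaustive grid search", {
  set.seed(101)
  for (k in 1:20) {
    n <- sample(20:60, 1)
    mu <- runif(1, 2, 12)
    phi_true <- sample(c(0, 0.3, 1, 3), 1)
    y <- if (phi_true == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi_true, mu = mu)
    y <- matrix(y, n, 1)
    if (sum(y) == 0) next
    g <- matrix(mean(y), n, 1)
    phi_hat <- estimate_dispersion(y, g)
    oracle <- grid_dispersion(y, g)
    ll_hat <- sum(dnbinom(y, size = 1 / phi_hat, mu = g, log = TRUE))
    expect_lt(oracle$loglik - ll_hat, 1e-4)
  }
})

test_that("dispersion MLE is consistent under Poisson and NB data", {
  set.seed(7)
  y <- matrix(rpois(200, 5), 200, 1)
  expect_lte(estimate_dispersion(y, matrix(mean(y), 200, 1)), 0.05)
  y <- matrix(rnbinom(400, size = 0.5, mu = 5), 400, 1)
  phi <- estimate_dispersion(y, matrix(mean(y), 400, 1))
  expect_gt(phi, 1.5)
  expect_lt(phi, 2.5)
})

test_that("family weights match the closed forms", {
  fit <- known_fit(matrix(4, 2, 1), matrix(4, 2, 1), "poisson")
  fw <- family_weights(fit)
  expect_equal(fw$delta[1, 1], 4)
  expect_equal(fw$w[1, 1], 4)
  expect_equal(fw$e[1, 1], 0)
  expect_equal(fw$w0, fw$w)
  expect_equal(fw$phi_diag[1, 1], 1)

  fitnb <- known_fit(matrix(1, 2, 1), matrix(1, 2, 1), "nb", phi = 1)
  fwnb <- family_weights(fitnb)
  expect_equal(fwnb$phi_diag[1, 1], 0.5)
  expect_equal(fwnb$w[1, 1], 0.5)
  expect_equal(fwnb$e[1, 1], 0.25)
})

test_that("NB weights converge to Poisson weights as dispersion vanishes", {
  set.seed(11)
  y <- matrix(rpois(12, 6), 4, 3)
  g <- matrix(colMeans(y), 4, 3, byrow = TRUE)
  fp <- family_weights(known_fit(y, g, "poisson"))
  fn <- family_weights(known_fit(y, g, "nb", phi = 1e-8))
  for (field in c("delta", "w", "w0", "e", "phi_diag")) {
    expect_lt(max(abs(fp[[field]] - fn[[field]])), 1e-6)
  }
})

test_that("random-mode fit approaches the fixed-mode fit as shrinkage vanishes", {
  set.seed(21)
  y <- iso_counts(matrix(rpois(120, c(4, 9, 15)[rep(1:3, each = 40)]), 40, 3))
  for (fam in c("poisson", "nb")) {
    fixed <- fit_null(y, fam, mode = "fixed")
    loose <- fit_null(y, fam, mode = "random", shrink_var = 1e6)
    expect_true(loose$converged)
    expect_lt(max(abs(loose$gamma / fixed$gamma - 1)), 0.01)
  }
  # strong shrinkage pulls the per-isoform means together
  tight <- fit_null(y, "poisson", mode = "random", shrink_var = 1e-8)
  expect_lt(diff(range(tight$gamma)), diff(range(fit_null(y, "poisson")$gamma)))
})
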