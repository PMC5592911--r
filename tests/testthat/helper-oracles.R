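# Independent oracles used across the suite.  Everything here is built from
# the dense Np-dimensional matrix expressions or brute-force search, kept
# deliberately separate from the package's simplified computational paths.

# Dense-matrix score statistic: stacks Y sample-major (isoform fastest),
# builds X = (x_1 I_p, ..., x_N I_p)^T explicitly and evaluates the full
# quadratic form and trace.
dense_U <- function(y, gamma, x, family, phi = 0) {
  N <- nrow(y); p <- ncol(y)
  yv <- as.vector(t(y))
  gv <- as.vector(t(gamma))
  X <- matrix(0, N * p, p)
  for (i in seq_len(N)) for (j in seq_len(p)) X[(i - 1) * p + j, j] <- x[i]
  XXt <- X %*% t(X)
  r <- yv - gv
  if (family == "poisson") {
    W <- diag(gv, N * p)
    0.5 * (drop(t(r) %*% XXt %*% r) - sum(diag(W %*% XXt)))
  } else {
    Phi <- diag(1 / (1 + phi * gv), N * p)
    w0 <- gv / (1 + phi * gv) + phi * gv * (yv - gv) / (1 + phi * gv)^2
    W0 <- diag(w0, N * p)
    0.5 * (drop(t(r) %*% Phi %*% XXt %*% Phi %*% r) - sum(diag(W0 %*% XXt)))
  }
}

# Exhaustive grid search for the NB dispersion MLE at fixed means.
grid_dispersion <- function(y, gamma, n_grid = 4000) {
  phis <- exp(seq(log(1e-8), log(1e3), length.out = n_grid))
  ll <- vapply(phis, function(ph) {
    sum(dnbinom(as.vector(y), size = 1 / ph, mu = as.vector(gamma), log = TRUE))
  }, numeric(1))
  list(phi = phis[which.max(ll)], loglik = max(ll))
}

# Build a null-fit object around externally chosen (known) means, bypassing
# estimation; used for known-parameter Monte-Carlo checks.
known_fit <- function(y, gamma, family = "poisson", phi = 0) {
  structure(list(family = family, mu_hat = mean(log(colMeans(gamma))),
                 alpha_hat = rep(0, ncol(y)), gamma = gamma,
                 phi_hat = phi, mode = "fixed", converged = TRUE,
                 kept = seq_len(ncol(y)), counts = unclass(y),
                 gene_id = "known"),
            class = "iso_nullfit")
}

# Closed-form expectation of the permuted score: for a random relabelling of
# a fixed vector z by a fixed design x,
#   E[ (sum_i x_{pi(i)} z_i)^2 ] = N^2 xbar^2 zbar^2 + Sxx Szz / (N - 1),
# and the trace term averages to (sum x^2)(sum_i t_i)/N.
perm_mean_U <- function(z, tvec, x) {
  N <- length(x)
  Sxx <- sum((x - mean(x))^2)
  eq <- vapply(seq_len(ncol(z)), function(j) {
    zj <- z[, j]
    N^2 * mean(x)^2 * mean(zj)^2 + Sxx * sum((zj - mean(zj))^2) / (N - 1)
  }, numeric(1))
  0.5 * (sum(eq) - sum(x^2) * sum(tvec) / N)
}

# Random small test instance for oracle-equivalence sweeps.
random_instance <- function(seed) {
  set.seed(seed)
  N <- sample(3:6, 1)
  p <- sample(1:3, 1)
  y <- matrix(rpois(N * p, lambda = runif(p, 2, 10)[rep(seq_len(p), each = N)]),
              N, p)
  y[1, ] <- y[1, ] + 1  # guard against all-zero columns
  x <- if (runif(1) < 0.5) {
    sample(c(0, 1), N, replace = TRUE)
  } else {
    round(runif(N), 2)
  }
  if (length(unique(x)) < 2) x[1] <- x[1] + 1
  list(y = iso_counts(y, gene_id = paste0("r", seed)), x = x)
}
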