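PHI_LOWER <- 1e-8

#' Fit the null model (no group effect) for one gene
#'
#' Under the null hypothesis the model reduces to a per-isoform intercept,
#' \eqn{\log E(Y_{ij}) = \mu + \alpha_j}.  The default `fixed` mode treats the
#' isoform baselines as fixed parameters, whose MLE for both families is the
#' per-isoform sample mean; `random` mode shrinks the baselines towards a
#' common intercept by penalized iteratively reweighted least squares and
#' reduces to `fixed` as the shrinkage variance grows.  For the NB family the
#' dispersion is estimated by [estimate_dispersion()] at the fitted means.
#'
#' Isoform columns with zero total count carry no information and are dropped
#' with a warning before fitting; a gene with no non-zero column is an error.
#'
#' @param counts an [iso_counts()] matrix (a plain matrix is accepted).
#' @param family `"poisson"` or `"nb"`.
#' @param mode `"fixed"` (default) or `"random"`.
#' @param shrink_var shrinkage variance of the per-isoform baselines in
#'   `random` mode.  `NULL` (default) uses a method-of-moments estimate, the
#'   sample variance of the log column means (floored at 0.01).
#' @return A list of class `iso_nullfit`: `family`, `mu_hat`, `alpha_hat`
#'   (sum-to-zero in fixed mode), `gamma` (N x p fitted means), `phi_hat`
#'   (0 for Poisson), `mode`, `converged`, `kept` (indices of retained
#'   isoform columns), `counts` (the retained count block).
#' @examples
#' y <- iso_counts(matrix(c(2, 4, 6, 8), 4, 1), gene_id = "g")
#' fit_null(y, family = "poisson")$gamma[1, 1]  # 5, the sample mean
#' @export
fit_null <- function(counts, family = c("poisson", "nb"),
                     mode = c("fixed", "random"), shrink_var = NULL) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  y <- unclass(as.matrix(counts))
  keep <- which(colSums(y) > 0)
  if (length(keep) == 0L) {
    stop("degenerate gene: all counts are zero")
  }
  if (length(keep) < ncol(y)) {
    warning(sprintf("gene %s: dropping %d isoform(s) with zero total count",
                    gene_id_of(counts), ncol(y) - length(keep)))
    y <- y[, keep, drop = FALSE]
  }
  n <- nrow(y)
  p <- ncol(y)
  cm <- colMeans(y)

  converged <- TRUE
  if (mode == "fixed") {
    # intercept-only MLE for Poisson and NB alike: the column mean
    log_cm <- log(cm)
    mu_hat <- mean(log_cm)
    alpha_hat <- log_cm - mu_hat
    gamma <- matrix(cm, n, p, byrow = TRUE)
  } else {
    if (is.null(shrink_var)) {
      shrink_var <- max(stats::var(log(cm)), 0.01)
      if (!is.finite(shrink_var)) shrink_var <- 0.01
    }
    rf <- fit_null_random(y, family, shrink_var)
    mu_hat <- rf$mu
    alpha_hat <- rf$alpha
    gamma <- exp(outer(rep(0, n), alpha_hat, "+") + mu_hat)
    converged <- rf$converged
  }
  dimnames(gamma) <- dimnames(y)

  phi_hat <- 0
  if (family == "nb") {
    phi_hat <- estimate_dispersion(y, gamma)
  }
  structure(list(family = family, mu_hat = mu_hat, alpha_hat = alpha_hat,
                 gamma = gamma, phi_hat = phi_hat, mode = mode,
                 converged = converged, kept = keep, counts = y,
                 gene_id = gene_id_of(counts)),
            class = "iso_nullfit")
}

#' @export
print.iso_nullfit <- function(x, ...) {
  cat(sprintf("null fit (%s, %s mode): %d isoforms, mu_hat = %.4f, phi_hat = %.4g\n",
              x$family, x$mode, length(x$alpha_hat), x$mu_hat, x$phi_hat))
  invisible(x)
}

# Penalized Newton fit of log gamma_ij = mu + alpha_j with alpha_j shrunk by
# a N(0, shrink_var) penalty.  Expected-information updates; NB working
# weights gamma/(1+phi*gamma) with phi re-estimated between sweeps.
fit_null_random <- function(y, family, shrink_var, max_iter = 100L, tol = 1e-9) {
  n <- nrow(y)
  p <- ncol(y)
  cm <- colMeans(y)
  mu <- mean(log(cm))
  alpha <- rep(0, p)
  phi <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gamma <- exp(outer(rep(mu, n), alpha, "+"))
    if (family == "nb" && iter > 1L) {
      phi <- estimate_dispersion(y, gamma)
    }
    scl <- 1 + phi * gamma
    u <- (y - gamma) / scl          # score wrt the linear predictor
    w <- gamma / scl                # expected information weights
    g_mu <- sum(u)
    g_al <- colSums(u) - alpha / shrink_var
    sw <- colSums(w)
    # Hessian: [sum(w), sw'; sw, diag(sw) + I/shrink_var]
    H <- rbind(c(sum(sw), sw), cbind(sw, diag(sw + 1 / shrink_var, p)))
    step <- tryCatch(solve(H, c(g_mu, g_al)), error = function(e) NULL)
    if (is.null(step)) {
      step <- pseudo_inverse(H) %*% c(g_mu, g_al)
    }
    mu <- mu + step[1L]
    alpha <- alpha + step[-1L]
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, alpha = alpha, converged = converged)
}

#' Maximum-likelihood NB dispersion at fixed means
#'
#' Estimates the dispersion \eqn{\phi} of the NB variance function
#' \eqn{V(\gamma) = \gamma + \phi\gamma^2} by one-dimensional bounded
#' maximization of the NB log-likelihood over \eqn{\log\phi}, holding the
#' fitted means fixed.  Returns the lower bound (1e-8) when the Poisson fits
#' as well or better, e.g. for under-dispersed or constant data.
#'
#' @param counts count matrix (or [iso_counts()]).
#' @param gamma matrix of fitted means, same shape, all positive.
#' @param upper upper bound for `phi`.
#' @return Scalar `phi` in `[1e-8, upper]`.
#' @export
estimate_dispersion <- function(counts, gamma, upper = 1e4) {
  y <- as.vector(unclass(as.matrix(counts)))
  g <- as.vector(gamma)
  stopifnot(length(y) == length(g), all(g > 0))
  nll <- function(logphi) {
    -sum(stats::dnbinom(y, size = exp(-logphi), mu = g, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(log(PHI_LOWER), log(upper)))
  ll_opt <- -opt$objective
  ll_lower <- -nll(log(PHI_LOWER))
  if (ll_lower >= ll_opt - 1e-8) {
    return(PHI_LOWER)
  }
  exp(opt$minimum)
}

#' Per-observation weights of the score statistic
#'
#' For the log link the working quantities entering the score and its
#' information are, per observation with mean \eqn{\gamma}:
#' \eqn{\delta = 1/g'(\gamma) = \gamma},
#' \eqn{w = V(\gamma)^{-1}\delta^2},
#' \eqn{w_0 = w + e(y - \gamma)} with
#' \eqn{e = (V'g' + Vg'')/(V^2 g'^3)}.
#' Poisson (\eqn{V = \gamma}): \eqn{w = \gamma}, \eqn{e = 0}, \eqn{w_0 = w},
#' and the residual scaling \eqn{\Phi} is the identity.  NB
#' (\eqn{V = \gamma + \phi\gamma^2}): \eqn{w = \gamma/(1+\phi\gamma)},
#' \eqn{e = \phi\gamma/(1+\phi\gamma)^2},
#' \eqn{w_0 = \gamma/(1+\phi\gamma) + \phi\gamma(y-\gamma)/(1+\phi\gamma)^2},
#' and \eqn{\Phi} has diagonal \eqn{1/(1+\phi\gamma)}.  Every NB field
#' converges to its Poisson value as \eqn{\phi \to 0}.
#'
#' @param fit an `iso_nullfit` from [fit_null()].
#' @return List of N x p matrices: `delta`, `w`, `w0`, `e`, `phi_diag`.
#' @export
family_weights <- function(fit) {
  stopifnot(inherits(fit, "iso_nullfit"))
  gamma <- fit$gamma
  y <- fit$counts
  delta <- gamma
  if (fit$family == "poisson") {
    w <- gamma
    e <- array(0, dim(gamma))
    w0 <- w
    phi_diag <- array(1, dim(gamma))
  } else {
    phi <- fit$phi_hat
    scl <- 1 + phi * gamma
    w <- gamma / scl
    e <- phi * gamma / scl^2
    w0 <- w + e * (y - gamma)
    phi_diag <- 1 / scl
  }
  list(delta = delta, w = w, w0 = w0, e = e, phi_diag = phi_diag)
}
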