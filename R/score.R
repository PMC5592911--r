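#' Variance-component score statistic for one gene
#'
#' The score of the effect-variance \eqn{\tau^2} at the null fit.  In the
#' per-isoform form used here,
#' \deqn{U = \frac{1}{2}\Big(\sum_j \big(\sum_i x_i z_{ij}\big)^2
#'            - \sum_i x_i^2 \sum_j \hat w_{ij}\Big),}
#' where \eqn{z_{ij} = y_{ij} - \hat\gamma_{ij}} for Poisson and
#' \eqn{(y_{ij} - \hat\gamma_{ij})/(1 + \hat\phi\hat\gamma_{ij})} for NB, and
#' the trace weights are \eqn{\hat w = \hat\gamma} (Poisson) or \eqn{\hat w_0}
#' (NB).  This equals the dense quadratic-form expression
#' \eqn{\tfrac12(z^T X X^T z - \mathrm{tr}(\hat W X X^T))} over the stacked
#' Np-vector, exploiting the block structure of \eqn{X}.
#'
#' @param counts count block (used only for dimension checks; residuals come
#'   from `fit$counts`, which reflects any dropped zero columns).
#' @param fit `iso_nullfit` from [fit_null()].
#' @param x design vector (0/1 group labels in case-control use).
#' @return List of class `vct_score`: `U`, `quadratic_term`, `trace_term`.
#' @examples
#' y <- iso_counts(matrix(c(1, 3, 2, 6), 4, 1))
#' f <- fit_null(y, "poisson")
#' score_statistic(y, f, c(0, 0, 1, 1))$U  # -1
#' @export
score_statistic <- function(counts, fit, x) {
  stopifnot(inherits(fit, "iso_nullfit"))
  x <- check_design(x, fit$counts, require_varying = FALSE)
  fw <- family_weights(fit)
  z <- (fit$counts - fit$gamma) * fw$phi_diag
  tw <- if (fit$family == "poisson") fw$w else fw$w0
  q <- as.vector(crossprod(z, x))        # per-isoform sums of x_i z_ij
  quadratic <- sum(q^2)
  trace <- sum(x^2 * rowSums(tw))
  structure(list(U = (quadratic - trace) / 2,
                 quadratic_term = quadratic, trace_term = trace),
            class = "vct_score")
}

#' Second, third and fourth cumulants of the count distribution
#'
#' Exponential-family recursion \eqn{\kappa_{r+1} = V(\gamma)\,d\kappa_r/d\gamma}
#' from \eqn{\kappa_2 = V(\gamma)}: \eqn{\kappa_3 = V'V} and
#' \eqn{\kappa_4 = (V''V + V'^2)V}.  Poisson (\eqn{V=\gamma}) gives
#' \eqn{\kappa_2 = \kappa_3 = \kappa_4 = \gamma}; NB uses
#' \eqn{V = \gamma + \phi\gamma^2}.
#'
#' @param family `"poisson"` or `"nb"`.
#' @param gamma matrix (or vector) of means.
#' @param phi NB dispersion (ignored for Poisson).
#' @return List `kappa2`, `kappa3`, `kappa4`, each shaped like `gamma`.
#' @export
cumulants <- function(family = c("poisson", "nb"), gamma, phi = 0) {
  family <- match.arg(family)
  if (family == "poisson") {
    return(list(kappa2 = gamma, kappa3 = gamma, kappa4 = gamma))
  }
  V <- gamma + phi * gamma^2
  Vp <- 1 + 2 * phi * gamma
  Vpp <- 2 * phi
  list(kappa2 = V, kappa3 = Vp * V, kappa4 = (Vpp * V + Vp^2) * V)
}

#' Chi-square p-value for the score statistic
#'
#' Standardizes the score by the efficient information:
#' \eqn{\chi^2 = U^2/\tilde I}, referred to a 1-df chi-square upper tail
#' (default).  `mode = "one_sided"` instead returns the upper-tail normal
#' probability of \eqn{U/\sqrt{\tilde I}}, reflecting the one-sided nature of
#' variance-component alternatives.
#'
#' @param U score statistic.
#' @param I_tilde efficient information, must be positive.
#' @param mode `"chisq"` (default) or `"one_sided"`.
#' @return p-value in `[0, 1]`.
#' @export
theoretical_pvalue <- function(U, I_tilde, mode = c("chisq", "one_sided")) {
  mode <- match.arg(mode)
  if (!is.finite(I_tilde) || I_tilde <= 0) {
    stop("I_tilde must be positive")
  }
  if (mode == "chisq") {
    stats::pchisq(U^2 / I_tilde, df = 1, lower.tail = FALSE)
  } else {
    stats::pnorm(U / sqrt(I_tilde), lower.tail = FALSE)
  }
}

#' Permutation p-value for the score statistic
#'
#' The null fit does not involve the design, so the fitted means, scaled
#' residuals and trace weights are computed once; each permutation only
#' reshuffles the label vector and recomputes \eqn{U} by two matrix products.
#' The p-value uses the add-one convention, one-sided in \eqn{U}:
#' \eqn{p = (1 + \#\{b: U_b \ge U_{obs}\})/(B + 1)}; ties count as exceedances.
#'
#' @param counts count block (dimension check only; see [score_statistic()]).
#' @param fit `iso_nullfit`.
#' @param x design vector.
#' @param B number of permutations (default 5000).
#' @param seed optional integer seed for reproducible permutations.
#' @return List: `p`, `U_obs`, `U_perm` (length-B vector).
#' @export
permutation_pvalue <- function(counts, fit, x, B = 5000L, seed = NULL) {
  stopifnot(B >= 1L)
  x <- check_design(x, fit$counts)
  obs <- score_statistic(counts, fit, x)
  fw <- family_weights(fit)
  z <- (fit$counts - fit$gamma) * fw$phi_diag
  tvec <- rowSums(if (fit$family == "poisson") fw$w else fw$w0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  XP <- matrix(0, B, n)
  for (b in seq_len(B)) XP[b, ] <- x[sample.int(n)]
  quad <- rowSums((XP %*% z)^2)
  trace <- as.vector((XP^2) %*% tvec)
  U_perm <- (quad - trace) / 2
  p <- (1 + sum(U_perm >= obs$U)) / (B + 1)
  list(p = p, U_obs = obs$U, U_perm = U_perm)
}
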