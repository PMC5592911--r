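# Moore-Penrose pseudo-inverse via SVD; relative singular-value cutoff.
# The profiled information block is singular by construction (the intercept
# column of the augmented design is the sum of the isoform columns), so a
# generalized inverse is required, mirroring standard practice for singular
# information matrices.
pseudo_inverse <- function(M, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * max(sv$d, 0)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Element generators for the variance (R) and covariance (C) kernels of the
# score.  Per observation:
#   r_ii = w^4 delta^-4 kappa4 + 2 w^2 + e^2 kappa2 - 2 w^2 delta^-2 e kappa3
#   off-diagonal (same isoform, samples i != i'): 2 w_i w_i'
#   c_ii = w^3 delta^-3 kappa3 - e w delta^-1 kappa2
# which reduce for Poisson to r_ii = gamma + 2 gamma^2, c_ii = gamma.
rc_elements <- function(weights, cum) {
  w <- weights$w
  d <- weights$delta
  e <- weights$e
  r_diag <- (w / d)^4 * cum$kappa4 + 2 * w^2 + e^2 * cum$kappa2 -
    2 * w^2 / d^2 * e * cum$kappa3
  c_diag <- (w / d)^3 * cum$kappa3 - e * (w / d) * cum$kappa2
  list(r_diag = r_diag, c_diag = c_diag, w = w)
}

#' Efficient information for the variance component
#'
#' Builds the information of the score for \eqn{\tau^2} and profiles out the
#' nuisance parameters \eqn{\tilde\alpha = (\mu, \alpha)}:
#' \deqn{\tilde I = I_{\tau\tau} - I_{\tilde\alpha\tau}^T
#'       I_{\tilde\alpha\tilde\alpha}^{-} I_{\tilde\alpha\tau}.}
#' With \eqn{a_i = x_i^2} and per-isoform kernels \eqn{R_j} (diagonal
#' \eqn{r_{ii}}, off-diagonal \eqn{2 w_i w_{i'}}),
#' \eqn{I_{\tau\tau} = \tfrac14 \sum_j a^T R_j a} — which equals
#' \eqn{\mathrm{Var}(U)} for known parameters —
#' \eqn{I_{\tilde\alpha\tau} = \tfrac12 \tilde K^T C a} and
#' \eqn{I_{\tilde\alpha\tilde\alpha} = \tilde K^T W \tilde K}, the latter
#' singular by construction and inverted by pseudo-inverse.
#'
#' @param counts count block (dimension checks).
#' @param fit `iso_nullfit` from [fit_null()].
#' @param x design vector; must not be constant.
#' @return List of class `vct_information`: `I_tautau`, `I_at` (length p+1),
#'   `I_aa` ((p+1) x (p+1)), `I_tilde`, plus the `r_diag`/`c_diag` element
#'   matrices and the cumulants used.
#' @export
information <- function(counts, fit, x) {
  stopifnot(inherits(fit, "iso_nullfit"))
  x <- check_design(x, fit$counts)
  fw <- family_weights(fit)
  cum <- cumulants(fit$family, fit$gamma, fit$phi_hat)
  rc <- rc_elements(fw, cum)
  a <- x^2
  w <- fw$w

  # a' R_j a = sum_i a_i^2 r_ii + [(sum_i a_i w_ij)^2 - sum_i a_i^2 w_ij^2] * 2 / ... :
  # off-diagonal part: sum_{i != i'} a_i a_i' 2 w_i w_i'
  aw <- as.vector(crossprod(w, a))            # per isoform: sum_i a_i w_ij
  off <- 2 * (aw^2 - as.vector(crossprod(w^2, a^2)))
  I_tautau <- (sum(as.vector(crossprod(rc$r_diag, a^2))) + sum(off)) / 4

  ca <- as.vector(crossprod(rc$c_diag, a))    # per isoform: sum_i c_ii a_i
  I_at <- c(sum(ca), ca) / 2

  sw <- colSums(w)
  p <- ncol(w)
  I_aa <- rbind(c(sum(sw), sw), cbind(sw, diag(sw, p)))

  if (!all(is.finite(I_tautau), is.finite(I_at), is.finite(I_aa))) {
    stop("information overflow: degenerate fit")
  }
  correction <- drop(crossprod(I_at, pseudo_inverse(I_aa) %*% I_at))
  I_tilde <- I_tautau - correction
  structure(list(I_tautau = I_tautau, I_at = I_at, I_aa = I_aa,
                 I_tilde = I_tilde, r_diag = rc$r_diag, c_diag = rc$c_diag,
                 cumulants = cum),
            class = "vct_information")
}
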