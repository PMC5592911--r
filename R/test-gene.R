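#' Adaptive choice between the NB and Poisson assumptions
#'
#' Fits the NB null model; if the fit fails or the estimated dispersion is
#' negligible (below `phi_threshold`), the Poisson assumption is used.
#'
#' @param counts an [iso_counts()] block.
#' @param phi_threshold dispersion below which the Poisson is preferred.
#' @param mode null-fit mode passed to [fit_null()].
#' @return `"poisson"` or `"nb"`.
#' @export
choose_family <- function(counts, phi_threshold = 1e-3, mode = "fixed") {
  fit <- tryCatch(fit_null(counts, family = "nb", mode = mode),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) {
    # retry without the warning trap (zero columns warn but are handled)
    fit <- tryCatch(suppressWarnings(fit_null(counts, family = "nb", mode = mode)),
                    error = function(e) NULL)
  }
  if (is.null(fit) || !isTRUE(fit$converged) || fit$phi_hat < phi_threshold) {
    return("poisson")
  }
  "nb"
}

#' Test one gene for differential expression across its isoforms
#'
#' Runs the full single-gene pipeline: family selection (or a forced family),
#' null fit, score statistic, theoretical chi-square p-value, and (for
#' `B > 0`) the permutation p-value.  If the requested NB fit fails, the test
#' falls back to the Poisson assumption and flags it.
#'
#' @param counts an [iso_counts()] block.
#' @param x design vector (0/1 groups).
#' @param family `"auto"` (default), `"poisson"` or `"nb"`.
#' @param B permutations for the empirical null; `0` disables it.
#' @param seed optional integer seed for the permutations.
#' @param mode null-fit mode, `"fixed"` (default) or `"random"`.
#' @param phi_threshold see [choose_family()] (used when `family = "auto"`).
#' @param pvalue_mode reference for the theoretical p-value, `"chisq"` or
#'   `"one_sided"` (see [theoretical_pvalue()]).
#' @return List of class `vct_result`: `gene_id`, `U`, `quadratic_term`,
#'   `trace_term`, `I_tilde`, `chi2`, `p_theoretical`, `p_one_sided`,
#'   `p_empirical` (`NA` if `B = 0`), `family_used`, `fell_back`, `B`, `seed`,
#'   `p_isoforms_used`.
#' @examples
#' set.seed(1)
#' y <- iso_counts(matrix(rpois(80, 5), 40, 2), gene_id = "g1")
#' x <- rep(c(0, 1), each = 20)
#' test_gene(y, x, family = "poisson", B = 200, seed = 7)
#' @export
test_gene <- function(counts, x, family = c("auto", "poisson", "nb"),
                      B = 5000L, seed = NULL, mode = "fixed",
                      phi_threshold = 1e-3, pvalue_mode = "chisq") {
  family <- match.arg(family)
  x <- check_design(x, counts)
  fell_back <- FALSE
  if (family == "auto") {
    family <- choose_family(counts, phi_threshold = phi_threshold, mode = mode)
  }
  fit <- tryCatch(fit_null(counts, family = family, mode = mode),
                  error = function(e) {
                    if (grepl("degenerate gene", conditionMessage(e))) stop(e)
                    NULL
                  })
  if ((is.null(fit) || !isTRUE(fit$converged)) && family == "nb") {
    fell_back <- TRUE
    family <- "poisson"
    fit <- fit_null(counts, family = "poisson", mode = mode)
  }
  if (is.null(fit)) {
    fit <- fit_null(counts, family = family, mode = "fixed")
  }
  sc <- score_statistic(counts, fit, x)
  info <- information(counts, fit, x)
  chi2 <- sc$U^2 / info$I_tilde
  p_the <- theoretical_pvalue(sc$U, info$I_tilde, mode = pvalue_mode)
  p_one <- theoretical_pvalue(sc$U, info$I_tilde, mode = "one_sided")
  p_emp <- NA_real_
  if (B > 0L) {
    p_emp <- permutation_pvalue(counts, fit, x, B = B, seed = seed)$p
  }
  structure(list(gene_id = fit$gene_id, U = sc$U,
                 quadratic_term = sc$quadratic_term,
                 trace_term = sc$trace_term,
                 I_tilde = info$I_tilde, chi2 = chi2,
                 p_theoretical = p_the, p_one_sided = p_one,
                 p_empirical = p_emp, family_used = family,
                 fell_back = fell_back, B = as.integer(B), seed = seed,
                 p_isoforms_used = length(fit$alpha_hat)),
            class = "vct_result")
}

#' @export
print.vct_result <- function(x, ...) {
  cat(sprintf("vct_result: gene %s (%s, %d isoforms%s)\n", x$gene_id,
              x$family_used, x$p_isoforms_used,
              if (x$fell_back) ", fell back to poisson" else ""))
  cat(sprintf("  U = %.4f, I_tilde = %.4f, chi2 = %.4f\n", x$U, x$I_tilde, x$chi2))
  cat(sprintf("  p (theoretical chi-square, 1 df) = %.4g\n", x$p_theoretical))
  cat(sprintf("  p (one-sided normal)             = %.4g\n", x$p_one_sided))
  if (!is.na(x$p_empirical)) {
    cat(sprintf("  p (permutation, B = %d)          = %.4g\n", x$B, x$p_empirical))
  }
  invisible(x)
}
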