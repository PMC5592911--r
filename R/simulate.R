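# Deterministic per-gene seed derivation: two decoupled streams (data and
# permutations) per replicate, independent of execution order and always
# below 2^31.
mix_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed %% 2147483647L) + i * 48271 + stream * 1299721) %%
               2147483629)
}

#' Simulation scenario for the generative model
#'
#' One setting of the count-generating model used in the type-I-error and
#' power studies: per-isoform log-baselines \eqn{\alpha_j \sim N(0, s)},
#' per-isoform group effects \eqn{\beta_j \sim N(0, l)} (identically zero
#' under the null \eqn{l = 0}), and counts with mean
#' \eqn{\exp(M + \alpha_j + \beta_j x_i)} drawn Poisson or NB with
#' dispersion `phi`.
#'
#' @param N total samples (default 40, split `n_cases` cases / rest controls).
#' @param p number of isoforms.
#' @param s variance of the baselines \eqn{\alpha_j}.
#' @param l variance of the effects \eqn{\beta_j}; `0` gives a null gene.
#' @param exp_M baseline mean scale \eqn{\exp(M)}.
#' @param phi NB dispersion; ignored for the Poisson family.
#' @param family `"nb"` or `"poisson"`.
#' @param n_cases cases in the design (default balanced `N/2`).
#' @return List of class `vct_scenario`.
#' @export
vct_scenario <- function(N = 40L, p = 2L, s = 0.04, l = 0, exp_M = exp(2.5),
                         phi = 0.5, family = c("nb", "poisson"),
                         n_cases = NULL) {
  family <- match.arg(family)
  if (is.null(n_cases)) n_cases <- as.integer(N %/% 2L)
  stopifnot(s >= 0, l >= 0, phi >= 0, exp_M > 0, N >= 2, p >= 1,
            n_cases >= 1, n_cases < N)
  structure(list(N = as.integer(N), p = as.integer(p), s = s, l = l,
                 M = log(exp_M), exp_M = exp_M, phi = phi, family = family,
                 n_cases = as.integer(n_cases)),
            class = "vct_scenario")
}

#' @export
print.vct_scenario <- function(x, ...) {
  cat(sprintf("scenario: N=%d (%d cases), p=%d, s=%.2f, l=%.2f, exp(M)=%.2f, phi=%.2f, %s\n",
              x$N, x$n_cases, x$p, x$s, x$l, x$exp_M, x$phi, x$family))
  invisible(x)
}

#' Simulate one gene under a scenario
#'
#' Draws \eqn{\alpha_j \sim N(0, s)} and (for `l > 0`)
#' \eqn{\beta_j \sim N(0, l)}, forms the mean matrix
#' \eqn{\exp(M)\exp(\alpha_j + \beta_j x_i)} with `x` = `n_cases` ones then
#' zeros, and draws counts from the scenario family.  Effects are redrawn per
#' call: each simulated gene is an independent draw of the random-effects
#' model.
#'
#' @param scenario a [vct_scenario()].
#' @param seed integer seed (reproducible draws).
#' @param gene_id identifier for the resulting count block.
#' @return List of class `sim_gene`: `counts` ([iso_counts()]), `x`,
#'   `alpha_true`, `beta_true`, `scenario`.
#' @export
simulate_gene <- function(scenario, seed = NULL, gene_id = "sim_gene") {
  stopifnot(inherits(scenario, "vct_scenario"))
  if (!is.null(seed)) set.seed(seed)
  N <- scenario$N
  p <- scenario$p
  x <- c(rep(1, scenario$n_cases), rep(0, N - scenario$n_cases))
  alpha <- if (scenario$s > 0) stats::rnorm(p, 0, sqrt(scenario$s)) else rep(0, p)
  beta <- if (scenario$l > 0) stats::rnorm(p, 0, sqrt(scenario$l)) else rep(0, p)
  mu <- scenario$exp_M * exp(outer(x, beta) + rep(alpha, each = N))
  counts <- if (scenario$family == "poisson" || scenario$phi <= 0) {
    matrix(stats::rpois(N * p, mu), N, p)
  } else {
    matrix(stats::rnbinom(N * p, size = 1 / scenario$phi, mu = mu), N, p)
  }
  structure(list(counts = iso_counts(counts, gene_id = gene_id),
                 x = x, alpha_true = alpha, beta_true = beta,
                 scenario = scenario),
            class = "sim_gene")
}

#' Rejection-rate study over one scenario
#'
#' Simulates `reps` independent genes under `scenario`, tests each with
#' [test_gene()] (family forced to the scenario's family), and reports the
#' rejection proportions of the empirical (permutation) and theoretical
#' (chi-square) p-values at `alpha_level`, with binomial Monte-Carlo standard
#' errors.  Under `l = 0` the rates are type-I error; otherwise power.
#' Per-replicate seeds are derived deterministically from `seed`, so the
#' result is identical regardless of execution order.
#'
#' @param scenario a [vct_scenario()].
#' @param reps number of simulated genes.
#' @param alpha_level nominal significance level (default 0.05).
#' @param B permutations per gene; `0` skips the empirical null.
#' @param seed master seed.
#' @return List of class `scenario_result`: `scenario`, `reps`,
#'   `rejection_rate_emp`, `rejection_rate_the`, `mc_se_emp`, `mc_se_the`,
#'   `alpha_level`, `B`, and the vectors `p_emp`, `p_the`.
#' @export
run_scenario <- function(scenario, reps = 1000L, alpha_level = 0.05,
                         B = 1000L, seed = 1L) {
  stopifnot(reps >= 1L)
  p_emp <- rep(NA_real_, reps)
  p_the <- rep(NA_real_, reps)
  for (g in seq_len(reps)) {
    sim <- simulate_gene(scenario, seed = mix_seed(seed, g, 0L),
                         gene_id = paste0("sim", g))
    res <- suppressWarnings(
      test_gene(sim$counts, sim$x, family = scenario$family, B = B,
                seed = mix_seed(seed, g, 1L)))
    p_emp[g] <- res$p_empirical
    p_the[g] <- res$p_theoretical
  }
  rate_emp <- if (B > 0L) mean(p_emp < alpha_level) else NA_real_
  rate_the <- mean(p_the < alpha_level)
  mc_se <- function(r) if (is.na(r)) NA_real_ else sqrt(r * (1 - r) / reps)
  structure(list(scenario = scenario, reps = as.integer(reps),
                 rejection_rate_emp = rate_emp, rejection_rate_the = rate_the,
                 mc_se_emp = mc_se(rate_emp), mc_se_the = mc_se(rate_the),
                 alpha_level = alpha_level, B = as.integer(B),
                 p_emp = p_emp, p_the = p_the),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  reps = %d, B = %d, alpha = %.3f\n", x$reps, x$B, x$alpha_level))
  cat(sprintf("  rejection rate (empirical)   = %.4f (MC SE %.4f)\n",
              x$rejection_rate_emp, x$mc_se_emp))
  cat(sprintf("  rejection rate (theoretical) = %.4f (MC SE %.4f)\n",
              x$rejection_rate_the, x$mc_se_the))
  invisible(x)
}

#' Parse a flat scenario-grid configuration file
#'
#' Plain-text `key = v1, v2, ...` lines (`#` comments allowed).  Recognized
#' keys: `N`, `n_cases`, `p`, `s`, `l`, `exp_M`, `phi`, `family`.  The grid is
#' the Cartesian product of all supplied value lists; omitted keys take the
#' [vct_scenario()] defaults.
#'
#' @param path configuration file.
#' @return A data.frame with one row per scenario.
#' @export
parse_scenario_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  keys <- c("N", "n_cases", "p", "s", "l", "exp_M", "phi", "family")
  vals <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed grid line: ", ln)
    key <- trimws(parts[1])
    if (!key %in% keys) stop("unknown grid key: ", key)
    items <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    vals[[key]] <- if (key == "family") items else as.numeric(items)
  }
  if (length(vals) == 0L) stop("empty scenario grid")
  expand.grid(vals, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Run a grid of scenarios and return a tidy table
#'
#' @param grid data.frame from [parse_scenario_grid()] (or hand-built).
#' @param reps,alpha_level,B,seed passed to [run_scenario()]; each scenario
#'   uses a distinct seed derived from `seed`.
#' @return A data.frame, one row per scenario x method, with columns
#'   `N, p, s, l, exp_M, phi, family, method, reps, B, alpha, rejection_rate,
#'   mc_se`.
#' @export
run_scenario_grid <- function(grid, reps = 1000L, alpha_level = 0.05,
                              B = 1000L, seed = 1L) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- as.list(grid[i, , drop = FALSE])
    sc <- do.call(vct_scenario, args)
    res <- run_scenario(sc, reps = reps, alpha_level = alpha_level, B = B,
                        seed = mix_seed(seed, i, 2L))
    base <- data.frame(N = sc$N, p = sc$p, s = sc$s, l = sc$l,
                       exp_M = sc$exp_M, phi = sc$phi, family = sc$family,
                       reps = res$reps, B = res$B, alpha = alpha_level,
                       stringsAsFactors = FALSE)
    out[[i]] <- rbind(
      cbind(base, method = "empirical", rejection_rate = res$rejection_rate_emp,
            mc_se = res$mc_se_emp),
      cbind(base, method = "theoretical", rejection_rate = res$rejection_rate_the,
            mc_se = res$mc_se_the))
  }
  do.call(rbind, out)
}
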