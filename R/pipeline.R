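#' Read an isoform-level count table
#'
#' Tab-separated file with header columns `gene_id`, `isoform_id`, then one
#' column per sample.  Rows are grouped by gene in file order; every gene
#' shares the same sample set (the file's sample columns).  Fractional
#' expected counts are rounded half-to-even with a message; negative or
#' non-numeric entries are errors naming the offending row and column.
#'
#' @param path TSV file path.
#' @return Named list of [iso_counts()] blocks, one per gene, in file order.
#' @export
read_isoform_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "isoform_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), required)
  if (length(sample_cols) < 2L) stop("need at least 2 sample columns")
  if (anyDuplicated(df[, required])) {
    dup <- df[duplicated(df[, required]), required, drop = FALSE][1L, ]
    stop(sprintf("duplicate (gene, isoform) pair: (%s, %s)",
                 dup$gene_id, dup$isoform_id))
  }
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2, as.numeric))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at row %d, column %s",
                 bad[1], sample_cols[bad[2]]))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative count at row %d, column %s",
                 neg[1, 1], sample_cols[neg[1, 2]]))
  }
  frac <- abs(vals - round(vals)) > 1e-8
  if (any(frac)) {
    message(sprintf("rounded %d fractional expected-count value(s) half-to-even",
                    sum(frac)))
    vals <- round(vals)
  }
  genes <- unique(df$gene_id)
  out <- lapply(genes, function(g) {
    rows <- which(df$gene_id == g)
    iso_counts(t(vals[rows, , drop = FALSE]), gene_id = g,
               sample_ids = sample_cols, isoform_ids = df$isoform_id[rows])
  })
  names(out) <- genes
  out
}

#' Write isoform count blocks to a TSV
#'
#' Inverse of [read_isoform_counts()].
#'
#' @param genes named list of [iso_counts()] blocks.
#' @param path output TSV path.
#' @export
write_isoform_counts <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    data.frame(gene_id = attr(g, "gene_id"), isoform_id = colnames(g),
               t(unclass(g)), check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table into a 0/1 design vector
#'
#' TSV with columns `sample_id` and `condition`.  Conditions must be exactly
#' two levels (mapped to 0/1 in lexicographic order, reported via a message)
#' or already numeric 0/1.
#'
#' @param path TSV file path.
#' @param sample_ids sample order the design must be aligned to.
#' @return Numeric 0/1 vector aligned to `sample_ids`.
#' @export
read_phenotype <- function(path, sample_ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("phenotype file needs columns sample_id and condition")
  }
  idx <- match(sample_ids, df$sample_id)
  if (anyNA(idx)) {
    stop("phenotype file is missing sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  cond <- df$condition[idx]
  if (is.numeric(cond) && all(cond %in% c(0, 1))) {
    x <- as.numeric(cond)
  } else {
    lev <- sort(unique(as.character(cond)))
    if (length(lev) != 2L) {
      stop("condition must have exactly two levels, got: ",
           paste(lev, collapse = ", "))
    }
    message(sprintf("condition mapping: %s -> 0, %s -> 1", lev[1], lev[2]))
    x <- as.numeric(as.character(cond) == lev[2])
  }
  x
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]).
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @return Monotone q-values, all at most 1.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  stats::p.adjust(pvalues, method = "BH")
}

#' Test every gene of a dataset
#'
#' Reads the count and phenotype tables, applies [test_gene()] per gene with
#' deterministic per-gene seeds, adjusts for multiple testing over the
#' empirical p-values when `B > 0` (else the theoretical ones), and returns a
#' tidy per-gene table.  Genes whose counts are all zero appear as
#' `skipped_degenerate` rows without statistics; NB fits that fail are
#' reported `fell_back_poisson` with statistics from the Poisson fallback.
#' When `out` is given the table is written as TSV with a JSON run-metadata
#' sidecar (`<out>.meta.json`: config, seed, package version, skip/fallback
#' counts).
#'
#' @param counts_path isoform count TSV (see [read_isoform_counts()]).
#' @param pheno_path phenotype TSV (see [read_phenotype()]).
#' @param family,B,mode,phi_threshold passed to [test_gene()].
#' @param seed master seed; per-gene permutation seeds are derived from it.
#' @param alpha significance level recorded in the metadata.
#' @param adjust `"bh"` (default) or `"none"`.
#' @param min_mean optional pre-filter: drop genes whose overall mean count is
#'   below this threshold (off by default).
#' @param heterogeneous_only optional pre-filter: keep only genes (p >= 2)
#'   whose per-isoform case-minus-control mean differences are not all of one
#'   sign (off by default).
#' @param out optional output TSV path.
#' @return A data.frame with one row per input gene: `gene_id`,
#'   `p_isoforms_used`, `family_used`, `U`, `chi2`, `p_theoretical`,
#'   `p_empirical`, `q_value`, `status`.
#' @export
run_dataset <- function(counts_path, pheno_path, family = "auto",
                        B = 5000L, seed = 1L, alpha = 0.05, adjust = "bh",
                        mode = "fixed", phi_threshold = 1e-3,
                        min_mean = NULL, heterogeneous_only = FALSE,
                        out = NULL) {
  genes <- read_isoform_counts(counts_path)
  x <- read_phenotype(pheno_path, rownames(genes[[1]]))
  if (!is.null(min_mean) || heterogeneous_only) {
    keep <- vapply(genes, function(g) {
      ok <- TRUE
      if (!is.null(min_mean)) ok <- mean(g) >= min_mean
      if (ok && heterogeneous_only) {
        d <- colMeans(unclass(g)[x == 1, , drop = FALSE]) -
          colMeans(unclass(g)[x == 0, , drop = FALSE])
        ok <- ncol(g) >= 2L && min(d) < 0 && max(d) > 0
      }
      ok
    }, logical(1))
    genes <- genes[keep]
    if (length(genes) == 0L) stop("no genes pass the pre-filter")
  }
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    res <- tryCatch(
      suppressWarnings(test_gene(g, x, family = family, B = B,
                                 seed = mix_seed(seed, i, 3L), mode = mode,
                                 phi_threshold = phi_threshold)),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(gene_id = attr(g, "gene_id"),
                              p_isoforms_used = 0L,
                              family_used = NA_character_, U = NA_real_,
                              chi2 = NA_real_, p_theoretical = NA_real_,
                              p_empirical = NA_real_,
                              status = "skipped_degenerate",
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(gene_id = res$gene_id,
                              p_isoforms_used = res$p_isoforms_used,
                              family_used = res$family_used, U = res$U,
                              chi2 = res$chi2,
                              p_theoretical = res$p_theoretical,
                              p_empirical = res$p_empirical,
                              status = if (res$fell_back) "fell_back_poisson" else "ok",
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  p_for_adjust <- if (B > 0L) tab$p_empirical else tab$p_theoretical
  tab$q_value <- if (identical(adjust, "bh")) bh_adjust(p_for_adjust) else p_for_adjust
  tab <- tab[, c("gene_id", "p_isoforms_used", "family_used", "U", "chi2",
                 "p_theoretical", "p_empirical", "q_value", "status")]
  if (!is.null(out)) {
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(counts_path = counts_path, pheno_path = pheno_path,
                 family = family, B = B, seed = seed, alpha = alpha,
                 adjust = adjust, mode = mode, phi_threshold = phi_threshold,
                 version = as.character(utils::packageVersion("isovct")),
                 n_genes = nrow(tab),
                 n_skipped = sum(tab$status == "skipped_degenerate"),
                 n_fell_back = sum(tab$status == "fell_back_poisson"))
    jsonlite::write_json(meta, paste0(out, ".meta.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  tab
}
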