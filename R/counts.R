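#' Isoform-level count matrix for one gene
#'
#' Bundles the N x p count block of one gene (rows = samples, columns =
#' isoforms) with its identifiers.  All statistics in the package operate on
#' this container.
#'
#' @param counts numeric matrix, N samples x p isoforms; entries must be
#'   non-negative integers (integer-valued doubles are accepted).
#' @param gene_id single string naming the gene.
#' @param sample_ids character vector of length N; defaults to existing
#'   rownames or `sample1..sampleN`.
#' @param isoform_ids character vector of length p; defaults to existing
#'   colnames or `iso1..isop`.
#' @return An object of class `iso_counts`: the counts matrix with dimnames
#'   set and a `gene_id` attribute.
#' @examples
#' y <- iso_counts(matrix(rpois(12, 5), 4, 3), gene_id = "g1")
#' dim(y)
#' @export
iso_counts <- function(counts, gene_id = "gene", sample_ids = NULL,
                       isoform_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  if (nrow(counts) < 2L) {
    stop("need at least 2 samples")
  }
  if (ncol(counts) < 1L) {
    stop("need at least 1 isoform")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain undefined entries")
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral; round fractional expected counts first")
  }
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(isoform_ids)) {
    isoform_ids <- colnames(counts)
    if (is.null(isoform_ids)) isoform_ids <- paste0("iso", seq_len(ncol(counts)))
  }
  stopifnot(length(sample_ids) == nrow(counts),
            length(isoform_ids) == ncol(counts))
  dimnames(counts) <- list(sample_ids, isoform_ids)
  structure(counts, gene_id = as.character(gene_id), class = c("iso_counts", "matrix"))
}

#' @export
print.iso_counts <- function(x, ...) {
  cat(sprintf("iso_counts: gene %s, %d samples x %d isoforms\n",
              attr(x, "gene_id"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("... %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

# Coerce/validate a design vector against a count block.  Testing a constant
# design is undefined (the score is identically zero), hence the check.
check_design <- function(x, counts, require_varying = TRUE) {
  x <- as.numeric(x)
  if (length(x) != nrow(counts)) {
    stop("design vector length does not match the number of samples")
  }
  if (anyNA(x)) stop("design vector contains NA")
  if (require_varying && length(unique(x)) < 2L) {
    stop("design vector is constant; the test is undefined")
  }
  x
}

gene_id_of <- function(counts) {
  gid <- attr(counts, "gene_id")
  if (is.null(gid)) "gene" else gid
}
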