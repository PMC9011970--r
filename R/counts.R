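#' Validate and preprocess a microbiome count table
#'
#' Checks that a count table is a non-negative integer matrix, orients it
#' samples-by-taxa, drops taxa and samples that are entirely zero (with a
#' warning naming the dropped labels), and attaches an optional per-sample
#' covariate.
#'
#' @param counts A numeric matrix (or object coercible to one) of sequencing
#'   counts. By default rows are samples and columns are taxa.
#' @param taxa_are_rows Logical; set `TRUE` if the table is taxa-by-samples,
#'   in which case it is transposed (labels are reattached).
#' @param covariate Optional numeric vector with one value per sample (e.g. a
#'   binary group indicator coded 0/1). Subset along with any dropped samples.
#'
#' @return An object of class `zippca_counts`: a list with elements `counts`
#'   (n x p integer matrix), `sample_ids`, `taxon_ids` and `covariate`
#'   (`NULL` when absent).
#'
#' @examples
#' x <- matrix(rpois(12, 3), 3, 4)
#' X <- preprocess(x)
#' dim(X$counts)
#' @export
preprocess <- function(counts, taxa_are_rows = FALSE, covariate = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("count table must be numeric")
  }
  if (taxa_are_rows) {
    counts <- t(counts)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "counts must be non-negative integers; offending cell [%s, %s] = %s",
      rownames(counts)[i], colnames(counts)[j], format(counts[i, j])))
  }
  if (!is.null(covariate)) {
    if (length(covariate) != nrow(counts)) {
      stop("covariate length must equal the number of samples")
    }
    if (any(!is.finite(covariate))) stop("covariate must be finite")
  }

  zero_taxa <- colSums(counts) == 0
  if (any(zero_taxa)) {
    warning(sprintf("dropping %d all-zero taxa: %s", sum(zero_taxa),
                    paste(colnames(counts)[zero_taxa], collapse = ", ")))
    counts <- counts[, !zero_taxa, drop = FALSE]
  }
  zero_samples <- rowSums(counts) == 0
  if (any(zero_samples)) {
    warning(sprintf("dropping %d all-zero samples: %s", sum(zero_samples),
                    paste(rownames(counts)[zero_samples], collapse = ", ")))
    counts <- counts[!zero_samples, , drop = FALSE]
    if (!is.null(covariate)) covariate <- covariate[!zero_samples]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 samples and 2 taxa after filtering")
  }
  storage.mode(counts) <- "double"
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         taxon_ids = colnames(counts),
         covariate = covariate),
    class = "zippca_counts")
}

#' @export
print.zippca_counts <- function(x, ...) {
  cat(sprintf("zippca count matrix: %d samples x %d taxa (%.1f%% zeros)%s\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0),
              if (is.null(x$covariate)) "" else ", with covariate"))
  invisible(x)
}

## Accepts either a zippca_counts object or a raw matrix (which is validated).
as_zippca_counts <- function(X, covariate = NULL) {
  if (inherits(X, "zippca_counts")) {
    if (!is.null(covariate)) X$covariate <- covariate
    return(X)
  }
  preprocess(X, covariate = covariate)
}
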