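#' Ordination of microbiome samples via denoising
#'
#' Either uses the variational posterior means of the latent factors
#' directly (`method = "intrinsic"`), or first denoises the counts with the
#' fitted model and then applies an algorithm-based method to
#' `log2(1 + denoised)`: PCA (`method = "pca"`, column-centred) or t-SNE
#' (`method = "tsne"`, requires the optional Rtsne package; perplexity 30,
#' clipped to `(n - 1) / 3` for small n).
#'
#' @param X A `zippca_counts` object or count matrix.
#' @param method `"pca"`, `"intrinsic"` or `"tsne"`.
#' @param config A [fit_config()] used for the underlying fit.
#' @param d Number of ordination axes (must not exceed `config$k` for the
#'   intrinsic method).
#' @param fit Optional precomputed `zippca_fit` to reuse.
#' @return A list with `scores` (n x d), `method`, and `variance_explained`
#'   (PCA only).
#' @export
ordinate <- function(X, method = c("pca", "intrinsic", "tsne"),
                     config = fit_config(), d = 2, fit = NULL) {
  method <- match.arg(method)
  if (is.null(fit)) fit <- fit_zippca(as_zippca_counts(X), config)
  if (method == "intrinsic") {
    if (d > fit$config$k) {
      stop("d exceeds the latent dimension k of the fit")
    }
    return(list(scores = fit$varparams$m[, seq_len(d), drop = FALSE],
                method = method, variance_explained = NULL))
  }
  L <- log2(1 + denoised_matrix(fit))
  if (method == "pca") {
    pr <- stats::prcomp(L, center = TRUE, scale. = FALSE)
    d <- min(d, ncol(pr$x))
    ve <- pr$sdev[seq_len(d)]^2 / sum(pr$sdev^2)
    return(list(scores = pr$x[, seq_len(d), drop = FALSE],
                method = method, variance_explained = ve))
  }
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop("method 'tsne' requires the optional Rtsne package")
  }
  set.seed(fit$config$seed)
  perp <- min(30, floor((nrow(L) - 1) / 3))
  ts <- Rtsne::Rtsne(L, dims = d, perplexity = perp, check_duplicates = FALSE)
  sc <- ts$Y
  rownames(sc) <- rownames(L)
  list(scores = sc, method = method, variance_explained = NULL)
}

#' Differential-abundance testing via covariate-adjusted denoising
#'
#' Fits the covariate-adjusted ZIPPCA model, denoises the counts (retaining
#' the group effect), log-transforms the denoised matrix as
#' `log2(1 + x)`, applies a per-taxon Welch two-sample t-test
#' (unequal variances, Welch-Satterthwaite degrees of freedom), and adjusts
#' p-values with the Benjamini-Hochberg step-up procedure.
#'
#' @param X A `zippca_counts` with a binary (0/1) covariate, or a count
#'   matrix plus `covariate`.
#' @param config A [fit_config()] for the underlying fit.
#' @param fdr FDR threshold used to flag significant taxa.
#' @param covariate Optional covariate to attach to `X`.
#' @param fit Optional precomputed covariate-adjusted `zippca_fit`.
#' @return A data frame (one row per taxon) with columns `taxon_id`,
#'   `mean_log_group0`, `mean_log_group1`, `t_statistic`, `df`, `p_value`,
#'   `q_value`, `is_significant`.
#' @export
da_test <- function(X, config = fit_config(), fdr = 0.05,
                    covariate = NULL, fit = NULL) {
  X <- as_zippca_counts(X, covariate = covariate)
  v <- X$covariate
  if (is.null(v)) stop("a binary group covariate is required")
  if (!all(v %in% c(0, 1))) stop("covariate must be coded 0/1")
  if (min(table(v)) < 2) stop("each group needs at least 2 samples")
  if (is.null(fit)) fit <- fit_zippca_cov(X, config)
  L <- log2(1 + denoised_matrix(fit))
  welch_table(L, v, fdr)
}

## Per-taxon Welch t-tests with BH correction on a samples-by-taxa matrix.
welch_table <- function(L, v, fdr) {
  g0 <- L[v == 0, , drop = FALSE]
  g1 <- L[v == 1, , drop = FALSE]
  n0 <- nrow(g0); n1 <- nrow(g1)
  m0 <- colMeans(g0); m1 <- colMeans(g1)
  v0 <- apply(g0, 2, stats::var); v1 <- apply(g1, 2, stats::var)
  se2 <- v0 / n0 + v1 / n1
  tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v0^2 / (n0^2 * (n0 - 1)) + v1^2 / (n1^2 * (n1 - 1))),
               n0 + n1 - 2)
  pval <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    warning(sprintf("%d taxa have zero variance in both groups; p = 1",
                    sum(degen)))
    pval[degen] <- 1
  }
  qval <- stats::p.adjust(pval, method = "BH")
  ids <- colnames(L)
  if (is.null(ids)) ids <- paste0("taxon", seq_along(pval))
  data.frame(taxon_id = ids, mean_log_group0 = m0, mean_log_group1 = m1,
             t_statistic = tstat, df = df, p_value = pval, q_value = qval,
             is_significant = qval <= fdr, row.names = NULL)
}

#' Compare alpha diversity between two groups
#'
#' Computes per-sample Shannon and Simpson indices from a composition
#' matrix and compares the two groups with two-sided Wilcoxon rank-sum
#' tests (exact when sample sizes permit and there are no ties).
#'
#' @param comp A row-stochastic composition matrix.
#' @param groups Binary group labels, one per sample (at least one sample
#'   per group; two distinct groups required).
#' @return A data frame with one row per index: group medians and the
#'   Wilcoxon p-value.
#' @export
compare_alpha <- function(comp, groups) {
  if (length(unique(groups)) < 2) {
    stop("need two groups to compare alpha diversity")
  }
  ad <- alpha_diversity(comp)
  lv <- sort(unique(groups))
  one <- function(vals) {
    p <- suppressWarnings(
      stats::wilcox.test(vals[groups == lv[1]], vals[groups == lv[2]],
                         alternative = "two.sided")$p.value)
    if (is.nan(p)) p <- 1   # complete ties: no evidence either way
    c(median_group0 = stats::median(vals[groups == lv[1]]),
      median_group1 = stats::median(vals[groups == lv[2]]),
      p_value = p)
  }
  out <- rbind(shannon = one(ad$shannon), simpson = one(ad$simpson))
  data.frame(index = rownames(out), out, row.names = NULL)
}
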