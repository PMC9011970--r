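#' Symmetric Procrustes error between two matrices
#'
#' Both matrices are column-centred and rescaled to unit Frobenius norm;
#' the second is then optimally rotated (and isotropically rescaled) onto
#' the first via the SVD `M_t' Mhat_t = U D V'`, and the squared Frobenius
#' norm of the residual is returned. Invariant to orthogonal rotation,
#' isotropic scaling and column translation of either argument.
#'
#' @param M,Mhat Numeric matrices of identical shape with at least 2 rows.
#' @return Scalar error in `[0, 2]`.
#' @export
procrustes_error <- function(M, Mhat) {
  M <- as.matrix(M); Mhat <- as.matrix(Mhat)
  if (!all(dim(M) == dim(Mhat))) stop("shape mismatch")
  if (nrow(M) < 2) stop("need at least 2 rows")
  std <- function(A) {
    A <- sweep(A, 2, colMeans(A))
    nrm <- sqrt(sum(A^2))
    if (nrm == 0) stop("matrix is zero after centring; error undefined")
    A / nrm
  }
  Mt <- std(M); Ht <- std(Mhat)
  sv <- svd(crossprod(Mt, Ht))
  rot <- (sum(sv$d) / sum(Ht^2)) * Ht %*% sv$v %*% t(sv$u)
  sum((Mt - rot)^2)
}

#' Orthogonal projection distance between column spaces
#'
#' Squared Frobenius norm of the difference of the orthogonal projectors
#' onto the column spaces of the two matrices,
#' `||M (M'M)^-1 M' - Mhat (Mhat'Mhat)^-1 Mhat'||_F^2`. Invariant to
#' right-multiplication by any invertible matrix.
#'
#' @param M,Mhat Numeric matrices with the same number of rows and full
#'   column rank.
#' @return Scalar distance in `[0, 2k]` for k columns.
#' @export
projection_distance <- function(M, Mhat) {
  M <- as.matrix(M); Mhat <- as.matrix(Mhat)
  if (nrow(M) != nrow(Mhat)) stop("matrices must have the same number of rows")
  proj <- function(A) {
    qa <- qr(A)
    if (qa$rank < ncol(A)) stop("matrix is rank deficient")
    Q <- qr.Q(qa)[, seq_len(ncol(A)), drop = FALSE]
    tcrossprod(Q)
  }
  sum((proj(M) - proj(Mhat))^2)
}

#' Composition estimation errors
#'
#' Four discrepancy measures between a true and an estimated row-stochastic
#' composition matrix: the Frobenius norm error, the average
#' Kullback-Leibler divergence, and the mean squared errors of the per-sample
#' Shannon and Simpson indices (natural log throughout).
#'
#' @param rho True compositions (rows sum to one, entries non-negative).
#' @param rhohat Estimated compositions (rows sum to one, entries strictly
#'   positive, as produced by the composition estimators).
#' @return Named vector `c(frobenius, kl, shannon_mse, simpson_mse)`.
#' @export
composition_errors <- function(rho, rhohat) {
  rho <- as.matrix(rho); rhohat <- as.matrix(rhohat)
  if (!all(dim(rho) == dim(rhohat))) stop("shape mismatch")
  if (any(abs(rowSums(rho) - 1) > 1e-6) ||
      any(abs(rowSums(rhohat) - 1) > 1e-6)) {
    stop("rows must sum to one")
  }
  if (any(rhohat <= 0)) {
    stop("estimated compositions must be strictly positive ",
         "(use the model-based composition estimators, not raw proportions)")
  }
  n <- nrow(rho)
  sh <- function(A) rowSums(xlogx(A))          # sum rho log rho (negated Shannon)
  si <- function(A) rowSums(A^2)
  kl <- sum(rho * (log(pmax(rho, .Machine$double.xmin)) - log(rhohat)) *
              (rho > 0)) / n
  c(frobenius = sqrt(sum((rhohat - rho)^2)),
    kl = kl,
    shannon_mse = mean((sh(rhohat) - sh(rho))^2),
    simpson_mse = mean((si(rho) - si(rhohat))^2))
}

#' Data recovery errors between a signal matrix and a denoised matrix
#'
#' Three agreement criteria: mean squared error on the `log2(1 + x)` scale;
#' mean taxon-wise Pearson correlation; and the Wasserstein distance between
#' the standardized mean community compositions, computed by sorting the
#' per-taxon standardized means `r_j = sum_i x_ij / (n * sd(x_.j))` of each
#' matrix and averaging absolute differences of the order statistics. Taxa
#' with zero sample variance in either matrix are skipped for the Pearson
#' and Wasserstein criteria (with a warning). Sample standard deviations use
#' the n - 1 denominator.
#'
#' @param signal True signal matrix (n x p, non-negative).
#' @param denoised Denoised/imputed matrix of the same shape.
#' @return Named vector `c(log_mse, pearson, wasserstein)`.
#' @export
recovery_errors <- function(signal, denoised) {
  signal <- as.matrix(signal); denoised <- as.matrix(denoised)
  if (!all(dim(signal) == dim(denoised))) stop("shape mismatch")
  n <- nrow(signal)
  c1 <- mean((log2(signal + 1) - log2(denoised + 1))^2)
  sd_s <- apply(signal, 2, stats::sd)
  sd_d <- apply(denoised, 2, stats::sd)
  keep <- sd_s > 0 & sd_d > 0
  if (!all(keep)) {
    warning(sprintf("skipping %d zero-variance taxa in Pearson/Wasserstein",
                    sum(!keep)))
  }
  if (!any(keep)) {
    return(c(log_mse = c1, pearson = NA_real_, wasserstein = NA_real_))
  }
  s <- signal[, keep, drop = FALSE]
  d <- denoised[, keep, drop = FALSE]
  cors <- vapply(seq_len(ncol(s)),
                 function(j) stats::cor(s[, j], d[, j]), numeric(1))
  r_s <- colSums(s) / (n * sd_s[keep])
  r_d <- colSums(d) / (n * sd_d[keep])
  c(log_mse = c1,
    pearson = mean(cors),
    wasserstein = mean(abs(sort(r_s) - sort(r_d))))
}
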