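## Expected log-mean pieces shared by the denoising and composition
## estimators: eta_ij = beta0_j (+ gamma_j v_i) + m_i' beta_j and the
## quadratic term q_ij = beta_j' Sigma_i beta_j / 2. Library-size effects
## alpha_i0 are deliberately excluded.
signal_terms <- function(fit) {
  th <- fit$params; de <- fit$varparams
  lin <- tcrossprod(de$m, th$B) + rep(th$beta0, each = nrow(de$m))
  if (!is.null(th$gamma)) {
    v <- fit$data$covariate
    if (is.null(v)) stop("covariate-adjusted fit but no covariate stored")
    lin <- lin + outer(v, th$gamma)
  }
  quad <- 0.5 * tcrossprod(de$S, th$B^2)
  list(lin = lin, quad = quad)
}

#' Empirical-Bayes denoised abundance matrix
#'
#' Posterior mean of the latent signal matrix under the fitted variational
#' posterior:
#' `xhat_ij = (1 - pi_ij) * exp(beta0_j + gamma_j v_i + m_i' beta_j +
#' beta_j' Sigma_i beta_j / 2)`.
#' Sample-specific library-size effects `alpha_i0` are removed, so denoised
#' values are on a common scale across samples; the covariate effect (if the
#' fit is covariate-adjusted) is retained so group differences survive
#' denoising.
#'
#' @param fit A `zippca_fit`.
#' @return An n x p non-negative matrix with sample and taxon dimnames.
#' @export
denoised_matrix <- function(fit) {
  stopifnot(inherits(fit, "zippca_fit"))
  st <- signal_terms(fit)
  out <- (1 - fit$varparams$pi) * exp(pmin(st$lin + st$quad, 700))
  dimnames(out) <- list(fit$data$sample_ids, fit$data$taxon_ids)
  out
}

#' Underlying composition estimate (Poisson-multinomial link)
#'
#' Row-wise softmax of the expected log-means:
#' `rho_ij = exp(beta0_j + m_i'beta_j + beta_j'Sigma_i beta_j/2) /
#' sum_k exp(...)`. Valid for either family; rows sum to one and all
#' entries are strictly positive.
#'
#' @param fit A `zippca_fit`.
#' @return An n x p row-stochastic matrix with attribute
#'   `estimator = "poi"`.
#' @export
composition_poi <- function(fit) {
  stopifnot(inherits(fit, "zippca_fit"))
  st <- signal_terms(fit)
  eta <- st$lin + st$quad
  eta <- eta - apply(eta, 1, max)             # log-sum-exp guard
  num <- exp(eta)
  rho <- num / rowSums(num)
  if (any(!is.finite(rho))) stop("non-finite composition estimate")
  dimnames(rho) <- list(fit$data$sample_ids, fit$data$taxon_ids)
  attr(rho, "estimator") <- "poi"
  rho
}

#' Underlying composition estimate with overdispersion correction
#'
#' Negative binomial variant built from the gamma-Poisson representation of
#' the NB distribution: the estimate is proportional to
#' `{exp(beta0_j + m_i'beta_j + beta_j'Sigma_i beta_j/2) + phi_j} / nu_ij`
#' with `nu_ij = 1 + phi_j * exp(-beta0_j - m_i'beta_j +
#' beta_j'Sigma_i beta_j/2)`, normalized within each sample.
#'
#' @param fit A `zippca_fit` with family `"zinb"`.
#' @return An n x p row-stochastic matrix with attribute
#'   `estimator = "nb"`.
#' @export
composition_nb <- function(fit) {
  stopifnot(inherits(fit, "zippca_fit"))
  if (fit$config$family != "zinb" || is.null(fit$params$phi)) {
    stop("composition_nb requires a zinb fit with estimated phi")
  }
  st <- signal_terms(fit)
  n <- nrow(st$lin)
  phim <- matrix(fit$params$phi, n, ncol(st$lin), byrow = TRUE)
  num <- exp(pmin(st$lin + st$quad, 700)) + phim
  nu <- 1 + phim * exp(pmin(-st$lin + st$quad, 700))
  w <- num / nu
  rho <- w / rowSums(w)
  if (any(!is.finite(rho))) stop("non-finite composition estimate")
  dimnames(rho) <- list(fit$data$sample_ids, fit$data$taxon_ids)
  attr(rho, "estimator") <- "nb"
  rho
}

#' Alpha diversity from a composition matrix
#'
#' Shannon entropy `-sum_j rho_ij log(rho_ij)` (natural log) and the Simpson
#' concentration index `sum_j rho_ij^2` for each sample.
#'
#' @param comp A row-stochastic composition matrix with strictly positive
#'   entries (e.g. from [composition_nb()]).
#' @return A data frame with columns `sample_id`, `shannon`, `simpson`.
#' @examples
#' rho <- matrix(0.25, 2, 4)
#' alpha_diversity(rho)  # shannon = log(4), simpson = 0.25
#' @export
alpha_diversity <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0)) stop("composition entries must be strictly positive")
  if (any(abs(rowSums(comp) - 1) > 1e-8)) {
    stop("composition rows must sum to one")
  }
  ids <- rownames(comp)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(comp)))
  data.frame(sample_id = ids,
             shannon = -rowSums(comp * log(comp)),
             simpson = rowSums(comp^2),
             row.names = NULL)
}
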