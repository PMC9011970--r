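## Internal numerics -----------------------------------------------------------

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  d <- -abs(a - b)
  m + log1p(exp(d))
}

xlogx <- function(x) {
  out <- x * log(x)
  out[x <= 0] <- 0
  out
}

row_matrix <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

## Variational expectations of the count log-density, cellwise.
##
## For the negative binomial family (mean mu, shape phi, variance
## mu + mu^2/phi) the intractable term E_q[log(phi + mu_ij)] is bounded above
## by log(phi + E_q[mu_ij]) (Jensen), giving a closed-form lower bound that
## reduces exactly to the Poisson bound as phi -> Inf.
## U = E_q[log mu], t = Var_q[log mu]/2, so E_q[mu] = exp(U + t).
## Hot path: the cellwise work lives in compiled code (src/count_terms.cpp).
count_terms <- function(x, U, t, phi, family, grad = FALSE, lgx1 = NULL) {
  if (is.null(lgx1)) lgx1 <- lgamma(x + 1)
  if (family == "zinb") {
    count_terms_nb_cpp(x, U, t, phi, lgx1, grad)
  } else {
    count_terms_pois_cpp(x, U, t, lgx1, grad)
  }
}

## Expected log-mean matrix given parameter pieces; alpha0 recycles down
## columns (column-major), beta0 across rows.
linpred <- function(alpha0, beta0, B, m, gamma = NULL, v = NULL) {
  U <- tcrossprod(m, B) + rep(beta0, each = nrow(m))
  U <- U + alpha0
  if (!is.null(gamma)) U <- U + outer(v, gamma)
  U
}

## Density -------------------------------------------------------------------

#' Zero-inflated negative binomial log density
#'
#' Log of `eta * 1[x = 0] + (1 - eta) * NB(x; mu, phi)` where the negative
#' binomial has mean `mu` and shape `phi` (variance `mu + mu^2/phi`).
#' Arguments are recycled to a common length.
#'
#' @param x Non-negative integer counts.
#' @param mu Positive means.
#' @param phi Positive shape parameters; the Poisson limit is `phi -> Inf`.
#' @param eta Zero-inflation probabilities in `[0, 1]`.
#' @return Log densities, one per element.
#' @examples
#' zinb_log_pmf(0, mu = 2, phi = 1, eta = 0.3)  # log(0.3 + 0.7/3)
#' @export
zinb_log_pmf <- function(x, mu, phi, eta) {
  nn <- max(length(x), length(mu), length(phi), length(eta))
  x <- rep_len(x, nn); mu <- rep_len(mu, nn)
  phi <- rep_len(phi, nn); eta <- rep_len(eta, nn)
  if (any(x < 0 | x != round(x))) stop("x must be non-negative integers")
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be positive")
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]")
  lnb <- stats::dnbinom(x, size = phi, mu = mu, log = TRUE)
  out <- ifelse(eta < 1, log1p(-eta) + lnb, -Inf)
  at0 <- x == 0 & eta > 0
  out[at0] <- logaddexp(log(eta[at0]),
                        ifelse(eta[at0] < 1,
                               log1p(-eta[at0]) + lnb[at0], -Inf))
  out
}

## ELBO ----------------------------------------------------------------------

elbo_core <- function(x, params, varparams, family, zero_inflation = TRUE,
                      lgx1 = NULL) {
  m <- varparams$m; S <- varparams$S; pi <- varparams$pi
  U <- linpred(params$alpha0, params$beta0, params$B, m,
               params$gamma, params$v)
  t <- 0.5 * tcrossprod(S, params$B^2)
  ct <- count_terms(x, U, t, params$phi, family, lgx1 = lgx1)
  W <- 1 - pi
  val <- sum(W * ct$L) + 0.5 * sum(log(S) - m^2 - S + 1)
  if (zero_inflation) {
    lin <- outer(params$c, params$tau, "+")
    val <- val +
      sum(pi * stats::plogis(lin, log.p = TRUE) +
            W * stats::plogis(-lin, log.p = TRUE)) -
      sum(xlogx(pi) + xlogx(W))
  }
  val
}

#' Evidence lower bound of a ZIPPCA model
#'
#' Computes the mean-field variational lower bound on the marginal
#' log-likelihood for given model and variational parameters. The
#' variational family is `q(z_ij) = Bern(pi_ij)`, `q(f_i) = N(m_i, diag(S_i))`.
#'
#' @param X A `zippca_counts` object or count matrix.
#' @param params List with `c`, `tau`, `alpha0`, `beta0`, `B` (p x k), `phi`
#'   (length p, `zinb` only) and optionally `gamma` plus the covariate `v`.
#' @param varparams List with `m` (n x k), `S` (n x k, positive), `pi`
#'   (n x p, zero wherever the count is positive).
#' @param family `"zinb"` or `"zip"`.
#' @return The scalar lower bound.
#' @export
elbo_zippca <- function(X, params, varparams, family = c("zinb", "zip")) {
  family <- match.arg(family)
  X <- as_zippca_counts(X)
  x <- X$counts
  n <- nrow(x); p <- ncol(x); k <- ncol(params$B)
  stopifnot(length(params$alpha0) == n, length(params$beta0) == p,
            nrow(params$B) == p)
  if (!all(dim(varparams$m) == c(n, k)) || !all(dim(varparams$S) == c(n, k)) ||
      !all(dim(varparams$pi) == c(n, p))) {
    stop("variational parameter dimensions do not match the data")
  }
  if (any(varparams$pi[x > 0] != 0)) {
    stop("pi must be exactly 0 wherever the observed count is positive")
  }
  if (any(varparams$S <= 0)) stop("S must be positive")
  if (family == "zinb" && (is.null(params$phi) || any(params$phi <= 0))) {
    stop("zinb family requires positive phi")
  }
  if (!is.null(params$gamma) && is.null(params$v)) {
    params$v <- X$covariate
    if (is.null(params$v)) stop("gamma given but no covariate available")
  }
  val <- elbo_core(x, params, varparams, family)
  if (!is.finite(val)) {
    stop("non-finite ELBO; parameter ranges: ",
         paste(vapply(params[c("alpha0", "beta0", "phi")], function(z)
           if (is.null(z)) "NULL" else paste(range(z), collapse = ".."),
           character(1)), collapse = " / "))
  }
  val
}

## Configuration -------------------------------------------------------------

#' Fitting configuration for ZIPPCA models
#'
#' @param family Count family: `"zinb"` (negative binomial) or `"zip"`
#'   (Poisson).
#' @param k Latent dimension (default 2, the usual ordination choice).
#' @param max_iter Maximum number of outer coordinate-ascent iterations.
#' @param tol Convergence tolerance on the relative ELBO change.
#' @param seed Integer recorded in outputs; fitting itself is deterministic.
#' @param use_covariate Include a per-taxon covariate coefficient `gamma_j`
#'   in the log-mean.
#' @param trace Print one line per outer iteration.
#' @param fixed_phi Optional positive scalar; freezes all NB shapes at this
#'   value instead of estimating them.
#' @param zero_inflation Set `FALSE` to drop the zero-inflation component
#'   entirely (plain NB/Poisson factor model).
#' @param inner_maxit Iteration cap for each block's quasi-Newton solve.
#' @return A `zippca_config` list.
#' @export
fit_config <- function(family = c("zinb", "zip"), k = 2, max_iter = 200,
                       tol = 1e-6, seed = 1L, use_covariate = FALSE,
                       trace = FALSE, fixed_phi = NULL, zero_inflation = TRUE,
                       inner_maxit = 15) {
  family <- match.arg(family)
  stopifnot(k >= 1, max_iter >= 1, tol > 0, inner_maxit >= 1)
  if (!is.null(fixed_phi)) stopifnot(fixed_phi > 0)
  structure(list(family = family, k = as.integer(k),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), use_covariate = use_covariate,
                 trace = trace, fixed_phi = fixed_phi,
                 zero_inflation = zero_inflation,
                 inner_maxit = as.integer(inner_maxit)),
            class = "zippca_config")
}

## Initialization ------------------------------------------------------------

#' Deterministic starting values for a ZIPPCA fit
#'
#' Library-size effects start at centred log row sums; taxon intercepts at
#' log mean relative abundances; scores and loadings at a rank-k truncated
#' SVD of the column-centred log2(1 + counts); posterior variances at 1;
#' zero-inflation posteriors at 0.5 on observed zeros (0 elsewhere); NB
#' shapes at 1; logit zero-inflation effects at clipped empirical zero
#' fractions.
#'
#' @param X A `zippca_counts` object or count matrix.
#' @param config A `zippca_config`.
#' @return List with elements `params` and `varparams`.
#' @export
initialize_zippca <- function(X, config = fit_config()) {
  X <- as_zippca_counts(X)
  x <- X$counts
  n <- nrow(x); p <- ncol(x); k <- config$k
  if (k >= min(n, p)) stop("k must be smaller than min(n, p)")
  N <- rowSums(x)
  alpha0 <- log(N) - mean(log(N))
  rel <- x / N
  beta0 <- log(colMeans(rel) + 1e-6)
  gamma <- NULL
  L <- log2(1 + x)
  if (config$use_covariate) {
    ## start gamma at the observed group log-fold-changes of relative
    ## abundances and take the group effect out of the matrix handed to the
    ## SVD; otherwise the factors swallow the group structure at the start
    ## and the fit struggles to reattribute it to gamma later
    v <- X$covariate
    if (is.null(v)) stop("config requests a covariate but none is attached")
    vc <- v - mean(v)
    if (sum(vc^2) == 0) stop("covariate is constant; gamma is unidentifiable")
    gm <- apply(rel, 2, function(col) {
      cf <- stats::coef(stats::lm.fit(cbind(1, vc), log(col + 1e-6)))
      cf[2]
    })
    gamma <- gm - mean(gm)
    L <- L - outer(vc, gamma) * log2(exp(1))
  }
  Lc <- sweep(L, 2, colMeans(L))
  sv <- svd(Lc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  # canonical sign: largest-magnitude loading of each axis is positive, so
  # the start point is equivariant under taxon relabelling
  sgn <- vapply(seq_len(k), function(l) {
    v <- sv$v[, l]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  sv$u <- sweep(sv$u, 2, sgn, "*")
  sv$v <- sweep(sv$v, 2, sgn, "*")
  m <- sv$u * sqrt(n)                         # unit-variance-ish scores
  B <- sv$v * rep(d / sqrt(n), each = p)
  if (any(d == 0)) {
    B[, d == 0] <- 0
  }
  S <- matrix(1, n, k)
  pi0 <- matrix(0, n, p)
  if (config$zero_inflation) pi0[x == 0] <- 0.5
  clip <- function(z) pmin(pmax(z, -5), 5)
  cvec <- clip(stats::qlogis(pmin(pmax(rowMeans(x == 0), 1e-3), 1 - 1e-3)))
  cvec <- cvec - mean(cvec)
  tau <- clip(stats::qlogis(pmin(pmax(colMeans(x == 0), 1e-3), 1 - 1e-3)))
  phi <- if (config$family == "zinb") {
    if (is.null(config$fixed_phi)) rep(1, p) else rep(config$fixed_phi, p)
  } else NULL
  list(params = list(c = cvec, tau = tau, alpha0 = alpha0, beta0 = beta0,
                     B = B, phi = phi, gamma = gamma),
       varparams = list(m = m, S = S, pi = pi0))
}

## Fitting -------------------------------------------------------------------

## Closed-form update of the zero-inflation posteriors: at observed zeros
## logit(pi) = logit(eta) - L0 where L0 is the count-term bound at x = 0.
pi_update <- function(x, params, family) {
  U <- linpred(params$alpha0, params$beta0, params$B, params$mv,
               params$gamma, params$v)
  t <- 0.5 * tcrossprod(params$Sv, params$B^2)
  b <- U + t
  if (family == "zinb") {
    n <- nrow(x)
    lphim <- row_matrix(log(params$phi), n)
    L0 <- -row_matrix(params$phi, n) * logaddexp(0, b - lphim)
  } else {
    L0 <- -exp(pmin(b, 700))
  }
  lin <- outer(params$c, params$tau, "+")
  pi <- stats::plogis(lin - L0)
  pi[x > 0] <- 0
  pi
}

## One guarded L-BFGS-B maximization of a block; returns the new parameter
## vector, falling back to the start if the solver failed to improve.
block_solve <- function(par, fn, gr, lower, upper, maxit) {
  f0 <- fn(par)
  res <- tryCatch(
    stats::optim(par, fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e7)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) ||
      res$value > f0 + 1e-10 * abs(f0)) {
    return(par)
  }
  res$par
}

#' Fit a ZIPPCA model by mean-field variational inference
#'
#' Block coordinate ascent on the evidence lower bound: the zero-inflation
#' posteriors `pi` are updated in closed form (and forced to 0 at positive
#' counts), then the logit zero-inflation effects `(c, tau)`, the per-sample
#' block `(alpha_i0, m_i, S_i)` and the per-taxon block
#' `(beta_0j, [gamma_j], beta_j, [phi_j])` are each maximized by bounded
#' quasi-Newton steps on unconstrained reparameterizations (log S, log phi).
#' Every accepted update is guarded so the ELBO never decreases. After
#' convergence the sample effects `alpha0` and `c` are recentred to mean
#' zero, with compensating shifts into `beta0` and `tau`.
#'
#' @param X A `zippca_counts` object or count matrix (validated via
#'   [preprocess()]).
#' @param config A [fit_config()] object.
#' @return A `zippca_fit` list: `params`, `varparams`, `elbo_trace`,
#'   `converged`, `n_iter`, `config`, `data`, `diagnostics`.
#' @examples
#' sim <- simulate_zippca(sim_config(scenario = "M1", n = 30, p = 15, seed = 1))
#' fit <- fit_zippca(sim$counts, fit_config(k = 2, max_iter = 20))
#' fit$converged
#' @export
fit_zippca <- function(X, config = fit_config()) {
  X <- as_zippca_counts(X)
  x <- X$counts
  n <- nrow(x); p <- ncol(x); k <- config$k
  family <- config$family
  zi <- config$zero_inflation
  v <- NULL
  if (config$use_covariate) {
    v <- X$covariate
    if (is.null(v)) stop("config requests a covariate but none is attached")
    if (stats::sd(v) == 0) {
      stop("covariate is constant; gamma is unidentifiable")
    }
  }

  init <- initialize_zippca(X, config)
  th <- init$params
  de <- init$varparams
  th$v <- v
  lgx1 <- lgamma(x + 1)
  fixed_phi <- !is.null(config$fixed_phi) || family == "zip"

  lower_ls <- log(1e-8); upper_ls <- log(1e4)
  lower_lp <- log(1e-4); upper_lp <- log(1e6)
  bnd <- 30

  state_elbo <- function() elbo_core(x, th, de, family, zi, lgx1)

  ## --- sample block: (alpha0, m, logS), separable over samples -------------
  sample_pack <- function() c(th$alpha0, de$m, log(de$S))
  sample_obj <- function(par, grad = FALSE) {
    a <- par[seq_len(n)]
    m <- matrix(par[n + seq_len(n * k)], n, k)
    S <- exp(matrix(par[n + n * k + seq_len(n * k)], n, k))
    U <- linpred(a, th$beta0, th$B, m, th$gamma, v)
    t <- 0.5 * tcrossprod(S, th$B^2)
    ct <- count_terms(x, U, t, th$phi, family, grad, lgx1)
    W <- 1 - de$pi
    f <- sum(W * ct$L) + 0.5 * sum(log(S) - m^2 - S + 1)
    if (!grad) return(-f)
    WdU <- W * ct$dU
    da <- rowSums(WdU)
    dm <- WdU %*% th$B - m
    dS <- 0.5 * (W * ct$dt) %*% (th$B^2) + 0.5 * (1 / S - 1)
    -c(da, dm, dS * S)
  }
  sample_lower <- c(rep(-bnd, n), rep(-bnd, n * k), rep(lower_ls, n * k))
  sample_upper <- c(rep(bnd, n), rep(bnd, n * k), rep(upper_ls, n * k))

  ## --- taxon block: (beta0, [gamma], B, [logphi]), separable over taxa -----
  taxon_pack <- function() {
    out <- c(th$beta0, if (!is.null(th$gamma)) th$gamma, th$B)
    if (family == "zinb" && !fixed_phi) out <- c(out, log(th$phi))
    out
  }
  taxon_unpack <- function(par) {
    i <- 0
    beta0 <- par[seq_len(p)]; i <- p
    gamma <- NULL
    if (!is.null(th$gamma)) { gamma <- par[i + seq_len(p)]; i <- i + p }
    B <- matrix(par[i + seq_len(p * k)], p, k); i <- i + p * k
    phi <- th$phi
    if (family == "zinb" && !fixed_phi) phi <- exp(par[i + seq_len(p)])
    list(beta0 = beta0, gamma = gamma, B = B, phi = phi)
  }
  taxon_obj <- function(par, grad = FALSE) {
    u <- taxon_unpack(par)
    U <- linpred(th$alpha0, u$beta0, u$B, de$m, u$gamma, v)
    t <- 0.5 * tcrossprod(de$S, u$B^2)
    ct <- count_terms(x, U, t, u$phi, family, grad, lgx1)
    W <- 1 - de$pi
    f <- sum(W * ct$L)
    if (!grad) return(-f)
    WdU <- W * ct$dU
    Wdt <- W * ct$dt
    g <- c(colSums(WdU),
           if (!is.null(u$gamma)) as.vector(crossprod(WdU, v)),
           crossprod(WdU, de$m) + u$B * crossprod(Wdt, de$S))
    if (family == "zinb" && !fixed_phi) {
      g <- c(g, u$phi * colSums(W * ct$dphi))
    }
    -g
  }
  ntx <- p + (if (config$use_covariate) p else 0) + p * k +
    (if (family == "zinb" && !fixed_phi) p else 0)
  taxon_lower <- rep(-bnd, ntx)
  taxon_upper <- rep(bnd, ntx)
  if (family == "zinb" && !fixed_phi) {
    idx <- (ntx - p + 1):ntx
    taxon_lower[idx] <- lower_lp
    taxon_upper[idx] <- upper_lp
  }

  ## --- zero-inflation block: (c, tau) --------------------------------------
  zi_obj <- function(par, grad = FALSE) {
    cc <- par[seq_len(n)]; tt <- par[n + seq_len(p)]
    lin <- outer(cc, tt, "+")
    f <- sum(de$pi * stats::plogis(lin, log.p = TRUE) +
               (1 - de$pi) * stats::plogis(-lin, log.p = TRUE))
    if (!grad) return(-f)
    diff <- de$pi - stats::plogis(lin)
    -c(rowSums(diff), colSums(diff))
  }

  neg_fn <- function(f) list(fn = function(p) f(p, FALSE),
                             gr = function(p) f(p, TRUE))

  ## warm-up: settle the posterior scales against the SVD start before any
  ## loading update. S starts at 1, which is far too diffuse for count data;
  ## without this the quadratic penalty beta_j' Sigma_i beta_j can crush the
  ## loadings to zero in the first sweep (a degenerate stationary point).
  o <- neg_fn(sample_obj)
  par <- block_solve(sample_pack(), o$fn, o$gr,
                     sample_lower, sample_upper, 200)
  th$alpha0 <- par[seq_len(n)]
  de$m <- matrix(par[n + seq_len(n * k)], n, k)
  de$S <- exp(matrix(par[n + n * k + seq_len(n * k)], n, k))

  elbo0 <- state_elbo()
  trace <- elbo0
  converged <- FALSE
  iter <- 0

  while (iter < config$max_iter) {
    iter <- iter + 1

    if (zi) {
      th$mv <- de$m; th$Sv <- de$S
      de$pi <- pi_update(x, th, family)
      th$mv <- NULL; th$Sv <- NULL

      o <- neg_fn(zi_obj)
      par <- block_solve(c(th$c, th$tau), o$fn, o$gr,
                         rep(-bnd, n + p), rep(bnd, n + p),
                         config$inner_maxit)
      th$c <- par[seq_len(n)]; th$tau <- par[n + seq_len(p)]
    }

    o <- neg_fn(sample_obj)
    par <- block_solve(sample_pack(), o$fn, o$gr,
                       sample_lower, sample_upper, config$inner_maxit)
    th$alpha0 <- par[seq_len(n)]
    de$m <- matrix(par[n + seq_len(n * k)], n, k)
    de$S <- exp(matrix(par[n + n * k + seq_len(n * k)], n, k))

    ## exact invariance recentring: a mean (and, with a covariate, a group
    ## trend) in the scores can be absorbed into the intercepts (and gamma)
    ## without changing the likelihood, while strictly reducing the prior
    ## cost of m. Without this move, block ascent crawls along the flat
    ## valley and group signal lingers in the factors, leaking into taxa
    ## without true effects.
    for (l in seq_len(k)) {
      if (is.null(v)) {
        a <- mean(de$m[, l]); d <- 0
      } else {
        cf <- stats::coef(stats::lm.fit(cbind(1, v), de$m[, l]))
        a <- cf[1]; d <- cf[2]
      }
      de$m[, l] <- de$m[, l] - a - if (is.null(v)) 0 else d * v
      th$beta0 <- th$beta0 + a * th$B[, l]
      if (!is.null(th$gamma)) th$gamma <- th$gamma + d * th$B[, l]
    }

    o <- neg_fn(taxon_obj)
    par <- block_solve(taxon_pack(), o$fn, o$gr,
                       taxon_lower, taxon_upper, config$inner_maxit)
    u <- taxon_unpack(par)
    th$beta0 <- u$beta0; th$gamma <- u$gamma; th$B <- u$B; th$phi <- u$phi

    ## gamma is identified only up to a constant absorbed by alpha0 (a
    ## shared shift of all gamma_j is a per-group sample effect); pin it to
    ## mean zero every sweep, moving the shift into alpha0 (ELBO-invariant).
    if (!is.null(th$gamma)) {
      g0 <- mean(th$gamma)
      th$gamma <- th$gamma - g0
      th$alpha0 <- th$alpha0 + g0 * v
    }

    e <- state_elbo()
    if (e < trace[length(trace)] - 1e-8 * abs(trace[length(trace)])) {
      stop(sprintf("ELBO decreased (%.10g -> %.10g): implementation bug",
                   trace[length(trace)], e))
    }
    rel <- abs(e - trace[length(trace)]) / abs(trace[length(trace)])
    trace <- c(trace, e)
    if (config$trace) {
      message(sprintf("iter %3d  elbo %.6f  rel %.3g", iter, e, rel))
    }
    if (rel < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("ZIPPCA fit did not converge in %d iterations", iter))
  }

  ## identifiability recentring: mean-zero sample effects
  ma <- mean(th$alpha0)
  th$alpha0 <- th$alpha0 - ma
  th$beta0 <- th$beta0 + ma
  if (zi) {
    mc <- mean(th$c)
    th$c <- th$c - mc
    th$tau <- th$tau + mc
  }

  diagnostics <- list(
    phi_at_bound = if (family == "zinb")
      sum(th$phi <= 1e-4 * (1 + 1e-6) | th$phi >= 1e6 * (1 - 1e-6)) else 0L)

  rownames(de$m) <- rownames(de$S) <- X$sample_ids
  rownames(de$pi) <- X$sample_ids
  colnames(de$pi) <- X$taxon_ids
  rownames(th$B) <- X$taxon_ids
  names(th$beta0) <- names(th$tau) <- X$taxon_ids
  if (!is.null(th$phi)) names(th$phi) <- X$taxon_ids
  if (!is.null(th$gamma)) names(th$gamma) <- X$taxon_ids
  names(th$alpha0) <- names(th$c) <- X$sample_ids
  th$v <- NULL

  structure(list(params = th, varparams = de, elbo_trace = trace,
                 converged = converged, n_iter = iter, config = config,
                 data = X, diagnostics = diagnostics),
            class = "zippca_fit")
}

#' Fit a covariate-adjusted ZIPPCA model
#'
#' Same fitting procedure as [fit_zippca()] with the log-mean extended to
#' `alpha_i0 + beta_0j + gamma_j v_i + f_i' beta_j`; the per-taxon covariate
#' coefficients `gamma_j` are estimated jointly with the other parameters.
#' This is the model behind covariate-adjusted denoising and the
#' differential-abundance pipeline.
#'
#' @inheritParams fit_zippca
#' @param covariate Optional covariate vector; defaults to the one attached
#'   to `X`.
#' @return A `zippca_fit` with `params$gamma` populated.
#' @export
fit_zippca_cov <- function(X, config = fit_config(), covariate = NULL) {
  X <- as_zippca_counts(X, covariate = covariate)
  if (is.null(X$covariate)) stop("a covariate is required")
  config$use_covariate <- TRUE
  fit_zippca(X, config)
}

#' @export
print.zippca_fit <- function(x, ...) {
  cat(sprintf(
    "ZIPPCA fit (%s, k = %d): %d x %d, ELBO %.3f, %d iterations%s\n",
    x$config$family, x$config$k, nrow(x$data$counts), ncol(x$data$counts),
    x$elbo_trace[length(x$elbo_trace)], x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}
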