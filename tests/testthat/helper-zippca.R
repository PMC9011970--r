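# Shared helpers: oracles and small utilities, independent of the package's
# own computational paths wherever they are used as references.

# F1 score of a flagged set against binary truth labels.
f1_score <- function(flag, truth) {
  tp <- sum(flag & truth == 1)
  fp <- sum(flag & truth == 0)
  fn <- sum(!flag & truth == 1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# Brute-force Benjamini-Hochberg step-up: reject the i smallest p-values
# where i is the largest index with p_(i) <= i * alpha / m.
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  i <- max(c(0, which(ps <= seq_len(m) * alpha / m)))
  rej <- rep(FALSE, m)
  if (i > 0) rej[o[seq_len(i)]] <- TRUE
  rej
}

# Mean silhouette width for 2-D scores with known labels (euclidean).
silhouette_mean <- function(scores, labels) {
  D <- as.matrix(dist(scores))
  mean(vapply(seq_len(nrow(D)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(D)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Importance-sampling estimate of the marginal log-likelihood of a fitted
# ZIPPCA model (proposal = the variational posterior q), with 3-SE slack
# returned alongside. Only for tiny instances (k = 1).
is_loglik <- function(fit, x, draws = 1e5, seed = 1) {
  th <- fit$params
  de <- fit$varparams
  fam <- fit$config$family
  n <- nrow(x); p <- ncol(x)
  set.seed(seed)
  total <- 0; se2 <- 0
  for (i in seq_len(n)) {
    f <- rnorm(draws, de$m[i, 1], sqrt(de$S[i, 1]))
    lpx <- dnorm(f, 0, 1, log = TRUE) -
      dnorm(f, de$m[i, 1], sqrt(de$S[i, 1]), log = TRUE)
    for (j in seq_len(p)) {
      eta <- plogis(th$c[i] + th$tau[j])
      mu <- exp(th$alpha0[i] + th$beta0[j] + f * th$B[j, 1])
      lcond <- if (fam == "zinb") {
        dnbinom(x[i, j], size = th$phi[j], mu = mu, log = TRUE)
      } else {
        dpois(x[i, j], mu, log = TRUE)
      }
      pij <- de$pi[i, j]
      if (x[i, j] > 0 || pij == 0) {
        lpx <- lpx + log(1 - eta) + lcond
      } else {
        z <- rbinom(draws, 1, pij)
        lp <- ifelse(z == 1, log(eta), log(1 - eta) + lcond)
        lq <- ifelse(z == 1, log(pij), log1p(-pij))
        lpx <- lpx + lp - lq
      }
    }
    mx <- max(lpx)
    w <- exp(lpx - mx)
    total <- total + mx + log(mean(w))
    se2 <- se2 + var(w) / (draws * mean(w)^2)
  }
  list(loglik = total, se = sqrt(se2))
}

# Hand-built zippca_fit object for formula-level oracles.
fake_fit <- function(params, varparams, family = "zinb", covariate = NULL) {
  n <- nrow(varparams$m); p <- nrow(params$B)
  structure(list(
    params = params, varparams = varparams,
    elbo_trace = 0, converged = TRUE, n_iter = 0,
    config = fit_config(family = family),
    data = list(sample_ids = paste0("s", seq_len(n)),
                taxon_ids = paste0("t", seq_len(p)),
                covariate = covariate)),
    class = "zippca_fit")
}

# Fast fitting configuration for tests.
quick_cfg <- function(...) {
  fit_config(max_iter = 40, tol = 1e-5, ...)
}
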