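test_that("zinb_log_pmf matches closed forms, limits, and normalization", {
  # pure zero-inflation: mass 1 at zero
  expect_equal(zinb_log_pmf(0, mu = 2, phi = 1, eta = 1), 0)
  # Poisson limit at large shape: log Poisson(3; 3) = 3 log 3 - 3 - log 6
  expect_equal(zinb_log_pmf(3, mu = 3, phi = 1e8, eta = 0),
               3 * log(3) - 3 - log(6), tolerance = 1e-6)
  expect_equal(zinb_log_pmf(3, mu = 3, phi = 1e8, eta = 0),
               dpois(3, 3, log = TRUE), tolerance = 1e-6)
  # NB(0; mu = 2, phi = 1) = 1/3, so density at zero is 0.3 + 0.7/3
  expect_equal(zinb_log_pmf(0, mu = 2, phi = 1, eta = 0.3),
               log(0.3 + 0.7 / 3))
  # mixture is a proper pmf
  expect_equal(sum(exp(zinb_log_pmf(0:2000, mu = 2, phi = 1, eta = 0.3))),
               1, tolerance = 1e-10)
  expect_error(zinb_log_pmf(-1, 1, 1, 0), "non-negative")
  expect_error(zinb_log_pmf(1, 1, 1, 1.2), "eta")
  expect_error(zinb_log_pmf(1, -1, 1, 0), "positive")
})

make_tiny <- function(seed = 5, n = 6, p = 4, k = 1) {
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = n, p = p, k = k, seed = seed, depth = 60)))
  sim
}

test_that("ELBO is additive over samples and drops masked count terms", {
  sim <- make_tiny()
  x <- sim$counts$counts
  n <- nrow(x); p <- ncol(x)
  init <- initialize_zippca(sim$counts, fit_config(k = 1))
  th <- init$params; de <- init$varparams
  e1 <- elbo_zippca(sim$counts, th, de, "zinb")

  # duplicating every sample (data and variational rows) doubles the ELBO
  x2 <- rbind(x, x); rownames(x2) <- paste0("r", seq_len(2 * n))
  th2 <- th
  th2$c <- rep(th$c, 2); th2$alpha0 <- rep(th$alpha0, 2)
  de2 <- list(m = rbind(de$m, de$m), S = rbind(de$S, de$S),
              pi = rbind(de$pi, de$pi))
  e2 <- elbo_zippca(preprocess(x2), th2, de2, "zinb")
  expect_equal(e2, 2 * e1, tolerance = 1e-12)

  # cells with pi = 1 contribute only Bernoulli prior/entropy terms: with a
  # zeroed column fully masked, its count parameters are inert
  x0 <- x; x0[, 1] <- 0
  Xm <- structure(list(counts = x0, sample_ids = rownames(x0),
                       taxon_ids = colnames(x0), covariate = NULL),
                  class = "zippca_counts")
  dem <- de
  dem$pi[x0 > 0] <- 0
  dem$pi[, 1] <- 1
  tha <- th; tha$phi[1] <- 0.37
  thb <- th; thb$phi[1] <- 42
  expect_equal(elbo_zippca(Xm, tha, dem, "zinb"),
               elbo_zippca(Xm, thb, dem, "zinb"))

  # contract violations error out
  expect_error(elbo_zippca(sim$counts, th,
                           list(m = de$m[-1, , drop = FALSE], S = de$S,
                                pi = de$pi), "zinb"),
               "dimensions")
  depos <- de; depos$pi[which(x > 0)[1]] <- 0.5
  expect_error(elbo_zippca(sim$counts, th, depos, "zinb"), "positive")
})

test_that("zinb ELBO with huge fixed phi reproduces the zip ELBO", {
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = 30, p = 15, k = 2, seed = 8, depth = 800)))
  fit <- suppressWarnings(fit_zippca(sim$counts, quick_cfg(family = "zip")))
  th <- fit$params
  e_zip <- elbo_zippca(sim$counts, th, fit$varparams, "zip")
  th$phi <- rep(1e6, ncol(sim$counts$counts))
  e_nb <- elbo_zippca(sim$counts, th, fit$varparams, "zinb")
  expect_lt(abs(e_nb - e_zip) / abs(e_zip), 1e-3)
})

test_that("fitting is deterministic, monotone, and respects the pi contract", {
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = 30, p = 15, k = 2, seed = 2, depth = 500)))
  cfg <- fit_config(k = 2, max_iter = 25, tol = 1e-6)
  f1 <- suppressWarnings(fit_zippca(sim$counts, cfg))
  f2 <- suppressWarnings(fit_zippca(sim$counts, cfg))
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  tr <- f1$elbo_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  expect_true(all(f1$varparams$pi[sim$counts$counts > 0] == 0))
  expect_true(all(is.finite(unlist(f1$params[c("c", "tau", "alpha0",
                                               "beta0", "B", "phi")]))))
  # identifiability recentring
  expect_equal(mean(f1$params$alpha0), 0, tolerance = 1e-12)
  expect_equal(mean(f1$params$c), 0, tolerance = 1e-12)
})

test_that("with no zeros the fit reduces to a plain NB factor model", {
  # high-depth draw without zero inflation: every count positive
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = 20, p = 8, k = 1, seed = 31,
               zero_inflation_level = 0, phi = 8, depth = 50000,
               library_size_spread = 0.2)))
  x <- sim$counts$counts
  expect_true(min(x) > 0)
  cfg_zi <- fit_config(k = 1, max_iter = 40, tol = 1e-6)
  cfg_nb <- fit_config(k = 1, max_iter = 40, tol = 1e-6,
                       zero_inflation = FALSE)
  fz <- suppressWarnings(fit_zippca(sim$counts, cfg_zi))
  fn <- suppressWarnings(fit_zippca(sim$counts, cfg_nb))
  expect_true(all(fz$varparams$pi == 0))
  ez <- tail(fz$elbo_trace, 1); en <- tail(fn$elbo_trace, 1)
  expect_lt(abs(ez - en) / abs(en), 1e-4)
})

test_that("permuting taxa permutes the fitted taxon parameters", {
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = 20, p = 8, k = 2, seed = 12, depth = 300)))
  x <- sim$counts$counts
  perm <- c(4, 1, 7, 2, 3, 8, 5, 6)[seq_len(ncol(x))]
  # equivariance is exact in exact arithmetic; in floating point the two
  # optimization paths only coincide near the optimum, so compare
  # well-converged fits at honest tolerances
  cfg <- fit_config(k = 2, max_iter = 150, tol = 1e-7)
  fa <- suppressWarnings(fit_zippca(preprocess(x), cfg))
  fb <- suppressWarnings(fit_zippca(preprocess(x[, perm]), cfg))
  expect_equal(unname(fb$params$beta0), unname(fa$params$beta0[perm]),
               tolerance = 0.02)
  expect_equal(unname(fb$params$tau), unname(fa$params$tau[perm]),
               tolerance = 0.05)
  expect_lt(procrustes_error(fa$params$B[perm, ], fb$params$B), 0.01)
  expect_true(all(abs(log(fb$params$phi / fa$params$phi[perm])) < 0.3))
})

test_that("initialization honours its stated contracts", {
  sim <- make_tiny(seed = 9, n = 10, p = 6, k = 2)
  ini <- initialize_zippca(sim$counts, fit_config(k = 2))
  x <- sim$counts$counts
  expect_true(all(ini$varparams$pi[x > 0] == 0))
  expect_true(all(ini$varparams$pi[x == 0] == 0.5))
  expect_true(all(ini$varparams$S == 1))
  # constant positive matrix: no structure left after centring
  flat <- matrix(7, 8, 5, dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  inif <- initialize_zippca(preprocess(flat), fit_config(k = 2))
  expect_equal(max(abs(inif$params$B)), 0, tolerance = 1e-10)
  expect_equal(max(abs(inif$params$alpha0)), 0, tolerance = 1e-10)
  # truncated-SVD reconstruction error is non-increasing in k
  L <- log2(1 + x); Lc <- sweep(L, 2, colMeans(L))
  errs <- vapply(1:3, function(k) {
    sv <- svd(Lc, nu = k, nv = k)
    sum((Lc - sv$u %*% diag(sv$d[1:k], k) %*% t(sv$v))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("covariate-adjusted fits recover effect signs and reject degenerate designs", {
  sim <- trim_sim(simulate_da(
    sim_config("M7", n = 100, p = 20, k = 2, seed = 21, effect_size = 5,
               da_fraction = 0.3)))
  fit <- suppressWarnings(fit_zippca_cov(sim$counts, quick_cfg(k = 2)))
  expect_false(is.null(fit$params$gamma))
  da <- sim$da_labels == 1
  sign_match <- mean(sign(fit$params$gamma[da]) == sign(sim$theta$gamma[da]))
  expect_gt(sign_match, 0.8)

  x <- sim$counts$counts
  expect_error(fit_zippca_cov(preprocess(x, covariate = rep(0, nrow(x))),
                              quick_cfg(k = 2)),
               "constant")
  expect_error(fit_zippca_cov(preprocess(x), quick_cfg(k = 2)), "covariate")
})
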