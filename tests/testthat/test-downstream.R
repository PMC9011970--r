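test_that("Welch/BH stage matches a brute-force step-up oracle", {
  set.seed(11)
  n <- 12
  v <- rep(c(0, 1), each = n / 2)
  L <- matrix(rnorm(n * 8), n, 8)
  L[v == 1, 1:2] <- L[v == 1, 1:2] + 3   # two strong effects
  colnames(L) <- paste0("t", 1:8)
  tab <- zippca:::welch_table(L, v, fdr = 0.05)
  # q <= alpha flags exactly the brute-force BH rejection set
  expect_identical(tab$is_significant, bh_reject(tab$p_value, 0.05))
  expect_true(all(diff(tab$q_value[order(tab$p_value)]) >= -1e-12))
  expect_true(all(tab$q_value >= tab$p_value))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # per-taxon values agree with stats::t.test Welch output
  tt <- t.test(L[v == 1, 3], L[v == 0, 3])
  expect_equal(tab$t_statistic[3], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(tab$df[3], unname(tt$parameter), tolerance = 1e-10)
  expect_equal(tab$p_value[3], tt$p.value, tolerance = 1e-10)
})

test_that("the testing stage is exact under the null and label-symmetric", {
  # identical data in both groups: all t statistics 0, nothing flagged
  half <- matrix(rpois(30, 5), 5, 6)
  L <- log2(1 + rbind(half, half))
  v <- rep(c(0, 1), each = 5)
  tab <- zippca:::welch_table(L, v, fdr = 0.05)
  expect_true(all(tab$t_statistic == 0))
  expect_true(all(!tab$is_significant))

  # swapping group labels flips t and preserves p and q
  set.seed(3)
  L2 <- matrix(rnorm(60), 10, 6)
  t1 <- zippca:::welch_table(L2, v, 0.05)
  t2 <- zippca:::welch_table(L2, 1 - v, 0.05)
  expect_equal(t2$t_statistic, -t1$t_statistic, tolerance = 1e-12)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-12)
  expect_equal(t2$q_value, t1$q_value, tolerance = 1e-12)

  # zero-variance taxa get p = 1 with a warning
  L3 <- cbind(L2, 7)
  expect_warning(t3 <- zippca:::welch_table(L3, v, 0.05), "zero variance")
  expect_equal(t3$p_value[7], 1)
})

test_that("da_test validates its inputs and returns a full table", {
  sim <- trim_sim(simulate_da(
    sim_config("M7", n = 40, p = 12, k = 2, seed = 33, effect_size = 5,
               da_fraction = 0.25)))
  tab <- suppressWarnings(da_test(sim$counts, quick_cfg(k = 2)))
  expect_identical(nrow(tab), ncol(sim$counts$counts))
  expect_true(all(c("taxon_id", "t_statistic", "df", "p_value", "q_value",
                    "is_significant") %in% names(tab)))
  expect_identical(tab$is_significant, bh_reject(tab$p_value, 0.05))

  x <- sim$counts$counts
  expect_error(da_test(preprocess(x)), "covariate")
  expect_error(da_test(preprocess(x, covariate = rep(c(0, 2), 20)),
                       quick_cfg()), "0/1")
  expect_error(da_test(preprocess(x, covariate = c(1, rep(0, 39))),
                       quick_cfg()), "at least 2")
})

test_that("group alpha-diversity comparison reproduces exact rank-sum p-values", {
  # six compositions with strictly increasing Shannon diversity
  p <- 6
  mix <- function(w) w * rep(1 / p, p) + (1 - w) * c(1 - 1e-6, rep(1e-6 / (p - 1), p - 1))
  comp <- t(sapply(seq(0.05, 0.95, length.out = 6), mix))
  comp <- comp / rowSums(comp)
  sh <- alpha_diversity(comp)$shannon
  expect_true(all(diff(sh) > 0))
  groups <- rep(c(0, 1), each = 3)   # ranks 1-3 vs 4-6
  res <- compare_alpha(comp, groups)
  expect_equal(res$p_value[res$index == "shannon"], 0.1, tolerance = 1e-12)
  expect_equal(res$p_value[res$index == "simpson"], 0.1, tolerance = 1e-12)
  # label swap leaves p unchanged
  res2 <- compare_alpha(comp, 1 - groups)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  # identical values in both groups: p = 1
  flat <- matrix(1 / p, 6, p)
  resf <- compare_alpha(flat, groups)
  expect_equal(resf$p_value, c(1, 1))
  expect_error(compare_alpha(comp, rep(0, 6)), "two groups")
})

test_that("ordination scores behave as specified", {
  sim <- trim_sim(simulate_zippca(
    sim_config("M1", n = 30, p = 12, k = 2, seed = 17, depth = 2000)))
  fit <- suppressWarnings(fit_zippca(sim$counts, quick_cfg(k = 2)))
  ordi <- ordinate(sim$counts, "intrinsic", d = 2, fit = fit)
  expect_identical(ordi$scores, fit$varparams$m[, 1:2])
  expect_error(ordinate(sim$counts, "intrinsic", d = 3, fit = fit), "exceeds")

  nkept <- nrow(sim$counts$counts)
  ordp <- ordinate(sim$counts, "pca", d = 2, fit = fit)
  expect_identical(dim(ordp$scores), c(nkept, 2L))
  expect_equal(length(ordp$variance_explained), 2L)
  # duplicated samples in the denoised matrix get identical PCA scores
  dup <- c(1, 1, 3:nkept)
  f2 <- fit
  f2$varparams$m <- fit$varparams$m[dup, ]
  f2$varparams$S <- fit$varparams$S[dup, ]
  f2$varparams$pi <- fit$varparams$pi[dup, ]
  ordd <- ordinate(sim$counts, "pca", d = 2, fit = f2)
  expect_equal(ordd$scores[1, ], ordd$scores[2, ], tolerance = 1e-10)
})

test_that("denoised PCA separates latent clusters better than raw PCA", {
  sils <- sapply(1:2, function(r) {
    cfg <- sim_config("M5", n = 60, p = 30, k = 2, seed = 50 + r,
                      mixture_components = 2, depth = 2000)
    sim <- trim_sim(simulate_zippca(cfg))
    labels <- apply(sim$f, 1, function(z) which.min(abs(z[1] - c(-1.5, 1.5))))
    fit <- suppressWarnings(fit_zippca(sim$counts, quick_cfg(k = 2)))
    den <- ordinate(sim$counts, "pca", d = 2, fit = fit)$scores
    raw <- prcomp(log2(1 + sim$counts$counts), center = TRUE)$x[, 1:2]
    c(silhouette_mean(den, labels), silhouette_mean(raw, labels))
  })
  expect_gt(mean(sils[1, ]), mean(sils[2, ]))
})
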