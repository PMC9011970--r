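#' Configuration for the synthetic-data generators
#'
#' Scenarios `M1`-`M6` cover zero-inflated NB counts (`M1`), zero-inflated
#' Poisson (`M2`), a zero-inflated logistic-normal multinomial (`M3`), a
#' zero-inflated log-normal with a continuous positive part (`M4`), an NB
#' latent-variable model whose factors follow a Gaussian mixture (`M5`), and
#' a multinomial with fixed, nonrandom factor scores (`M6`). `M7`-`M9` extend
#' `M1`-`M3` with two balanced groups and per-taxon log-scale effects for
#' differential-abundance benchmarking.
#'
#' Defaults emulate sparse, overdispersed microbiome data: latent dimension
#' 2, structural-zero probability averaging ~0.3 (total zero fractions around
#' 40-70% once sampling zeros are included), NB shape 1, and library sizes
#' varying around `depth` on roughly one order of magnitude
#' (`library_size_spread` is the SD of the log library-size effect).
#'
#' @param scenario One of `"M1"`..`"M9"`.
#' @param n Number of samples (total; DA scenarios use two balanced groups).
#' @param p Number of taxa.
#' @param k Latent dimension.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param zero_inflation_level Mean structural-zero probability in `[0, 1)`;
#'   0 disables zero inflation exactly.
#' @param phi NB shape (scalar or length-p vector).
#' @param library_size_spread SD of the per-sample log library-size effect.
#' @param effect_size Log-scale group shift for DA taxa (`M7`-`M9`).
#' @param da_fraction Fraction of taxa receiving a group effect, in `(0, 1]`.
#' @param mixture_components Number of Gaussian mixture components (`M5`).
#' @param depth Target library size (multinomial total for `M6`).
#' @return A `zippca_sim_config` list.
#' @export
sim_config <- function(scenario = "M1", n = 100, p = 200, k = 2, seed = 1L,
                       zero_inflation_level = 0.3, phi = 1,
                       library_size_spread = 1, effect_size = 1,
                       da_fraction = 0.2, mixture_components = 3,
                       depth = 5000) {
  scenario <- match.arg(scenario, paste0("M", 1:9))
  stopifnot(n >= 2, p >= 2, k >= 1, k < min(n, p),
            zero_inflation_level >= 0, zero_inflation_level < 1,
            all(phi > 0), library_size_spread > 0,
            da_fraction > 0, da_fraction <= 1,
            mixture_components >= 1, depth >= 1)
  if (scenario %in% c("M7", "M8", "M9") && round(da_fraction * p) < 1) {
    stop("da_fraction * p must be at least 1 for DA scenarios")
  }
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 k = as.integer(k), seed = as.integer(seed),
                 zero_inflation_level = zero_inflation_level, phi = phi,
                 library_size_spread = library_size_spread,
                 effect_size = effect_size, da_fraction = da_fraction,
                 mixture_components = as.integer(mixture_components),
                 depth = as.integer(depth)),
            class = "zippca_sim_config")
}

## Deterministic grid of factor scores for M6 ("nonrandom factors"):
## equally spaced points on [-2, 2]^k, first n rows of the tensor grid.
factor_grid <- function(n, k) {
  g <- ceiling(n^(1 / k))
  pts <- seq(-2, 2, length.out = g)
  f <- as.matrix(expand.grid(rep(list(pts), k)))[seq_len(n), , drop = FALSE]
  dimnames(f) <- NULL
  f
}

#' Generate synthetic microbiome count data with full ground truth
#'
#' Draws a dataset from the scenario in `config` and returns the counts
#' together with every ground-truth quantity needed by the evaluation
#' metrics: factor scores, structural-zero indicators, the latent signal
#' matrix `x*_ij = (1 - z_ij) exp(beta_0j + [gamma_j v_i] + f_i' beta_j)`,
#' the underlying compositions (softmax of the same linear predictor;
#' defined for `M1`-`M3` and `M6`, `NULL` otherwise), and all generative
#' parameters. `M4` additionally exposes the continuous positive part.
#'
#' @param config A [sim_config()].
#' @return A `zippca_sim` list: `counts` (a `zippca_counts`), `f`, `z`,
#'   `signal`, `composition`, `theta`, `da_labels`, `covariate`,
#'   `continuous`, `config`.
#' @examples
#' sim <- simulate_zippca(sim_config("M1", n = 40, p = 20, seed = 7))
#' mean(sim$counts$counts == 0)
#' @export
simulate_zippca <- function(config) {
  stopifnot(inherits(config, "zippca_sim_config"))
  if (config$scenario %in% c("M7", "M8", "M9")) return(simulate_da(config))
  simulate_core(config, gamma = NULL, v = NULL, da_labels = NULL)
}

#' Generate two-group data for differential-abundance benchmarking
#'
#' Scenarios `M7`-`M9` reuse the generative processes of `M1`-`M3` with two
#' balanced groups: a random `da_fraction` subset of taxa receives a
#' log-scale shift `gamma_j = +/- effect_size` (signs balanced so the
#' perturbation is not confounded with library size), and `da_labels`
#' records which taxa carry the effect.
#'
#' @param config A [sim_config()] with scenario `"M7"`, `"M8"` or `"M9"`.
#' @return A `zippca_sim`; `counts$covariate` holds the 0/1 group labels.
#' @export
simulate_da <- function(config) {
  stopifnot(inherits(config, "zippca_sim_config"))
  if (!config$scenario %in% c("M7", "M8", "M9")) {
    stop("simulate_da requires scenario M7, M8 or M9")
  }
  if (config$n %% 2 != 0) stop("n must be even for two balanced groups")
  set.seed(config$seed)
  p <- config$p
  n_da <- round(config$da_fraction * p)
  idx <- sample.int(p, n_da)
  signs <- rep(c(1, -1), length.out = n_da)
  gamma <- numeric(p)
  gamma[idx] <- signs * config$effect_size
  da_labels <- integer(p)
  da_labels[idx] <- 1L
  v <- rep(c(0, 1), each = config$n / 2)
  simulate_core(config, gamma = gamma, v = v, da_labels = da_labels,
                reseed = FALSE)
}

simulate_core <- function(config, gamma, v, da_labels, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  n <- config$n; p <- config$p; k <- config$k
  base <- switch(config$scenario,
                 M1 = "M1", M2 = "M2", M3 = "M3", M4 = "M4",
                 M5 = "M5", M6 = "M6", M7 = "M1", M8 = "M2", M9 = "M3")
  phi <- rep_len(config$phi, p)
  spread <- config$library_size_spread
  level <- config$zero_inflation_level

  beta0 <- stats::rnorm(p)   # rescaled to the target depth below
  B <- matrix(stats::rnorm(p * k), p, k)

  f <- switch(base,
    M5 = {
      G <- config$mixture_components
      centers <- matrix(3 * (seq_len(G) - (G + 1) / 2), G, k)
      assign <- sample.int(G, n, replace = TRUE)
      centers[assign, , drop = FALSE] +
        matrix(stats::rnorm(n * k, sd = 0.7), n, k)
    },
    M6 = factor_grid(n, k),
    matrix(stats::rnorm(n * k), n, k))

  U0 <- tcrossprod(f, B) + rep(beta0, each = n)
  if (!is.null(gamma)) U0 <- U0 + outer(v, gamma)
  ## one constant shift of all taxon intercepts puts the latent signal on
  ## the count scale: at alpha0 = 0 the expected library size is `depth`
  ## (compositions are invariant to this shift)
  s0 <- log(config$depth) - log(mean(rowSums(exp(U0))))
  beta0 <- beta0 + s0
  U0 <- U0 + s0

  use_zi <- level > 0 && !base %in% c("M5", "M6")
  if (use_zi) {
    cvec <- stats::rnorm(n, sd = 0.5)
    tau <- stats::qlogis(level) + stats::rnorm(p, sd = 0.5)
    eta <- stats::plogis(outer(cvec, tau, "+"))
    z <- matrix(stats::rbinom(n * p, 1, eta), n, p)
  } else {
    cvec <- rep(0, n)
    tau <- rep(-Inf, p)
    z <- matrix(0L, n, p)
  }

  expU0 <- exp(U0)
  rs <- rowSums(expU0)
  ## library-size effects: mean-zero on the log scale, so the latent signal
  ## and the observed counts share a common scale
  alpha0 <- spread * stats::rnorm(n)

  if (base %in% c("M3", "M6")) {
    N <- if (base == "M6") rep(config$depth, n) else
      pmax(1, round(exp(alpha0) * rs))
    if (base == "M6") alpha0 <- rep(0, n)
    rho_rows <- expU0 / rs
    x0 <- t(vapply(seq_len(n),
                   function(i) stats::rmultinom(1, N[i], rho_rows[i, ])[, 1],
                   numeric(p)))
    continuous <- NULL
  } else {
    mu <- exp(alpha0 + U0)
    phim <- matrix(phi, n, p, byrow = TRUE)
    if (base == "M1" || base == "M5") {
      x0 <- matrix(stats::rnbinom(n * p, size = phim, mu = mu), n, p)
      continuous <- NULL
    } else if (base == "M2") {
      x0 <- matrix(stats::rpois(n * p, mu), n, p)
      continuous <- NULL
    } else {                                    # M4: zero-inflated log-normal
      y <- exp(alpha0 + U0 + matrix(stats::rnorm(n * p), n, p))
      continuous <- (1 - z) * y
      x0 <- round(y)
    }
  }
  x <- (1 - z) * x0
  if (!is.null(continuous)) continuous <- (1 - z) * continuous

  signal <- if (base == "M6") NULL else (1 - z) * expU0
  composition <- if (base %in% c("M1", "M2", "M3", "M6")) expU0 / rs else NULL

  sample_ids <- paste0("s", seq_len(n))
  taxon_ids <- paste0("t", seq_len(p))
  dimnames(x) <- list(sample_ids, taxon_ids)
  storage.mode(x) <- "double"
  counts <- structure(list(counts = x, sample_ids = sample_ids,
                           taxon_ids = taxon_ids, covariate = v),
                      class = "zippca_counts")
  if (!is.null(signal)) dimnames(signal) <- dimnames(x)
  if (!is.null(composition)) dimnames(composition) <- dimnames(x)

  structure(list(counts = counts, f = f, z = z, signal = signal,
                 composition = composition,
                 theta = list(c = cvec, tau = tau, alpha0 = alpha0,
                              beta0 = beta0, B = B,
                              phi = if (base %in% c("M1", "M5")) phi else NULL,
                              gamma = gamma),
                 da_labels = da_labels, covariate = v,
                 continuous = continuous, config = config),
            class = "zippca_sim")
}

#' Drop all-zero rows and columns of a simulated dataset
#'
#' Removes taxa and samples with zero total count from the generated counts
#' while keeping every ground-truth matrix and parameter vector aligned
#' (compositions are renormalized over the retained taxa).
#'
#' @param sim A `zippca_sim` from [simulate_zippca()] or [simulate_da()].
#' @return The trimmed `zippca_sim`.
#' @export
trim_sim <- function(sim) {
  x <- sim$counts$counts
  keep_t <- colSums(x) > 0
  keep_s <- rowSums(x) > 0
  if (all(keep_t) && all(keep_s)) return(sim)
  sub <- function(M) if (is.null(M)) NULL else M[keep_s, keep_t, drop = FALSE]
  sim$z <- sub(sim$z)
  sim$signal <- sub(sim$signal)
  sim$continuous <- sub(sim$continuous)
  if (!is.null(sim$composition)) {
    comp <- sim$composition[keep_s, keep_t, drop = FALSE]
    sim$composition <- comp / rowSums(comp)
  }
  sim$f <- sim$f[keep_s, , drop = FALSE]
  sim$theta$c <- sim$theta$c[keep_s]
  sim$theta$alpha0 <- sim$theta$alpha0[keep_s]
  sim$theta$tau <- sim$theta$tau[keep_t]
  sim$theta$beta0 <- sim$theta$beta0[keep_t]
  sim$theta$B <- sim$theta$B[keep_t, , drop = FALSE]
  if (!is.null(sim$theta$phi)) sim$theta$phi <- sim$theta$phi[keep_t]
  if (!is.null(sim$theta$gamma)) sim$theta$gamma <- sim$theta$gamma[keep_t]
  if (!is.null(sim$da_labels)) sim$da_labels <- sim$da_labels[keep_t]
  if (!is.null(sim$covariate)) sim$covariate <- sim$covariate[keep_s]
  x <- x[keep_s, keep_t, drop = FALSE]
  sim$counts <- structure(list(counts = x, sample_ids = rownames(x),
                               taxon_ids = colnames(x),
                               covariate = sim$covariate),
                          class = "zippca_counts")
  sim
}
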