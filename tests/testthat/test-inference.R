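test_that("dataset validation catches schema violations", {
  df <- data.frame(domain_id = "d1", color = "active", length_bp = 1e5,
                   cell_id = 1:25, rg2_nm2 = seq(1e3, 2e3, length.out = 25))
  expect_s3_class(gyration_dataset(df), "gyration_dataset")
  expect_error(gyration_dataset(transform(df, color = "purple")), "color")
  expect_error(gyration_dataset(transform(df, rg2_nm2 = -rg2_nm2)), "rg2")
  expect_error(gyration_dataset(df[, -1]), "missing columns")
  expect_error(gyration_dataset(rbind(df, df[1, ])), "duplicate")
  expect_warning(gyration_dataset(df[1:5, ]), "20-100")
})

test_that("total log-likelihood equals an independent quadrature oracle", {
  cs <- toy_coeffs()
  pm <- model_params(0.44, 1500, 37)
  bp <- bundle_params(94)
  ds <- suppressWarnings(make_color_data(cs, pm, bp, n_domains = 2,
                                         n_cells = 5, seed = 31))
  theta <- c(0.44, 1500, 37, 94)
  ll <- total_log_likelihood(ds, theta, cs, "constant_bundle")
  df <- as.data.frame(ds)
  oracle <- sum(vapply(unique(df$length_bp), function(L) {
    sum(log(oracle_convolved_density(df$rg2_nm2[df$length_bp == L],
                                     L, pm, bp, cs)))
  }, numeric(1)))
  expect_lt(abs(ll - oracle), 1e-4 * abs(oracle))
  # single observation equals the log convolved density at that point
  one <- gyration_dataset(suppressWarnings(df[1, , drop = FALSE]))
  expect_equal(suppressWarnings(total_log_likelihood(one, theta, cs,
                                                     "constant_bundle")),
               log(oracle_convolved_density(df$rg2_nm2[1], df$length_bp[1],
                                            pm, bp, cs)),
               tolerance = 1e-4)
})

test_that("log-likelihood is additive over length groups and permutation invariant", {
  cs <- toy_coeffs()
  pm <- model_params(0.32, 3900, 60)
  bp <- bundle_params(93, 170, 10)
  ds <- make_color_data(cs, pm, bp, color = "inactive", n_domains = 4,
                        n_cells = 25, seed = 8)
  theta <- c(0.32, 3900, 60, 93, 170, 10)
  df <- as.data.frame(ds)
  Ls <- unique(df$length_bp)
  half <- df$length_bp %in% Ls[1:2]
  llA <- suppressWarnings(total_log_likelihood(gyration_dataset(df[half, ]),
                                               theta, cs, "full"))
  llB <- suppressWarnings(total_log_likelihood(gyration_dataset(df[!half, ]),
                                               theta, cs, "full"))
  ll <- total_log_likelihood(ds, theta, cs, "full")
  expect_equal(ll, llA + llB, tolerance = 1e-10)
  perm <- gyration_dataset(df[sample.int(nrow(df)), ])
  expect_equal(total_log_likelihood(perm, theta, cs, "full"), ll,
               tolerance = 1e-10)
  # support violations hit the sentinel
  expect_equal(total_log_likelihood(ds, c(0.32, 3e5, 60, 93, 170, 10), cs,
                                    "full"), -1e10)
})

test_that("stretch sampler recovers a two-dimensional Gaussian target", {
  lp <- function(th) -0.5 * sum((th - c(1, 2))^2 / c(0.5, 2)^2)
  set.seed(1)
  init <- cbind(stats::rnorm(32, 1, 0.2), stats::rnorm(32, 2, 0.2))
  r <- stretch_sampler(lp, init, 900, seed = 5)
  m <- apply(r$chain[301:900, , ], 3, identity)
  n_eff <- 300   # conservative effective count given walker correlation
  expect_lt(abs(mean(m[, 1]) - 1), 3 * 0.5 / sqrt(n_eff))
  expect_lt(abs(mean(m[, 2]) - 2), 3 * 2 / sqrt(n_eff))
  expect_lt(abs(stats::sd(m[, 1]) - 0.5), 0.08)
  expect_lt(abs(stats::sd(m[, 2]) - 2), 0.32)
  # determinism
  r2 <- stretch_sampler(lp, init, 50, seed = 9)
  r3 <- stretch_sampler(lp, init, 50, seed = 9)
  expect_identical(r2$chain, r3$chain)
})

test_that("nominal credible intervals of the sampler cover a known target", {
  # 20 replicates of a 2-D Gaussian: 95% intervals should cover ~95%
  covered <- 0
  for (k in 1:20) {
    mu <- c(k %% 3, -1 + k %% 5)
    lp <- function(th) -0.5 * sum((th - mu)^2)
    set.seed(k)
    init <- cbind(stats::rnorm(16, mu[1], 0.3), stats::rnorm(16, mu[2], 0.3))
    r <- stretch_sampler(lp, init, 400, seed = 100 + k)
    m <- apply(r$chain[201:400, , ], 3, identity)
    qs <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
    covered <- covered + all(mu >= qs[1, ] & mu <= qs[2, ])
  }
  # binomial(20, 0.95^2 per-pair joint coverage ~0.90): reject only clear failure
  expect_gte(covered, 14)
})

test_that("posterior summaries are recomputable bookkeeping", {
  lp <- function(th) -0.5 * sum(th^2)
  set.seed(2)
  init <- matrix(stats::rnorm(16 * 2, 0, 0.5), 16, 2)
  r <- stretch_sampler(lp, init, 200, seed = 3)
  post <- structure(list(chain = r$chain, log_prob = r$log_prob,
                         par_names = c("x", "y"), burn_in = 100,
                         acceptance = r$acceptance, tau_int = c(1, 1),
                         ess = c(100, 100), variant = "full", seed = 3,
                         prior_bounds = NULL),
                    class = "posterior_samples")
  s <- summarize_posterior(post)
  m <- posterior_matrix(post)
  expect_equal(s$table$mean, unname(colMeans(m)))
  expect_equal(s$table$sd, unname(apply(m, 2, stats::sd)))
  expect_equal(dim(s$correlation), c(2, 2))
  # constant chain has zero SD
  cst <- post
  cst$chain[] <- 1.5
  expect_equal(summarize_posterior(cst)$table$sd, c(0, 0))
})

test_that("ridge fitting is exact on a planted power law and errors shrink with n", {
  set.seed(6)
  K_bp <- exp(stats::runif(400, log(300), log(8000)))
  K_nm <- 2 * K_bp^0.5
  r <- fit_ridge(cbind(K_bp, K_nm), seed = 1)
  expect_equal(r$exponent, 0.5, tolerance = 1e-10)
  expect_equal(r$kappa, 2, tolerance = 1e-8)
  # noisy ridge: bootstrap SE shrinks roughly like 1/sqrt(n)
  K_nm_noisy <- K_nm * exp(stats::rnorm(400, 0, 0.1))
  r_small <- fit_ridge(cbind(K_bp, K_nm_noisy)[1:100, ], seed = 2)
  r_big <- fit_ridge(cbind(K_bp, K_nm_noisy), seed = 3)
  expect_lt(r_big$exponent_se, r_small$exponent_se)
  # non-degenerate cloud triggers the warning
  expect_warning(fit_ridge(cbind(exp(stats::rnorm(200, 7, 0.3)),
                                 exp(stats::rnorm(200, 3.5, 0.3))), seed = 4),
                 "not")
})
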