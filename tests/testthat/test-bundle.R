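test_that("bundle section spreading follows the logistic-in-N form", {
  bp <- bundle_params(93, 170, 10)
  expect_equal(sigma_of_N(0, bp), 93)
  expect_equal(sigma_of_N(1e7, bp), 170, tolerance = 1e-9)
  # direct arithmetic at N = 10 (one crossover length)
  expect_equal(sigma_of_N(10, bp), 170 / (1 + (170 / 93 - 1) * exp(-1)),
               tolerance = 1e-12)
  expect_equal(round(sigma_of_N(10, bp), 1), 130.3)
  # monotone in N
  s <- sigma_of_N(seq(0, 100, by = 5), bp)
  expect_true(all(diff(s) > 0))
  # constant variant ignores N
  bc <- bundle_params(94)
  expect_equal(sigma_of_N(c(0, 10, 1e5), bc), rep(94, 3))
  expect_error(bundle_params(-1), "positive")
  expect_error(bundle_params(100, 50, 10), "a_inf")
})

test_that("bundle density is a unit-mean-sigma^2 exponential", {
  expect_equal(stats::integrate(bundle_density, 0, Inf, sigma = 77)$value, 1,
               tolerance = 1e-7)
  # lambda = 1: median at ln 2
  expect_equal(stats::integrate(bundle_density, 0, log(2), sigma = 1)$value,
               0.5, tolerance = 1e-9)
  set.seed(3)
  x <- stats::rexp(1e6, rate = 1 / 100^2)
  se <- stats::sd(x) / 1000
  expect_lt(abs(mean(x) - 1e4), 3 * se)
  expect_error(bundle_density(-1, 10), "B2")
})

test_that("convolution preserves mass, adds means, and dominates stochastically", {
  cs <- toy_coeffs()
  pm <- model_params(0.32, 3900, 60)
  bp <- bundle_params(93, 170, 10)
  L <- 2e5
  g <- chromocoil:::.convolved_grid(L, pm, bp, cs)
  w <- c(diff(g$y) / 2, 0) + c(0, diff(g$y) / 2)
  expect_lt(abs(sum(w * g$dens) - 1), 1e-3)
  # mean additivity <Rg^2>_obs = <R_1^2> + sigma^2
  N <- L / pm$K_bp
  m_single <- mean_rg(L = L, params = pm, coeffs = cs)^2
  expect_equal(convolved_mean_rg2(L, pm, bp, cs),
               m_single + sigma_of_N(N, bp)^2, tolerance = 1e-4)
  # observed CDF lies below the single-polymer CDF pointwise
  g0 <- chromocoil:::.pdf_grid_adim(L / pm$K_bp, pm$eps, cs)
  xs <- g0$rg2 * pm$K_nm^2
  cdf_obs <- stats::approx(g$y, g$cdf, xout = xs, rule = 2)$y
  expect_true(all(cdf_obs <= g0$cdf + 1e-3))
  # Monte Carlo oracle: sampled single + exponential sums match in KS
  x <- sample_rg2(L, pm, bp, cs, n = 2e4, seed = 21)
  ks <- max(abs(stats::ecdf(x)(g$y) - g$cdf))
  expect_lt(ks, 0.02)
})

test_that("a vanishing bundle reduces the convolution to the bare density", {
  cs <- toy_coeffs()
  pm <- model_params(0.32, 3900, 60)
  tiny <- bundle_params(0.5)     # sigma^2 = 0.25 nm^2, negligible
  L <- 2e5
  x <- seq(3e4, 3e5, length.out = 7)
  expect_equal(convolve_pdf(x, L, pm, tiny, cs),
               pdf_rg2_dimensional(x, L, pm, cs), tolerance = 5e-3)
  expect_equal(convolve_pdf(x, L, pm, NULL, cs),
               pdf_rg2_dimensional(x, L, pm, cs), tolerance = 1e-6)
})

test_that("mean deconvolution inverts the bundle shift", {
  expect_equal(deconvolve_mean(500, 0), 500)
  expect_error(deconvolve_mean(90, 10), "bundle-dominated")
  cs <- toy_coeffs()
  pm <- model_params(0.44, 1500, 37)
  bp <- bundle_params(94)
  L <- 1.2e5
  m_obs <- convolved_mean_rg2(L, pm, bp, cs)
  expect_equal(deconvolve_mean(m_obs, 94),
               mean_rg(L = L, params = pm, coeffs = cs)^2, tolerance = 1e-4)
  expect_lt(deconvolve_mean(m_obs, 94), m_obs)
})

test_that("bundle spread is recovered from the smallest domains", {
  # pooled pure-exponential data at sigma = 100 nm
  set.seed(14)
  rows <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(domain_id = paste0("s", i), color = "inactive",
               length_bp = 1e4 + i, cell_id = 1:40,
               rg2_nm2 = stats::rexp(40, rate = 1 / 100^2))
  }))
  big <- data.frame(domain_id = "big", color = "inactive", length_bp = 5e5,
                    cell_id = 1:40, rg2_nm2 = stats::rexp(40, 1 / 300^2))
  ds <- gyration_dataset(rbind(rows, big))
  est <- estimate_bundle_from_small_domains(ds, length_threshold = 1e5,
                                            seed = 2)
  expect_gt(100, est$ci[1])
  expect_lt(100, est$ci[2])
  expect_false("big" %in% est$domains)
  # single observation: sigma-hat is the square root of that observation
  one <- gyration_dataset(data.frame(domain_id = "o", color = "active",
                                     length_bp = 1e4, cell_id = 1:10,
                                     rg2_nm2 = rep(400, 10)))
  est1 <- estimate_bundle_from_small_domains(one, length_threshold = 1e5,
                                             n_boot = 10, seed = 1)
  expect_equal(est1$sigma, 20)
})
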