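test_that("renormalized density follows the rho^(5/4) convention", {
  # identity case rho = 1 for any exponent
  expect_equal(renormalized_density(1000, 100), 1)
  # direct arithmetic: rho = 0.1, nu = 3/5 -> t = 0.1^1.25
  expect_equal(renormalized_density(100, 100), 0.1^1.25, tolerance = 1e-12)
  # strictly decreasing in rg2
  expect_gt(renormalized_density(500, 50), renormalized_density(500, 200))
  expect_error(renormalized_density(500, -1), "positive")
  expect_error(renormalized_density(1, 10), "N must be")
})

test_that("free energy matches an independent term-by-term oracle", {
  cs <- toy_coeffs()
  # single-term evaluations
  cs0 <- coefficient_set(c(0, 1), a1 = c(1, 1), a2 = c(1e-12, 1e-12),
                         a3 = c(1e-12, 1e-12), a4 = c(0, 0), c_log = 0)
  expect_equal(free_energy_adim(2, 10, 0.5, cs0), 20, tolerance = 1e-6)
  # all terms ~0, c_log = -1.13, Nt = 1 -> ln term vanishes
  cs1 <- coefficient_set(c(0, 1), a1 = c(0, 0), a2 = c(1e-15, 1e-15),
                         a3 = c(1e-15, 1e-15), a4 = c(0, 0))
  expect_equal(free_energy_adim(1 / 10, 10, 0.5, cs1), 0, tolerance = 1e-10)
  # full set at a grid point vs independent summation
  a <- unlist(cs$table[cs$table$eps == 0.27, c("a1", "a2", "a3", "a4")])
  for (tt in c(0.01, 0.3, 2)) {
    N <- 50
    manual <- a[[1]] * N * tt + a[[2]] * N * tt^2 + a[[3]] * (N * tt)^(-2 / 3) +
      a[[4]] * (N * tt^2)^(2 / 3) + 1.13 * log(N * tt)
    expect_equal(free_energy_adim(tt, N, 0.27, cs), unname(manual),
                 tolerance = 1e-12)
  }
  expect_error(free_energy_adim(1, 10, 0.9, cs), "extrapolate")
})

test_that("rg2 densities are normalized and peak at the free-energy minimum", {
  cs <- toy_coeffs()
  for (case in list(c(500, 0.32), c(100, 0.1), c(50, 0.44))) {
    N <- case[1]; eps <- case[2]
    sup <- rg2_support(N)
    f <- function(x) pdf_rg2_adim(x, N, eps, cs)
    Z <- stats::integrate(f, sup[1], sup[2], rel.tol = 1e-9,
                          subdivisions = 2000L)$value
    expect_lt(abs(Z - 1), 1e-6)
    expect_true(all(f(seq(sup[1], sup[2], length.out = 50)) >= 0))
  }
  # argmax of the density equals argmin of the free energy on a dense grid
  N <- 200; eps <- 0.32
  x <- exp(seq(log(rg2_support(N)[1]), log(rg2_support(N)[2]), length.out = 2000))
  dens <- pdf_rg2_adim(x, N, eps, cs)
  bf <- free_energy_adim(renormalized_density(N, x), N, eps, cs)
  expect_equal(which.max(dens), which.min(bf))
})

test_that("dimensional mapping preserves normalization and scales exactly", {
  cs <- toy_coeffs()
  pm1 <- model_params(0.32, 1, 1)
  x <- c(30, 80, 200)
  expect_equal(pdf_rg2_dimensional(x, 390, pm1, cs),
               pdf_rg2_adim(x, 390, 0.32, cs))
  pm <- model_params(0.32, 3900, 60)
  N <- 390000 / 3900    # evaluated at N = 100
  sup <- rg2_support(N) * pm$K_nm^2
  f <- function(x) pdf_rg2_dimensional(x, 390000, pm, cs)
  Z <- stats::integrate(f, sup[1], sup[2], rel.tol = 1e-9,
                        subdivisions = 2000L)$value
  expect_lt(abs(Z - 1), 1e-6)
  # dimensional consistency of the mean
  expect_equal(mean_rg(L = 390000, params = pm, coeffs = cs),
               pm$K_nm * mean_rg(N = 100, eps = 0.32, coeffs = cs),
               tolerance = 1e-12)
  expect_error(pdf_rg2_dimensional(100, 5000, pm, cs), "< 2")
})

test_that("mean and median agree with a Monte Carlo sampling oracle", {
  cs <- toy_coeffs()
  N <- 300; eps <- 0.32
  x <- sample_rg2_adim(1e5, N, eps, cs, seed = 11)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean_rg(N = N, eps = eps, coeffs = cs)^2), 3 * se)
  med_model <- median_rg(N = N, eps = eps, coeffs = cs)^2
  med_se <- 1.2533 * se                      # asymptotic for near-normal bulk
  expect_lt(abs(stats::median(x) - med_model), 4 * med_se)
  # attraction shrinks the chain
  expect_gt(mean_rg(N = 500, eps = 0.10, coeffs = cs),
            mean_rg(N = 500, eps = 0.44, coeffs = cs))
  # median has CDF exactly one half
  g <- chromocoil:::.pdf_grid_adim(N, eps, cs)
  expect_equal(stats::approx(g$rg2, g$cdf, xout = med_model)$y, 0.5,
               tolerance = 1e-6)
})

test_that("crossover length exists only above the theta point and moves with attraction", {
  cs <- toy_coeffs()
  expect_true(is.na(crossover_length(0.10, cs)))
  n44 <- crossover_length(0.44, cs, N_range = c(10, 5e4))
  n38 <- crossover_length(0.38, cs, N_range = c(10, 5e4))
  expect_true(is.finite(n44) && n44 > 0)
  # stronger attraction moves the crossover to shorter chains
  expect_lt(n44, n38)
  # mean radius is nearly flat around the knee
  r <- mean_rg(N = n44 * c(0.8, 1, 1.25), eps = 0.44, coeffs = cs)
  expect_lt(abs(log(r[3] / r[1])) / log(1.25 / 0.8), 0.25)
})
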