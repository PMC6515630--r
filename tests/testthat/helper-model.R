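# Hand-made coefficient set with realistic magnitudes: a1 linear with a zero
# crossing at 0.27 kT, constant three-body and elastic terms. Used wherever a
# test exercises machinery rather than the shipped calibration.
toy_coeffs <- function() {
  eg <- c(0, 0.1, 0.2, 0.27, 0.35, 0.45, 0.6)
  coefficient_set(eps_grid = eg,
                  a1 = 0.012 * (0.27 - eg) / 0.27,
                  a2 = rep(0.002, length(eg)),
                  a3 = rep(35, length(eg)),
                  a4 = rep(0, length(eg)))
}

# Small one-color synthetic dataset drawn from the generative model at known
# parameters (constant-section bundle), for likelihood and recovery tests.
make_color_data <- function(coeffs, params, bundle, color = "repressed",
                            n_domains = 6, n_cells = 30, seed = 9,
                            length_range = c(3e4, 4e5)) {
  set.seed(seed)
  Ls <- round(exp(runif(n_domains, log(length_range[1]), log(length_range[2]))))
  rows <- lapply(seq_along(Ls), function(i) {
    data.frame(domain_id = sprintf("%s_%02d", color, i), color = color,
               length_bp = Ls[i], cell_id = seq_len(n_cells),
               rg2_nm2 = sample_rg2(Ls[i], params, bundle, coeffs,
                                    n = n_cells, seed = seed + 1000 + i))
  })
  gyration_dataset(do.call(rbind, rows))
}

# Independent convolved-density oracle: adaptive quadrature of the defining
# integral (single-polymer density times exponential bundle kernel) via
# stats::integrate, no shared code with the grid convolution.
oracle_convolved_density <- function(y, L, params, bundle, coeffs) {
  N <- L / params$K_bp
  sig <- sigma_of_N(N, bundle)
  lam <- 1 / sig^2
  lo <- rg2_support(N)[1] * params$K_nm^2
  vapply(y, function(yy) {
    if (yy <= lo) return(0)
    stats::integrate(function(x) {
      pdf_rg2_dimensional(x, L, params, coeffs) * lam * exp(-lam * (yy - x))
    }, lower = lo, upper = min(yy, rg2_support(N)[2] * params$K_nm^2),
    rel.tol = 1e-9, subdivisions = 400L)$value
  }, numeric(1))
}
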