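#' Model parameters for one epigenetic color
#'
#' The dimensional mapping of the adimensional polymer model onto chromatin
#' uses three parameters per epigenetic state: the interaction energy per
#' Kuhn segment `eps` (kT), and the Kuhn length expressed in base pairs
#' (`K_bp`) and in nanometers (`K_nm`). A domain of genomic length `L` bp
#' maps to a chain of `N = L / K_bp` Kuhn segments, and model lengths scale
#' by `K_nm`. The ratio `K_bp / K_nm` is the linear compaction in bp/nm.
#'
#' @param eps interaction energy per Kuhn segment (kT), `>= 0`.
#' @param K_bp Kuhn length in base pairs, `> 0`.
#' @param K_nm Kuhn length in nanometers, `> 0`.
#' @return object of class `model_params`.
#' @export
model_params <- function(eps, K_bp, K_nm) {
  stopifnot(eps >= 0, K_bp > 0, K_nm > 0)
  structure(list(eps = eps, K_bp = K_bp, K_nm = K_nm), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model params: eps = %.3f kT, K_bp = %.0f bp, K_nm = %.1f nm (c = %.1f bp/nm)\n",
              x$eps, x$K_bp, x$K_nm, compaction(x)))
  invisible(x)
}

#' Linear compaction of a parameter set
#'
#' @param params a [model_params].
#' @return compaction `K_bp / K_nm` in bp/nm.
#' @export
compaction <- function(params) params$K_bp / params$K_nm

# Flory exponent entering the density renormalization (see vignette)
.NU_RENORM <- 3 / 5

#' Renormalized monomer density
#'
#' The monomer density of a chain of `N` segments with squared gyration
#' radius `rg2` (Kuhn-length^2 units) is `rho = N / rg2^{3/2}` in d = 3
#' dimensions; the renormalized density is `t = rho^{1/(nu d - 1)}`, with the
#' Flory self-avoiding-walk exponent `nu = 3/5`, so `t = rho^{5/4}`. `t = 1`
#' exactly at `rho = 1` for any exponent convention, and `t` is strictly
#' decreasing in `rg2`.
#'
#' @param N chain length in Kuhn segments (`>= 2`, may be fractional).
#' @param rg2 squared gyration radius (`> 0`), vectorized.
#' @param nu Flory exponent used in the renormalization exponent.
#' @return renormalized density `t > 0`.
#' @export
renormalized_density <- function(N, rg2, nu = .NU_RENORM) {
  if (any(N < 2)) stop("N must be >= 2 (domain shorter than two Kuhn segments)")
  if (any(rg2 <= 0)) stop("rg2 must be positive")
  (N / rg2^(3 / 2))^(1 / (3 * nu - 1))
}

#' Adimensional finite-size free energy
#'
#' Evaluates \eqn{\beta F = a_1 N t + a_2 N t^2 + a_3 (N t)^{-2/3} +
#' a_4 (N t^2)^{2/3} - c \ln(N t)} with coefficients interpolated from a
#' calibrated [coefficient_set] at energy `eps`.
#'
#' @param t renormalized density (`> 0`), vectorized.
#' @param N chain length (`>= 2`).
#' @param eps interaction energy (kT), inside the calibrated range.
#' @param coeffs a [coefficient_set].
#' @return dimensionless free energy `beta F`, finite for all `t > 0`.
#' @export
free_energy_adim <- function(t, N, eps, coeffs = default_coefficients()) {
  if (any(t <= 0)) stop("t must be positive")
  if (any(N < 2)) stop("N must be >= 2")
  a <- coef_at(coeffs, eps)
  Nt <- N * t
  a[["a1"]] * Nt + a[["a2"]] * N * t^2 + a[["a3"]] * Nt^(-2 / 3) +
    a[["a4"]] * (N * t^2)^(2 / 3) - coeffs$c_log * log(Nt)
}

#' Quadrature support for the squared gyration radius
#'
#' Lower bound from a density cap well beyond physical close packing
#' (`rho = N / rg2^{3/2} <= rho_max`), upper bound from the rod limit
#' (`rg2 <= N^2 / 4`).
#'
#' @param N chain length.
#' @return numeric vector `c(rg2_min, rg2_max)` in Kuhn-length^2 units.
#' @export
rg2_support <- function(N) {
  c(0.15 * N^(2 / 3), N^2 / 4)
}

# Normalized density of rg2 on an adaptive log-spaced grid, for raw
# coefficient values (used both for model evaluation and coefficient
# fitting). Returns grid, normalized density, cdf, logZ, support and the
# log unnormalized density function. Refines by doubling until the
# trapezoid normalization is stable to `tol`.
.pdf_grid_raw <- function(N, a, c_log, tol = 1e-8, n0 = 301L, nmax = 4801L) {
  sup <- rg2_support(N)
  logf <- function(rg2) {
    t <- (N / rg2^1.5)^(1 / (3 * .NU_RENORM - 1))
    Nt <- N * t
    -(a[["a1"]] * Nt + a[["a2"]] * N * t^2 + a[["a3"]] * Nt^(-2 / 3) +
        a[["a4"]] * (N * t^2)^(2 / 3) - c_log * log(Nt))
  }
  n <- as.integer(n0)
  if (n %% 2L == 0L) n <- n + 1L                 # Simpson needs an odd count
  Z_prev <- NA_real_
  sup_full <- sup
  shrunk <- FALSE
  repeat {
    u <- seq(log(sup[1]), log(sup[2]), length.out = n)
    x <- exp(u)
    lf <- logf(x)
    m <- max(lf)
    f <- exp(lf - m)
    # composite Simpson in u = ln(rg2) (uniform spacing, x jacobian), so the
    # normalization converges at modest grid sizes
    ws <- rep(c(2, 4), length.out = n)
    ws[1] <- 1; ws[n] <- 1
    w <- (u[2] - u[1]) / 3 * ws * x
    Z <- sum(w * f)
    if (!is.finite(Z) || Z <= 0) {
      stop(sprintf("quadrature failed for N = %g (Z = %g)", N, Z))
    }
    if (!shrunk) {
      # for long chains the density occupies a narrow slice of the full
      # support: restrict the grid to the mass-carrying region once
      shrunk <- TRUE
      live <- which(lf - m > -46)                # relative density > 1e-20
      if (length(live) >= 5 && (live[1] > 1 || live[length(live)] < n)) {
        sup <- c(x[max(1L, live[1] - 1L)], x[min(n, live[length(live)] + 1L)])
        Z_prev <- NA_real_
        next
      }
    }
    if (is.na(tol)) break                        # fixed-grid fast path
    if (!is.na(Z_prev) && abs(Z / Z_prev - 1) < tol) break
    if (n >= nmax) {
      if (is.na(Z_prev) || abs(Z / Z_prev - 1) > 1e-4) {
        stop(sprintf("normalization did not converge for N = %g", N))
      }
      break
    }
    Z_prev <- Z
    n <- min(2L * n - 1L, nmax)
  }
  dens <- f / Z
  dx <- diff(x)
  tw <- c(dx / 2, 0) + c(0, dx / 2)              # trapezoid weights for the cdf
  cw <- tw * dens
  cdf <- cumsum(cw) - cw / 2
  cdf <- pmin(pmax(cdf / cdf[length(cdf)], 0), 1)
  list(rg2 = x, dens = dens, cdf = cdf, logZ = log(Z) + m, support = sup_full,
       logf = logf, w = w)
}

.pdf_grid_adim <- function(N, eps, coeffs, tol = 1e-8, n0 = 300L, nmax = 9601L) {
  .pdf_grid_raw(N, coef_at(coeffs, eps), coeffs$c_log, tol = tol, n0 = n0,
                nmax = nmax)
}

#' Density of the squared gyration radius (adimensional)
#'
#' Probability density of `Rg^2` (in Kuhn-length^2 units) for a chain of `N`
#' segments at energy `eps`, `P(rg2) ∝ exp(-beta F)`, normalized by adaptive
#' log-spaced quadrature over the support [rg2_support()]. The density is over
#' `Rg^2`, not `Rg`.
#'
#' @param rg2 evaluation points (vectorized); values outside the support get
#'   density 0.
#' @inheritParams free_energy_adim
#' @return density values.
#' @export
pdf_rg2_adim <- function(rg2, N, eps, coeffs = default_coefficients()) {
  g <- .pdf_grid_adim(N, eps, coeffs)
  out <- numeric(length(rg2))
  inside <- rg2 >= g$support[1] & rg2 <= g$support[2]
  out[inside] <- exp(g$logf(rg2[inside]) - g$logZ)
  out
}

#' Density of the squared gyration radius (dimensional, nm^2)
#'
#' Maps the adimensional density through the Kuhn lengths:
#' `P_L(rg2_nm2) = (1/K_nm^2) P_N(rg2_nm2 / K_nm^2)` with `N = L / K_bp`.
#'
#' @param rg2_nm2 squared gyration radius in nm^2 (vectorized).
#' @param L domain length in bp.
#' @param params a [model_params].
#' @param coeffs a [coefficient_set].
#' @return density values in nm^-2.
#' @export
pdf_rg2_dimensional <- function(rg2_nm2, L, params, coeffs = default_coefficients()) {
  stopifnot(inherits(params, "model_params"), L > 0)
  N <- L / params$K_bp
  if (N < 2) {
    stop(sprintf("L = %g bp with K_bp = %g gives N = %.2f < 2 Kuhn segments",
                 L, params$K_bp, N))
  }
  pdf_rg2_adim(rg2_nm2 / params$K_nm^2, N, params$eps, coeffs) / params$K_nm^2
}

# grid moments -----------------------------------------------------------

.grid_mean <- function(g) {
  sum(g$w * g$dens * g$rg2)
}

.grid_quantile <- function(g, p) {
  stats::approx(g$cdf, g$rg2, xout = p, ties = "ordered")$y
}

#' Mean gyration radius
#'
#' Root-mean-square convention: `mean_rg = sqrt(<Rg^2>)`, with the average
#' under the model density of `Rg^2`. Called either adimensionally
#' (`N`, `eps`) or dimensionally (`L` in bp with a [model_params]); the two
#' are related exactly by `mean_rg(L) = K_nm * mean_rg(N = L/K_bp)`.
#'
#' @param N chain length (adimensional form).
#' @param eps energy (adimensional form).
#' @param L domain length in bp (dimensional form).
#' @param params a [model_params] (dimensional form).
#' @param coeffs a [coefficient_set].
#' @return mean gyration radius (Kuhn lengths, or nm in the dimensional form).
#' @export
mean_rg <- function(N = NULL, eps = NULL, L = NULL, params = NULL,
                    coeffs = default_coefficients()) {
  if (!is.null(L)) {
    stopifnot(inherits(params, "model_params"))
    N <- L / params$K_bp
    eps <- params$eps
    scale <- params$K_nm
  } else {
    scale <- 1
  }
  if (any(N < 2)) stop("N must be >= 2")
  scale * vapply(N, function(n) sqrt(.grid_mean(.pdf_grid_adim(n, eps, coeffs))),
                 numeric(1))
}

#' Median gyration radius
#'
#' Square root of the median of the `Rg^2` density (the median commutes with
#' the monotone square root, so this is also the median of `Rg`).
#'
#' @inheritParams mean_rg
#' @return median gyration radius.
#' @export
median_rg <- function(N = NULL, eps = NULL, L = NULL, params = NULL,
                      coeffs = default_coefficients()) {
  if (!is.null(L)) {
    stopifnot(inherits(params, "model_params"))
    N <- L / params$K_bp
    eps <- params$eps
    scale <- params$K_nm
  } else {
    scale <- 1
  }
  if (any(N < 2)) stop("N must be >= 2")
  scale * vapply(N, function(n) sqrt(.grid_quantile(.pdf_grid_adim(n, eps, coeffs), 0.5)),
                 numeric(1))
}

#' Sample squared gyration radii from the adimensional model
#'
#' Inverse-CDF sampling on the quadrature grid (monotone interpolation of the
#' cumulative distribution).
#'
#' @param n number of draws.
#' @inheritParams free_energy_adim
#' @param seed optional integer seed.
#' @return numeric vector of `rg2` draws (Kuhn-length^2 units).
#' @export
sample_rg2_adim <- function(n, N, eps, coeffs = default_coefficients(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- .pdf_grid_adim(N, eps, coeffs)
  u <- stats::runif(n)
  keep <- !duplicated(g$cdf)
  stats::approx(g$cdf[keep], g$rg2[keep], xout = u, rule = 2, ties = "ordered")$y
}

#' Coil-globule crossover length
#'
#' For energies above the theta point, the mean gyration radius versus chain
#' length displays a knee: the log-log slope `d ln mean_rg / d ln N` dips to
#' a minimum at some `N*` before recovering toward the globule exponent 1/3.
#' Returns that `N*` (the slope minimum on a log-spaced grid), or `NA` for
#' energies at or below the theta point, where no knee exists.
#'
#' @param eps energy (kT), inside the calibrated range.
#' @param coeffs a [coefficient_set].
#' @param N_range range of chain lengths scanned.
#' @param n_grid number of log-spaced grid points (resolution).
#' @return `N*` (possibly fractional), or `NA_real_` below the theta point.
#' @export
crossover_length <- function(eps, coeffs = default_coefficients(),
                             N_range = c(10, 5000), n_grid = 60L) {
  if (is.na(coeffs$eps_theta)) stop("coefficient set has no theta point")
  if (eps <= coeffs$eps_theta) return(NA_real_)
  Ns <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = n_grid))
  lr <- log(mean_rg(N = Ns, eps = eps, coeffs = coeffs))
  ln <- log(Ns)
  slope <- diff(lr) / diff(ln)
  i <- which.min(slope)
  if (i <= 1 || i >= length(slope)) {
    stop("slope minimum at grid edge: widen N_range or refine the grid")
  }
  exp((ln[i] + ln[i + 1]) / 2)
}
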