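#' Tetraploid-bundle parameters
#'
#' Paired homologous chromosomes in the tetraploid Kc167 line are not
#' resolved by the imaging, so a measured `Rg^2` is the single-polymer
#' `R_1^2` plus a bundle contribution `B^2` (spread of the chain centers of
#' mass). `B^2` is modeled as exponentially distributed with mean
#' `sigma^2(N)`, the squared bundle-section spreading, which grows with
#' chain length from `a0` to `a_inf` over a crossover scale `N0`:
#' \deqn{\sigma(N) = a_\infty / (1 + (a_\infty/a_0 - 1) e^{-N/N_0})}
#' The constant-section variant (`constant_section = TRUE`) uses
#' `sigma(N) = a0` for all `N` (used for repressed domains, where the
#' spreading parameters diverge in the fit).
#'
#' @param a0 minimal section spread (nm), `> 0`.
#' @param a_inf asymptotic spread (nm), `>= a0` (ignored in the constant
#'   variant).
#' @param N0 crossover chain length (monomers), `> 0` (ignored in the
#'   constant variant).
#' @param constant_section use the constant-section model.
#' @return object of class `bundle_params`.
#' @export
bundle_params <- function(a0, a_inf = NULL, N0 = NULL,
                          constant_section = is.null(a_inf)) {
  if (!is.numeric(a0) || a0 <= 0) stop("a0 must be positive")
  if (!constant_section) {
    if (is.null(a_inf) || is.null(N0)) {
      stop("a_inf and N0 are required unless constant_section = TRUE")
    }
    if (a_inf < a0) stop("a_inf must be >= a0")
    if (N0 <= 0) stop("N0 must be positive")
  }
  structure(list(a0 = a0,
                 a_inf = if (constant_section) NULL else a_inf,
                 N0 = if (constant_section) NULL else N0,
                 constant_section = constant_section),
            class = "bundle_params")
}

#' @export
print.bundle_params <- function(x, ...) {
  if (x$constant_section) {
    cat(sprintf("bundle params (constant section): a0 = %.1f nm\n", x$a0))
  } else {
    cat(sprintf("bundle params: a0 = %.1f nm, a_inf = %.1f nm, N0 = %.0f\n",
                x$a0, x$a_inf, x$N0))
  }
  invisible(x)
}

#' Bundle section spreading as a function of chain length
#'
#' @param N chain length in Kuhn segments (`>= 0`), vectorized.
#' @param bp a [bundle_params].
#' @return `sigma(N)` in nm (equals `a0` at `N = 0`, tends to `a_inf` as
#'   `N` grows; constant `a0` in the constant-section variant).
#' @export
sigma_of_N <- function(N, bp) {
  stopifnot(inherits(bp, "bundle_params"))
  if (any(N < 0)) stop("N must be >= 0")
  if (bp$constant_section) return(rep(bp$a0, length(N)))
  bp$a_inf / (1 + (bp$a_inf / bp$a0 - 1) * exp(-N / bp$N0))
}

#' Exponential density of the bundle contribution
#'
#' `f(B^2) = lambda exp(-lambda B^2)` with rate `lambda = 1/sigma^2`, so the
#' mean bundle contribution is `sigma^2`.
#'
#' @param B2 squared bundle contribution in nm^2 (`>= 0`), vectorized.
#' @param sigma bundle section spread in nm (`> 0`).
#' @return density values in nm^-2.
#' @export
bundle_density <- function(B2, sigma) {
  if (any(B2 < 0)) stop("B2 must be >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  lam <- 1 / sigma^2
  lam * exp(-lam * B2)
}

# Dimensional single-polymer grid (x in nm^2, density fx, bundle sigma at
# this length); the light-weight kernel behind likelihood evaluation.
.single_poly_grid <- function(L, params, bundle, coeffs, quad_tol = NA,
                              n0 = 301L) {
  N <- L / params$K_bp
  if (N < 2) stop(sprintf("L = %g bp gives N = %.2f < 2", L, N))
  g <- .pdf_grid_adim(N, params$eps, coeffs, tol = quad_tol, n0 = n0)
  list(x = g$rg2 * params$K_nm^2,
       fx = g$dens / params$K_nm^2,
       sigma = if (is.null(bundle)) 0 else sigma_of_N(N, bundle))
}

# Convolved density of observed rg2 on a grid: single-polymer dimensional
# grid convolved with the exponential bundle term. Returns evaluation grid
# (nm^2), density, cdf, plus the single-polymer grid and sigma used.
.convolved_grid <- function(L, params, bundle, coeffs, quad_tol = 1e-8,
                            n_y = 400L) {
  stopifnot(inherits(params, "model_params"))
  N <- L / params$K_bp
  if (N < 2) stop(sprintf("L = %g bp gives N = %.2f < 2", L, N))
  g <- .pdf_grid_adim(N, params$eps, coeffs, tol = quad_tol)
  x <- g$rg2 * params$K_nm^2              # nm^2
  fx <- g$dens / params$K_nm^2
  if (is.null(bundle)) {
    dx <- diff(x)
    w <- c(dx / 2, 0) + c(0, dx / 2)
    cw <- w * fx
    cdf <- pmin(cumsum(cw) - cw / 2, 1)
    return(list(y = x, dens = fx, cdf = cdf / max(cdf), x = x, fx = fx,
                sigma = 0))
  }
  sigma <- sigma_of_N(N, bundle)
  lam <- 1 / sigma^2
  # observed support: from the single-polymer lower edge out to the upper
  # edge plus enough exponential tail for the truncation error to vanish
  y <- c(x, max(x) + sigma^2 * exp(seq(log(0.02), log(40), length.out = 120L)))
  dens <- .convolve_eval(y, x, fx, lam)
  dy <- diff(y)
  wy <- c(dy / 2, 0) + c(0, dy / 2)
  Z <- sum(wy * dens)
  if (abs(Z - 1) > 0.05) {
    stop(sprintf("bundle convolution not converged (mass = %.5f) for L = %g", Z, L))
  }
  dens <- dens / Z
  cw <- wy * dens
  cdf <- cumsum(cw) - cw / 2
  cdf <- pmin(pmax(cdf / cdf[length(cdf)], 0), 1)
  list(y = y, dens = dens, cdf = cdf, x = x, fx = fx, sigma = sigma)
}

# Exact convolution of the piecewise-linear interpolant of (x, fx) with the
# exponential kernel lam * exp(-lam * (y - x)): per segment [a, b] with
# f = c0 + s (x - a),
#   I = (c0 + s (u - a)) e^{-lam (y - u)} - c0 e^{-lam (y - a)}
#       - (s / lam) (e^{-lam (y - u)} - e^{-lam (y - a)}),  u = min(b, y).
# All exponents are <= 0, so the form is stable for any lam, including the
# delta-kernel limit of a vanishing bundle.
.convolve_eval <- function(y, x, fx, lam) {
  n <- length(x)
  if (length(y) * (n - 1) > 2e6 && length(y) > 64) {   # chunk to bound memory
    csize <- max(64L, as.integer(2e6 / n))
    idx <- split(seq_along(y), ceiling(seq_along(y) / csize))
    return(unlist(lapply(idx, function(i) .convolve_eval(y[i], x, fx, lam)),
                  use.names = FALSE))
  }
  a <- x[-n]; b <- x[-1]
  c0 <- fx[-n]
  s <- (fx[-1] - c0) / (b - a)
  D <- outer(y, a, "-")                       # y - a
  seg <- matrix(b - a, length(y), n - 1, byrow = TRUE)
  ula <- pmin(seg, D)                         # u - a
  Eu <- exp(-lam * (D - ula))                 # e^{-lam (y - u)}
  Ea <- exp(-lam * D)                         # e^{-lam (y - a)}
  C0 <- matrix(c0, length(y), n - 1, byrow = TRUE)
  S <- matrix(s, length(y), n - 1, byrow = TRUE)
  I <- (C0 + S * ula) * Eu - C0 * Ea - (S / lam) * (Eu - Ea)
  I[D <= 0] <- 0
  rowSums(I)
}

#' Observed (bundle-convolved) density of the squared gyration radius
#'
#' Density of the measured `Rg^2` for a domain of length `L`: the
#' single-polymer dimensional density convolved with the exponential bundle
#' density, `(P_L * f_lambda)(Rg^2)`, with `sigma` evaluated at
#' `N = L/K_bp`. With `bundle = NULL` (or a vanishing `sigma`) this reduces
#' to the single-polymer density. The observed mean obeys the additivity
#' `<Rg^2> = <R_1^2> + sigma^2`.
#'
#' @param rg2_nm2 evaluation points in nm^2 (vectorized).
#' @param L domain length in bp.
#' @param params a [model_params].
#' @param bundle a [bundle_params], or `NULL` for no bundle.
#' @param coeffs a [coefficient_set].
#' @return density values in nm^-2.
#' @export
convolve_pdf <- function(rg2_nm2, L, params, bundle, coeffs = default_coefficients()) {
  if (is.null(bundle)) {
    return(pdf_rg2_dimensional(rg2_nm2, L, params, coeffs))
  }
  g <- .convolved_grid(L, params, bundle, coeffs)
  out <- numeric(length(rg2_nm2))
  lam <- 1 / g$sigma^2
  inside <- rg2_nm2 >= min(g$x)
  out[inside] <- .convolve_eval(rg2_nm2[inside], g$x, g$fx, lam)
  out
}

#' Mean observed squared gyration radius (with bundle)
#'
#' @inheritParams convolve_pdf
#' @return `<Rg^2>` in nm^2 under the convolved density.
#' @export
convolved_mean_rg2 <- function(L, params, bundle, coeffs = default_coefficients()) {
  g <- .convolved_grid(L, params, bundle, coeffs)
  dy <- diff(g$y)
  w <- c(dy / 2, 0) + c(0, dy / 2)
  sum(w * g$dens * g$y)
}

#' Deconvolve the bundle from an observed mean
#'
#' Inverts the mean additivity `<Rg^2>_obs = <R_1^2> + sigma^2`: the haploid
#' (single-polymer) mean squared gyration radius is the observed mean minus
#' the bundle variance.
#'
#' @param observed_mean_rg2 observed mean `Rg^2` in nm^2.
#' @param sigma bundle section spread in nm.
#' @return haploid mean `Rg^2` in nm^2.
#' @export
deconvolve_mean <- function(observed_mean_rg2, sigma) {
  if (any(observed_mean_rg2 <= sigma^2)) {
    stop("observed mean <= sigma^2: bundle-dominated regime, no valid haploid estimate")
  }
  observed_mean_rg2 - sigma^2
}

#' Estimate the bundle spread from the smallest domains
#'
#' For the smallest epigenetic domains the measured `Rg^2` is dominated by
#' the bundle contribution, so the pooled `Rg^2` of domains below a length
#' threshold is fitted by a pure exponential: the maximum-likelihood rate is
#' `1/mean`, giving `sigma_hat = sqrt(mean)`. A percentile bootstrap over
#' the pooled observations provides the confidence interval.
#'
#' @param dataset a [gyration_dataset].
#' @param length_threshold domains strictly below this length (bp) are used;
#'   default: the shortest decile of domain lengths.
#' @param min_cells minimum number of cells for a domain to qualify.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return list with `sigma` (nm), `ci` (nm), `lambda`, `n_obs`, `domains`.
#' @export
estimate_bundle_from_small_domains <- function(dataset, length_threshold = NULL,
                                               min_cells = 10, n_boot = 500,
                                               conf = 0.95, seed = NULL) {
  df <- as.data.frame(dataset)
  dom <- unique(df[, c("domain_id", "length_bp")])
  if (is.null(length_threshold)) {
    length_threshold <- stats::quantile(dom$length_bp, 0.1, names = FALSE) +
      .Machine$double.eps
  }
  counts <- table(df$domain_id)
  ok_ids <- dom$domain_id[dom$length_bp < length_threshold]
  ok_ids <- ok_ids[counts[as.character(ok_ids)] >= min_cells]
  if (length(ok_ids) < 1) {
    stop("no domain below the length threshold has enough cells")
  }
  x <- df$rg2_nm2[df$domain_id %in% ok_ids]
  sigma_hat <- sqrt(mean(x))
  if (!is.null(seed)) set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(i) {
    sqrt(mean(sample(x, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(sigma = sigma_hat,
       ci = stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE),
       lambda = 1 / mean(x),
       n_obs = length(x),
       domains = ok_ids)
}
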