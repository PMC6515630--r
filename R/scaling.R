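#' Power-law exponent fit
#'
#' Ordinary least squares in log-log space for `y ~ prefactor * L^nu`.
#' The exponent is scale-equivariant: rescaling `L` by a constant changes
#' only the prefactor.
#'
#' @param L_values genomic lengths (bp), at least 3 distinct values.
#' @param y_values radii (nm), positive.
#' @param weights optional OLS weights.
#' @return list with `nu`, `se` (from the fit covariance), `prefactor`.
#' @export
fit_power_law <- function(L_values, y_values, weights = NULL) {
  stopifnot(length(L_values) == length(y_values))
  if (length(unique(L_values)) < 3) stop("need >= 3 distinct lengths")
  if (any(L_values <= 0) || any(y_values <= 0)) stop("values must be positive")
  if (stats::sd(log(L_values)) < 1e-9) stop("degenerate spread in L")
  fit <- stats::lm(log(y_values) ~ log(L_values), weights = weights)
  co <- summary(fit)$coefficients
  list(nu = unname(co[2, 1]), se = unname(co[2, 2]),
       prefactor = exp(unname(co[1, 1])))
}

#' Scaling exponent of the model curve
#'
#' Computes the theoretical mean (or median) gyration radius on a log-spaced
#' grid of lengths, optionally convolved with the bundle, and fits the
#' power-law exponent over that window. `deconvolved = TRUE` gives the
#' haploid curve: the bundle variance is subtracted from the observed mean
#' squared radius before taking the square root (for the mean statistic),
#' i.e. the curve a haploid system would show. At fixed energy the exponent
#' is invariant to `K_nm`, which only shifts the curve vertically in log-log
#' space.
#'
#' @param params a [model_params].
#' @param bundle a [bundle_params] or `NULL` (no bundle: plain model curve).
#' @param coeffs a [coefficient_set].
#' @param L_window length window in bp (default 10-60 kb, the small-domain
#'   region).
#' @param statistic `"mean"` or `"median"`.
#' @param deconvolved subtract the bundle (haploid curve) rather than
#'   ignoring it.
#' @param n_points grid points in the window.
#' @return list as from [fit_power_law()] plus the curve (`L`, `rg`).
#' @export
model_scaling_exponent <- function(params, bundle = NULL,
                                   coeffs = default_coefficients(),
                                   L_window = c(10e3, 60e3),
                                   statistic = c("mean", "median"),
                                   deconvolved = TRUE,
                                   n_points = 20L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(params, "model_params"))
  if (L_window[1] / params$K_bp < 2) {
    stop("window start below the two-Kuhn-segment limit for these parameters")
  }
  Ls <- exp(seq(log(L_window[1]), log(L_window[2]), length.out = n_points))
  rg <- vapply(Ls, function(L) {
    if (is.null(bundle)) {
      if (statistic == "mean") mean_rg(L = L, params = params, coeffs = coeffs)
      else median_rg(L = L, params = params, coeffs = coeffs)
    } else if (deconvolved) {
      if (statistic == "mean") {
        m_obs <- convolved_mean_rg2(L, params, bundle, coeffs)
        sqrt(deconvolve_mean(m_obs, sigma_of_N(L / params$K_bp, bundle)))
      } else {
        # haploid median: the single-polymer model median
        median_rg(L = L, params = params, coeffs = coeffs)
      }
    } else {
      g <- .convolved_grid(L, params, bundle, coeffs)
      if (statistic == "mean") {
        sqrt(convolved_mean_rg2(L, params, bundle, coeffs))
      } else {
        sqrt(stats::approx(g$cdf, g$y, xout = 0.5, ties = "ordered")$y)
      }
    }
  }, numeric(1))
  out <- fit_power_law(Ls, rg)
  out$curve <- data.frame(L = Ls, rg = rg)
  out
}

#' Derived chromatin architecture parameters
#'
#' Converts the fitted Kuhn lengths into linear compaction and nucleosome
#' line densities: `c = K_bp / K_nm` (bp/nm), `c10 = 10 c / NRL`
#' (nucleosomes per 10 nm of fiber), `C = K_bp / NRL` (nucleosomes per Kuhn
#' segment), with `NRL` the nucleosome repeat length (182 bp for active,
#' 192 bp for inactive and repressed domains).
#'
#' @param params a [model_params].
#' @param NRL nucleosome repeat length in bp.
#' @return object of class `derived_chromatin`: list with `c_lin`, `c10`,
#'   `C`, `NRL`.
#' @export
derived_chromatin_params <- function(params, NRL) {
  stopifnot(inherits(params, "model_params"), NRL > 0)
  c_lin <- compaction(params)
  structure(list(c_lin = c_lin,
                 c10 = 10 * c_lin / NRL,
                 C = params$K_bp / NRL,
                 NRL = NRL),
            class = "derived_chromatin")
}

#' @export
print.derived_chromatin <- function(x, ...) {
  cat(sprintf("derived: c = %.1f bp/nm, c10 = %.2f nucl./10 nm, C = %.1f nucl./Kuhn (NRL %d bp)\n",
              x$c_lin, x$c10, x$C, as.integer(x$NRL)))
  invisible(x)
}

#' Globule volume at a given gyration radius
#'
#' Volume of the sphere of radius `sqrt(5/3) * Rg` (the radius of the
#' uniform ball with gyration radius `Rg`), in monomer volumes when `rg` is
#' adimensional: `V = (4/3) pi (5/3 Rg^2)^{3/2}`. A globule with `V < N` is
#' denser than close packed.
#'
#' @param rg gyration radius (Kuhn-length units), `>= 0`.
#' @return volume in monomer volumes.
#' @export
globule_volume <- function(rg) {
  if (any(rg < 0)) stop("rg must be >= 0")
  (4 / 3) * pi * (5 / 3 * rg^2)^(3 / 2)
}

#' Evaluate the Kuhn-length ridge relation
#'
#' The coil-regime posterior constrains `K_nm = kappa * K_bp^exponent`;
#' this evaluates that relation at a given `K_bp`.
#'
#' @param kappa ridge prefactor.
#' @param exponent ridge exponent.
#' @param K_bp Kuhn length in bp (vectorized).
#' @return `K_nm` in nm.
#' @export
ridge_kuhn_nm <- function(kappa, exponent, K_bp) {
  stopifnot(kappa > 0, all(K_bp > 0))
  kappa * K_bp^exponent
}
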