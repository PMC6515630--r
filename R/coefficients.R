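#' Calibrated coefficient set for the finite-size free energy
#'
#' The free energy of a self-attracting polymer of `N` Kuhn segments, as a
#' function of the renormalized density `t`, is
#' \deqn{\beta F = a_1 N t + a_2 N t^2 + a_3 (N t)^{-2/3} + a_4 (N t^2)^{2/3}
#'   - c \ln(N t)}
#' with the log coefficient fixed at `c = -1.13` (the self-avoiding-walk
#' enhancement factor) and `a_1..a_4` empirical functions of the interaction
#' energy `eps`, calibrated against cubic-lattice ISAW simulations. `a_1`
#' plays the role of a second virial coefficient and changes sign at the
#' theta point; `a_2` (three-body term) stays positive.
#'
#' A coefficient set stores the tabulated `a_1..a_4` on an energy grid plus
#' the theta energy and calibration metadata. Coefficients are interpolated
#' in `eps` with a monotone (Fritsch-Carlson) cubic; evaluation outside the
#' calibrated grid raises an error rather than extrapolating.
#'
#' @param eps_grid ordered interaction energies (kT).
#' @param a1,a2,a3,a4 coefficient values at the grid points; `a2 > 0` required.
#' @param eps_theta theta energy; if `NULL`, located from the `a1` zero
#'   crossing (NA if `a1` does not change sign on the grid).
#' @param c_log fixed log coefficient, `-1.13`.
#' @param metadata named list (lattice, move set, seeds, sample sizes, ...).
#' @return object of class `coefficient_set`.
#' @export
coefficient_set <- function(eps_grid, a1, a2, a3, a4,
                            eps_theta = NULL, c_log = -1.13,
                            metadata = list()) {
  stopifnot(length(eps_grid) >= 2,
            !is.unsorted(eps_grid, strictly = TRUE),
            length(a1) == length(eps_grid), length(a2) == length(eps_grid),
            length(a3) == length(eps_grid), length(a4) == length(eps_grid))
  if (any(a2 <= 0)) stop("a2 must be positive on the calibrated range")
  obj <- list(table = data.frame(eps = eps_grid, a1 = a1, a2 = a2,
                                 a3 = a3, a4 = a4),
              c_log = c_log, metadata = metadata)
  obj$interp <- lapply(obj$table[c("a1", "a2", "a3", "a4")], function(v) {
    stats::splinefun(eps_grid, v, method = "monoH.FC")
  })
  class(obj) <- "coefficient_set"
  if (is.null(eps_theta)) {
    eps_theta <- tryCatch(locate_theta(obj), error = function(e) NA_real_)
  }
  obj$eps_theta <- eps_theta
  obj
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("Free-energy coefficient set: %d grid points, eps in [%.3f, %.3f] kT\n",
              nrow(x$table), min(x$table$eps), max(x$table$eps)))
  cat(sprintf("  theta point: eps_theta = %s kT; c_log = %.2f\n",
              ifelse(is.na(x$eps_theta), "NA", sprintf("%.4f", x$eps_theta)),
              x$c_log))
  invisible(x)
}

#' Interpolate the free-energy coefficients at an energy
#'
#' @param coeffs a [coefficient_set].
#' @param eps energy in kT; must lie inside the calibrated grid (no silent
#'   extrapolation).
#' @return named numeric vector `(a1, a2, a3, a4)`.
#' @export
coef_at <- function(coeffs, eps) {
  stopifnot(inherits(coeffs, "coefficient_set"), length(eps) == 1)
  tb <- coeffs$table
  if (eps < min(tb$eps) - 1e-12 || eps > max(tb$eps) + 1e-12) {
    stop(sprintf("eps = %g outside calibrated range [%g, %g]: refusing to extrapolate",
                 eps, min(tb$eps), max(tb$eps)))
  }
  eps <- min(max(eps, min(tb$eps)), max(tb$eps))
  c(a1 = coeffs$interp$a1(eps), a2 = coeffs$interp$a2(eps),
    a3 = coeffs$interp$a3(eps), a4 = coeffs$interp$a4(eps))
}

#' Write / read a coefficient set (versioned JSON)
#'
#' The on-disk format is a single JSON object with a format version, the
#' coefficient table, the theta energy, the fixed log coefficient and the
#' calibration metadata.
#'
#' @param coeffs a [coefficient_set].
#' @param path file path.
#' @return `write_coefficients` returns `path` invisibly;
#'   `read_coefficients` returns a [coefficient_set].
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  obj <- list(format = "chromocoil-coefficients",
              version = 1L,
              c_log = coeffs$c_log,
              eps_theta = coeffs$eps_theta,
              table = coeffs$table,
              metadata = coeffs$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chromocoil-coefficients")) {
    stop("not a chromocoil coefficient file: ", path)
  }
  tb <- as.data.frame(obj$table)
  coefficient_set(tb$eps, tb$a1, tb$a2, tb$a3, tb$a4,
                  eps_theta = obj$eps_theta, c_log = obj$c_log,
                  metadata = as.list(obj$metadata))
}

.chromocoil_cache <- new.env(parent = emptyenv())

#' Default calibrated coefficient set
#'
#' Loads the coefficient table shipped with the package, calibrated with
#' [build_calibration_grid()] and [fit_coefficients()] on cubic-lattice ISAW
#' simulations at N in \{16, 32, 64, 128, 256, 512\} over an energy grid
#' covering 0 to 0.6 kT (see the metadata of the returned object for seeds
#' and sample sizes).
#'
#' @return a [coefficient_set].
#' @export
default_coefficients <- function() {
  if (is.null(.chromocoil_cache$default_coeffs)) {
    path <- system.file("extdata", "coeffs-isaw-v1.json", package = "chromocoil",
                        mustWork = TRUE)
    .chromocoil_cache$default_coeffs <- read_coefficients(path)
  }
  .chromocoil_cache$default_coeffs
}
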