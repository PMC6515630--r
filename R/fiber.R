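#' Two-angle nucleosome fiber specification
#'
#' A regular nucleosome fiber is parameterized by the nucleosome repeat
#' length (NRL) and a wrapping angle spanning roughly +50 degrees (fully
#' wrapped, crystallographic, crossed linkers) to -30 degrees (largely open
#' nucleosome). The wrapped DNA is mapped linearly onto the angle: 147 bp at
#' +50 degrees, losing 1 bp per degree of opening (a configurable
#' convention; the module is a plausibility checker, not a crystallographic
#' model). The linker is the remaining DNA, `linker_bp = NRL - wrapped_bp`,
#' converted to nm at 0.34 nm/bp; linker torsion follows the DNA helical
#' twist of 10.5 bp/turn.
#'
#' Geometry: the entry-exit deflection between successive linker directions
#' is mapped linearly from the wrapping angle, from 0 degrees (collinear
#' linkers) at -30 to 150 degrees (strongly crossed) at +50.
#'
#' @param NRL nucleosome repeat length (bp).
#' @param wrap_angle wrapping angle in degrees, within [-30, 50].
#' @param bp_rise DNA rise per bp (nm).
#' @param helical_twist DNA helical repeat (bp/turn).
#' @param wrap_map function mapping the wrap angle to wrapped bp.
#' @return object of class `fiber_spec` with derived `linker_bp`,
#'   `linker_nm`, `deflection_deg`, `dihedral_deg`.
#' @export
fiber_spec <- function(NRL, wrap_angle, bp_rise = 0.34, helical_twist = 10.5,
                       wrap_map = function(a) 97 + a) {
  if (wrap_angle < -30 || wrap_angle > 50) {
    stop("wrap_angle must lie in [-30, 50] degrees")
  }
  wrapped_bp <- wrap_map(wrap_angle)
  linker_bp <- NRL - wrapped_bp
  if (linker_bp <= 0) {
    stop(sprintf("NRL = %g bp leaves no linker at wrap angle %g (wrapped %g bp)",
                 NRL, wrap_angle, wrapped_bp))
  }
  structure(list(NRL = NRL, wrap_angle = wrap_angle,
                 wrapped_bp = wrapped_bp, linker_bp = linker_bp,
                 linker_nm = linker_bp * bp_rise,
                 deflection_deg = (wrap_angle + 30) * 150 / 80,
                 dihedral_deg = (linker_bp %% helical_twist) / helical_twist * 360,
                 bp_rise = bp_rise, helical_twist = helical_twist),
            class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("fiber spec: NRL %g bp, wrap %g deg -> linker %.1f bp (%.1f nm), deflection %.1f deg, dihedral %.1f deg\n",
              x$NRL, x$wrap_angle, x$linker_bp, x$linker_nm,
              x$deflection_deg, x$dihedral_deg))
  invisible(x)
}

# build a chain of unit bond directions with fixed bond angle (deflection,
# degrees, between successive bonds) and fixed dihedral (degrees), returning
# n points spaced by len
.build_helix <- function(n, len, deflection_deg, dihedral_deg) {
  gam <- deflection_deg * pi / 180
  phi <- dihedral_deg * pi / 180
  tvec <- c(1, 0, 0); nvec <- c(0, 1, 0); bvec <- c(0, 0, 1)
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    pos[i, ] <- pos[i - 1, ] + len * tvec
    t_new <- cos(gam) * tvec + sin(gam) * (cos(phi) * nvec + sin(phi) * bvec)
    n_raw <- -sin(gam) * tvec + cos(gam) * (cos(phi) * nvec + sin(phi) * bvec)
    t_new <- t_new / sqrt(sum(t_new^2))
    n_new <- n_raw - sum(n_raw * t_new) * t_new
    n_new <- n_new / sqrt(sum(n_new^2))
    b_new <- c(t_new[2] * n_new[3] - t_new[3] * n_new[2],
               t_new[3] * n_new[1] - t_new[1] * n_new[3],
               t_new[1] * n_new[2] - t_new[2] * n_new[1])
    tvec <- t_new; nvec <- n_new; bvec <- b_new
  }
  pos
}

#' Build a regular two-angle fiber
#'
#' Nucleosomes are treated as points joined by straight rigid linkers; the
#' deflection between successive linkers and the dihedral (linker torsion)
#' are fixed by the [fiber_spec], producing a regular helix. Zero deflection
#' and zero dihedral give collinear nucleosomes.
#'
#' @param spec a [fiber_spec].
#' @param n_nucl number of nucleosomes, `>= 3`.
#' @return `n_nucl x 3` matrix of nucleosome coordinates in nm.
#' @export
build_regular_fiber <- function(spec, n_nucl) {
  stopifnot(inherits(spec, "fiber_spec"), n_nucl >= 3)
  pos <- .build_helix(n_nucl, spec$linker_nm, spec$deflection_deg,
                      spec$dihedral_deg)
  # steric sanity: nucleosome points must not coincide
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (min(d) < 1e-6) {
    stop("self-intersecting fiber geometry at these angles")
  }
  pos
}

#' Linear compaction of a regular fiber
#'
#' The fiber-axis rise per nucleosome is estimated from the end-to-end
#' displacement of the regular helix (which averages out the transverse
#' helical wobble); `c10 = 10 / rise` is the nucleosome line density per
#' 10 nm of fiber axis and `c_lin = NRL * c10 / 10` the compaction in bp/nm.
#'
#' @param coords nucleosome coordinates from [build_regular_fiber()]
#'   (at least one full helical period).
#' @param NRL nucleosome repeat length (bp).
#' @return list with `c10` (nucl./10 nm), `c_lin` (bp/nm), `rise_nm`.
#' @export
fiber_compaction <- function(coords, NRL) {
  stopifnot(is.matrix(coords), nrow(coords) >= 4)
  n <- nrow(coords)
  rise <- sqrt(sum((coords[n, ] - coords[1, ])^2)) / (n - 1)
  if (rise < 1e-4) {
    stop("degenerate fiber geometry: no defined axis (near-zero rise)")
  }
  list(c10 = 10 / rise, c_lin = NRL / rise, rise_nm = rise)
}

#' Geometric Kuhn length of the fluctuating fiber
#'
#' Maps the fiber to a chain of per-nucleosome virtual bonds (length
#' `b = linker_nm`) and estimates the Kuhn length from the orientation
#' correlation `g` between successive bonds via the freely rotating chain
#' relation `K = b (1 + g) / (1 - g)`. Thermal fluctuations enter through
#' the linker, modeled as a worm-like segment of DNA with persistence
#' length `P`: `g = cos(deflection) * exp(-linker / P)`, the deterministic
#' deflection attenuated by the linker's thermal orientation decorrelation.
#' Stiffer linkers (larger `P`) raise `g` and hence the Kuhn length.
#'
#' @param spec a [fiber_spec].
#' @param persistence_nm DNA persistence length (nm), default 50.
#' @return Kuhn length in nm.
#' @export
geometric_kuhn_length <- function(spec, persistence_nm = 50) {
  stopifnot(inherits(spec, "fiber_spec"), persistence_nm > 0)
  b <- spec$linker_nm
  g <- cos(spec$deflection_deg * pi / 180) * exp(-b / persistence_nm)
  if (g >= 1) stop("orientation correlation >= 1: rigid-rod limit exceeds validity")
  b * (1 + g) / (1 - g)
}

#' Geometry-based Kuhn length versus compaction curve
#'
#' Sweeps the wrapping angle at fixed NRL and tabulates the regular-fiber
#' compaction together with the geometric Kuhn length, the curve compared
#' against the data-derived ridge relation.
#'
#' @param NRL nucleosome repeat length (bp).
#' @param angles wrapping angles swept (degrees).
#' @param n_nucl nucleosomes per constructed fiber.
#' @param persistence_nm DNA persistence length (nm).
#' @return data.frame with `wrap_angle`, `c10`, `c_lin`, `K_geom_nm`.
#' @export
kuhn_vs_compaction_curve <- function(NRL, angles = seq(-29.5, 49.5, by = 0.5),
                                     n_nucl = 120L, persistence_nm = 50) {
  rows <- lapply(angles, function(a) {
    sp <- fiber_spec(NRL, a)
    cm <- tryCatch(fiber_compaction(build_regular_fiber(sp, n_nucl), NRL),
                   error = function(e) NULL)
    if (is.null(cm)) return(NULL)
    data.frame(wrap_angle = a, c10 = cm$c10, c_lin = cm$c_lin,
               K_geom_nm = geometric_kuhn_length(sp, persistence_nm))
  })
  do.call(rbind, rows)
}

#' Intercept of the geometric curve with the data ridge
#'
#' The coil-regime data constrain `K_nm = kappa K_bp^nu`; substituting
#' `K_bp = c K_nm` gives the data curve
#' `K_nm(c) = (kappa c^nu)^{1/(1-nu)}`. This finds the compaction(s) where
#' the geometry-based `K_geom(c)` curve crosses the data curve, returning
#' `(K_nm, K_bp = c K_nm)` at each crossing (all crossings are returned,
#' with a flag when there are several), or `NULL` when the curves do not
#' cross.
#'
#' @param curve data.frame from [kuhn_vs_compaction_curve()].
#' @param ridge list with `kappa` and `exponent` (as from [fit_ridge()]).
#' @return data.frame with `c_lin`, `K_nm`, `K_bp` (one row per crossing)
#'   with attribute `ambiguous = TRUE` when several crossings exist, or
#'   `NULL` if none.
#' @export
intercept_with_ridge <- function(curve, ridge) {
  stopifnot(all(c("c_lin", "K_geom_nm") %in% names(curve)))
  nu <- ridge$exponent
  if (nu >= 1) stop("ridge exponent must be < 1")
  cv <- curve[order(curve$c_lin), ]
  K_data <- (ridge$kappa * cv$c_lin^nu)^(1 / (1 - nu))
  diff_k <- cv$K_geom_nm - K_data
  sgn <- sign(diff_k)
  idx <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  if (!length(idx)) return(NULL)
  rows <- lapply(idx, function(i) {
    # linear interpolation of the crossing in c
    w <- diff_k[i] / (diff_k[i] - diff_k[i + 1])
    cc <- cv$c_lin[i] + w * (cv$c_lin[i + 1] - cv$c_lin[i])
    K <- (ridge$kappa * cc^nu)^(1 / (1 - nu))
    data.frame(c_lin = cc, K_nm = K, K_bp = cc * K)
  })
  out <- do.call(rbind, rows)
  attr(out, "ambiguous") <- nrow(out) > 1
  if (nrow(out) > 1) warning("multiple crossings between geometric and data curves")
  out
}

#' Export fiber coordinates as XYZ-style CSV
#'
#' @param coords nucleosome coordinates (nm).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fiber_xyz <- function(coords, path) {
  df <- data.frame(nucleosome = seq_len(nrow(coords)),
                   x_nm = coords[, 1], y_nm = coords[, 2], z_nm = coords[, 3])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
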