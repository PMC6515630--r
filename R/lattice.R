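#' Simulate an interacting self-avoiding walk on the cubic lattice
#'
#' Metropolis Monte Carlo sampling of a chain of `N` monomers on the simple
#' cubic lattice with contact energy `-eps` per non-bonded nearest-neighbour
#' pair (energies in units of kT). One lattice monomer represents one Kuhn
#' segment, so `eps` is directly the interaction energy per Kuhn segment. The
#' move set mixes pivot moves (random proper octahedral rotation about a
#' random internal site) with local moves (end rotation, corner flip,
#' crankshaft); a sweep is `N` attempted moves.
#'
#' @param N chain length (monomers), `>= 2`.
#' @param eps contact energy per non-bonded nearest-neighbour pair, in kT,
#'   `>= 0`.
#' @param n_samples number of recorded squared gyration radii.
#' @param seed integer seed; runs are fully reproducible given the seed.
#' @param sweeps_per_sample sweeps between recorded samples.
#' @param burnin_sweeps sweeps discarded before sampling.
#' @param p_pivot fraction of attempted moves that are pivots.
#' @param init_coords optional `N x 3` integer matrix of starting coordinates
#'   (used to chain runs when annealing across energies); defaults to a
#'   straight rod.
#' @param audit if `TRUE`, the incrementally tracked contact count is checked
#'   against a full recount every 1000 accepted moves (and at the end), and
#'   the run aborts on any mismatch.
#'
#' @return An object of class `isaw_samples`: a list with `rg2` (squared
#'   gyration radii in lattice = Kuhn-length^2 units), `N`, `eps`,
#'   `acceptance`, `tau_int` (integrated autocorrelation time of rg2, in
#'   recorded samples), `ess` (effective sample size) and `final_coords`.
#' @export
simulate_isaw <- function(N, eps, n_samples, seed,
                          sweeps_per_sample = 4L,
                          burnin_sweeps = NULL,
                          p_pivot = 0.2,
                          init_coords = NULL,
                          audit = FALSE) {
  stopifnot(N >= 2, eps >= 0, n_samples >= 1)
  if (is.null(burnin_sweeps)) {
    # generous default: local-move relaxation scales like N, pivots mix the
    # global shape in O(1) sweeps; dense chains are annealed via init_coords
    burnin_sweeps <- max(400L, 4L * as.integer(N))
  }
  set.seed(as.integer(seed))
  res <- isaw_run_cpp(as.integer(N), eps, as.integer(n_samples),
                      as.integer(sweeps_per_sample), as.integer(burnin_sweeps),
                      p_pivot, init_coords, audit)
  if (res$acceptance < 1e-4) {
    warning("move acceptance ", signif(res$acceptance, 2),
            " is close to zero: chain may be jammed (ergodicity at risk)")
  }
  tau <- .tau_int(res$rg2)
  out <- list(rg2 = res$rg2, N = N, eps = eps,
              acceptance = res$acceptance,
              tau_int = tau,
              ess = length(res$rg2) / (2 * tau),
              seed = as.integer(seed),
              sweeps_per_sample = sweeps_per_sample,
              burnin_sweeps = burnin_sweeps,
              final_coords = res$final_coords)
  class(out) <- "isaw_samples"
  out
}

#' @export
print.isaw_samples <- function(x, ...) {
  cat(sprintf("ISAW samples: N = %d, eps = %.3f kT, %d samples\n",
              x$N, x$eps, length(x$rg2)))
  cat(sprintf("  <Rg^2> = %.3f, acceptance = %.3f, tau_int = %.1f, ESS = %.0f\n",
              mean(x$rg2), x$acceptance, x$tau_int, x$ess))
  invisible(x)
}

# integrated autocorrelation time by the initial-positive-sequence rule
.tau_int <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(0.5)
  maxlag <- min(n %/% 4, 400L)
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1L)]
  0.5 + sum(ac)
}

#' Derive the per-entry seed for a calibration-grid cell
#'
#' Splitting rule: `(master + 7919 * i_N + 104729 * i_eps) mod (2^31 - 1)`,
#' where `i_N` and `i_eps` are 1-based indices into the `N` and `eps` lists.
#' @param master_seed integer master seed.
#' @param i_N,i_eps 1-based grid indices.
#' @return integer seed.
#' @export
grid_seed <- function(master_seed, i_N, i_eps) {
  as.integer((as.numeric(master_seed) + 7919 * i_N + 104729 * i_eps) %% 2147483647)
}

#' Build a calibration grid of gyration-radius samples over (N, eps)
#'
#' Runs [simulate_isaw()] at every combination of chain length and energy.
#' For each `N`, energies are visited in increasing order and the final
#' configuration of one run seeds the next (annealing), which keeps dense
#' globular states equilibrated; seeds are derived deterministically from the
#' master seed via [grid_seed()], so the whole grid is reproducible.
#'
#' @param N_list chain lengths.
#' @param eps_list energies in kT.
#' @param n_samples samples per grid entry.
#' @param seed master seed.
#' @param ess_floor entries whose effective sample size falls below this are
#'   flagged (`ok = FALSE`), never silently kept.
#' @param ... passed to [simulate_isaw()].
#' @return An object of class `calibration_grid`: list of entries with the
#'   fields of `isaw_samples` plus an `ok` flag, plus attributes recording the
#'   grids and master seed.
#' @export
build_calibration_grid <- function(N_list, eps_list, n_samples, seed,
                                   ess_floor = 50, ...) {
  stopifnot(length(N_list) >= 1, length(eps_list) >= 1)
  eps_list <- sort(eps_list)
  entries <- list()
  for (i_N in seq_along(N_list)) {
    N <- N_list[[i_N]]
    init <- NULL
    for (i_eps in seq_along(eps_list)) {
      eps <- eps_list[[i_eps]]
      s <- simulate_isaw(N, eps, n_samples,
                         seed = grid_seed(seed, i_N, i_eps),
                         init_coords = init, ...)
      s$ok <- s$ess >= ess_floor
      if (!s$ok) {
        warning(sprintf("grid entry N=%d eps=%.3f: ESS %.0f below floor %g",
                        N, eps, s$ess, ess_floor))
      }
      init <- s$final_coords
      entries[[sprintf("N%d_eps%.4f", N, eps)]] <- s
    }
  }
  structure(entries, class = "calibration_grid",
            N_list = N_list, eps_list = eps_list,
            n_samples = n_samples, master_seed = seed)
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf("ISAW calibration grid: %d entries, N in {%s}, eps in [%.2f, %.2f]\n",
              length(x), paste(attr(x, "N_list"), collapse = ", "),
              min(attr(x, "eps_list")), max(attr(x, "eps_list"))))
  invisible(x)
}

#' Mean squared gyration radius per grid entry
#'
#' @param grid a `calibration_grid`.
#' @return data.frame with columns `N`, `eps`, `mean_rg2`, `se`, `ess`.
#' @export
grid_means <- function(grid) {
  stopifnot(inherits(grid, "calibration_grid"))
  do.call(rbind, lapply(grid, function(s) {
    data.frame(N = s$N, eps = s$eps, mean_rg2 = mean(s$rg2),
               se = stats::sd(s$rg2) / sqrt(max(s$ess, 1)), ess = s$ess)
  }))
}

#' Locate the theta point
#'
#' Two estimators are provided, dispatched on the input class. For a
#' [coefficient_set] the theta energy is the zero crossing of the second
#' virial coefficient `a1(eps)` (root finding on the interpolant). For a
#' `calibration_grid` it is the energy at which `<Rg^2>` scales linearly with
#' `N` (random-walk scaling): for each energy the log-log slope of `<Rg^2>`
#' versus `N` is computed, and the energy where the slope crosses 1 is
#' interpolated.
#'
#' @param x a `coefficient_set` or a `calibration_grid`.
#' @param ... unused.
#' @return theta energy in kT.
#' @export
locate_theta <- function(x, ...) UseMethod("locate_theta")

#' @rdname locate_theta
#' @export
locate_theta.coefficient_set <- function(x, ...) {
  a1 <- x$table$a1
  eg <- x$table$eps
  if (min(a1) > 0 || max(a1) < 0) {
    stop("a1(eps) does not change sign on the calibrated range; cannot locate theta")
  }
  f <- stats::splinefun(eg, a1, method = "monoH.FC")
  # bracket at the first sign change of the tabulated values
  i <- which(diff(sign(a1)) != 0)[1]
  stats::uniroot(f, lower = eg[i], upper = eg[i + 1], tol = 1e-8)$root
}

#' @rdname locate_theta
#' @export
locate_theta.calibration_grid <- function(x, ...) {
  gm <- grid_means(x)
  eps_list <- sort(unique(gm$eps))
  if (length(unique(gm$N)) < 3) stop("need >= 3 chain lengths to fit slopes")
  slopes <- vapply(eps_list, function(e) {
    d <- gm[gm$eps == e, ]
    stats::coef(stats::lm(log(mean_rg2) ~ log(N), data = d))[2]
  }, numeric(1))
  dev <- slopes - 1
  if (min(dev) > 0 || max(dev) < 0) {
    stop("log-log slope of <Rg^2> vs N does not cross 1 on the energy range; ",
         "widen the eps grid")
  }
  i <- which(diff(sign(dev)) != 0)[1]
  # linear interpolation of the slope-1 crossing
  e1 <- eps_list[i]; e2 <- eps_list[i + 1]
  d1 <- dev[i]; d2 <- dev[i + 1]
  e1 - d1 * (e2 - e1) / (d2 - d1)
}

#' Exact enumeration of self-avoiding walks (small chains)
#'
#' Brute-force enumeration of all cubic-lattice self-avoiding walks of `N`
#' sites, returning each walk's squared gyration radius and Boltzmann weight
#' `exp(eps * contacts)`. Used as an independent oracle for the Monte Carlo
#' sampler; feasible for `N <= 7` or so.
#'
#' @param N number of sites.
#' @param eps contact energy in kT.
#' @return data.frame with columns `rg2`, `contacts`, `weight`, one row per
#'   walk (walks related by symmetry are enumerated individually).
#' @export
enumerate_saw_rg2 <- function(N, eps = 0) {
  stopifnot(N >= 2, N <= 8)
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  out <- list()
  rec <- function(coords) {
    n <- nrow(coords)
    if (n == N) {
      g <- colMeans(coords)
      rg2 <- mean(rowSums(sweep(coords, 2, g)^2))
      cc <- 0L
      for (i in seq_len(N)) {
        for (j in seq_len(N)) {
          if (j > i + 1 && sum(abs(coords[i, ] - coords[j, ])) == 1) cc <- cc + 1L
        }
      }
      out[[length(out) + 1L]] <<- c(rg2, cc)
      return(invisible())
    }
    last <- coords[n, ]
    for (k in 1:6) {
      nxt <- last + dirs[k, ]
      if (!any(coords[, 1] == nxt[1] & coords[, 2] == nxt[2] & coords[, 3] == nxt[3])) {
        rec(rbind(coords, nxt))
      }
    }
  }
  rec(matrix(0, nrow = 1, ncol = 3))
  m <- do.call(rbind, out)
  data.frame(rg2 = m[, 1], contacts = m[, 2], weight = exp(eps * m[, 2]))
}
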