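#' Per-cell gyration-radius dataset
#'
#' Validates and wraps a data.frame of per-cell squared gyration radii with
#' columns `domain_id`, `color` (one of `active`, `inactive`, `repressed`),
#' `length_bp`, `cell_id`, `rg2_nm2`. Each domain is expected to be observed
#' in 20-100 cells (a warning, not an error, outside that range).
#'
#' @param df data.frame with the columns above.
#' @return object of class `gyration_dataset` (a data.frame).
#' @export
gyration_dataset <- function(df) {
  req <- c("domain_id", "color", "length_bp", "cell_id", "rg2_nm2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!df$color %in% c("active", "inactive", "repressed"))) {
    bad <- which(!df$color %in% c("active", "inactive", "repressed"))
    stop("unknown color in rows ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(df$rg2_nm2 <= 0)) {
    stop("nonpositive rg2 in rows ",
         paste(head(which(df$rg2_nm2 <= 0), 5), collapse = ", "))
  }
  if (any(df$length_bp <= 0)) {
    stop("nonpositive length in rows ",
         paste(head(which(df$length_bp <= 0), 5), collapse = ", "))
  }
  if (anyDuplicated(df[, c("domain_id", "cell_id")])) {
    stop("duplicate (domain_id, cell_id) records")
  }
  cc <- table(df$domain_id)
  if (any(cc < 20 | cc > 100)) {
    warning(sum(cc < 20 | cc > 100),
            " domain(s) observed outside the expected 20-100 cell range")
  }
  class(df) <- c("gyration_dataset", "data.frame")
  df
}

#' @export
print.gyration_dataset <- function(x, ...) {
  dom <- unique(as.data.frame(x)[, c("domain_id", "color")])
  cat(sprintf("gyration dataset: %d observations, %d domains (%s)\n",
              nrow(x), nrow(dom),
              paste(sprintf("%s: %d", names(table(dom$color)), table(dom$color)),
                    collapse = ", ")))
  invisible(x)
}

# parameter vector layout per model variant
.theta_names <- function(variant = c("full", "constant_bundle")) {
  variant <- match.arg(variant)
  if (variant == "full") c("eps", "K_bp", "K_nm", "a0", "a_inf", "N0")
  else c("eps", "K_bp", "K_nm", "a0")
}

.theta_to_model <- function(theta, variant) {
  if (variant == "full") {
    list(params = model_params(theta[1], theta[2], theta[3]),
         bundle = bundle_params(theta[4], theta[5], theta[6]))
  } else {
    list(params = model_params(theta[1], theta[2], theta[3]),
         bundle = bundle_params(theta[4]))
  }
}

#' Total log-likelihood of a one-color dataset
#'
#' Sum over domain lengths of the log-likelihoods of the per-cell `Rg^2`
#' observations under the bundle-convolved model density:
#' `LL = sum_L sum_i ln (P_L * f_lambda)(rg2_i)`. Observations with zero
#' model density (outside the support implied by `theta`) yield a large
#' negative sentinel rather than `-Inf`-driven errors.
#'
#' @param dataset a [gyration_dataset] restricted to a single color.
#' @param theta parameter vector: `(eps, K_bp, K_nm, a0, a_inf, N0)` for the
#'   full variant, `(eps, K_bp, K_nm, a0)` for the constant-bundle variant.
#' @param coeffs a [coefficient_set].
#' @param variant `"full"` or `"constant_bundle"`.
#' @return scalar log-likelihood (sentinel `-1e10` outside the support).
#' @export
total_log_likelihood <- function(dataset, theta, coeffs = default_coefficients(),
                                 variant = c("full", "constant_bundle")) {
  variant <- match.arg(variant)
  df <- as.data.frame(dataset)
  if (nrow(df) == 0) stop("empty dataset")
  if (length(unique(df$color)) > 1) {
    stop("dataset spans several colors; fit each color separately")
  }
  names(theta) <- .theta_names(variant)
  mdl <- tryCatch(.theta_to_model(theta, variant), error = function(e) NULL)
  if (is.null(mdl)) return(-1e10)
  eps_rng <- range(coeffs$table$eps)
  if (theta[["eps"]] < eps_rng[1] || theta[["eps"]] > eps_rng[2]) return(-1e10)
  total <- 0
  for (L in unique(df$length_bp)) {
    x <- df$rg2_nm2[df$length_bp == L]
    if (L / mdl$params$K_bp < 2) return(-1e10)
    g <- tryCatch(
      .single_poly_grid(L, mdl$params, mdl$bundle, coeffs),
      error = function(e) NULL)
    if (is.null(g)) return(-1e10)
    d <- .convolve_eval(x, g$x, g$fx, 1 / g$sigma^2)
    if (any(d <= 0)) return(-1e10)
    total <- total + sum(log(d))
  }
  total
}

#' Default prior bounds for the Bayesian fit
#'
#' Uniform (positivity-enforcing) prior box: eps in (0, 1] kT, K_bp in
#' (100, 20000] bp, K_nm in (5, 300] nm, a0 and a_inf in (1, 1000] nm, N0 in
#' (1, 5000]. The eps range is additionally clipped to the calibrated
#' coefficient grid at likelihood evaluation.
#'
#' @param variant model variant.
#' @return matrix with columns `lower`, `upper` and one row per parameter.
#' @export
default_prior_bounds <- function(variant = c("full", "constant_bundle")) {
  variant <- match.arg(variant)
  b <- rbind(eps = c(1e-3, 1), K_bp = c(100, 20000), K_nm = c(5, 300),
             a0 = c(1, 1000), a_inf = c(1, 1000), N0 = c(1, 5000))
  colnames(b) <- c("lower", "upper")
  b[.theta_names(variant), , drop = FALSE]
}

#' Bayesian inference of the polymer and bundle parameters
#'
#' Samples the posterior of `theta` (uniform prior on the bounds times the
#' total likelihood) for a one-color dataset with the affine-invariant
#' ensemble sampler ([stretch_sampler()]). Walkers start in a small ball
#' around `init` (or around the prior-box center on the log scale). The
#' constant-bundle variant drops `(a_inf, N0)` and is the recommended model
#' for repressed domains.
#'
#' @param dataset a one-color [gyration_dataset].
#' @param coeffs a [coefficient_set].
#' @param prior_bounds bounds matrix as from [default_prior_bounds()].
#' @param n_walkers number of walkers (default `8 * dim`).
#' @param n_steps ensemble steps.
#' @param seed integer seed.
#' @param variant `"full"` or `"constant_bundle"`.
#' @param init optional center of the walker initialization ball.
#' @param burn_in steps discarded by [summarize_posterior()] and accessors;
#'   default half the chain.
#' @return object of class `posterior_samples`: chains
#'   (`n_steps x n_walkers x dim`), log posterior, parameter names, burn-in,
#'   acceptance, autocorrelation time and ESS per parameter, seed.
#' @export
run_ensemble_mcmc <- function(dataset, coeffs = default_coefficients(),
                              prior_bounds = NULL, n_walkers = NULL,
                              n_steps = 600, seed = 1,
                              variant = c("full", "constant_bundle"),
                              init = NULL, burn_in = NULL) {
  variant <- match.arg(variant)
  pn <- .theta_names(variant)
  dim <- length(pn)
  if (is.null(prior_bounds)) prior_bounds <- default_prior_bounds(variant)
  stopifnot(nrow(prior_bounds) == dim, all(prior_bounds[, "lower"] > 0),
            all(is.finite(prior_bounds[, "upper"])))
  if (is.null(n_walkers)) n_walkers <- 8L * dim
  # cap eps inside the calibrated range so the prior support is computable
  eps_rng <- range(coeffs$table$eps)
  prior_bounds["eps", "lower"] <- max(prior_bounds["eps", "lower"],
                                      eps_rng[1] + 1e-6)
  prior_bounds["eps", "upper"] <- min(prior_bounds["eps", "upper"], eps_rng[2])

  log_post <- function(theta) {
    if (any(theta <= prior_bounds[, "lower"]) ||
        any(theta > prior_bounds[, "upper"])) return(-Inf)
    if (variant == "full" && theta[5] < theta[4]) return(-Inf)  # a_inf >= a0
    ll <- total_log_likelihood(dataset, theta, coeffs, variant)
    if (ll <= -1e9) return(-Inf)
    ll
  }

  set.seed(as.integer(seed))
  if (is.null(init)) {
    init <- exp((log(prior_bounds[, "lower"]) + log(prior_bounds[, "upper"])) / 2)
  }
  pos <- matrix(NA_real_, n_walkers, dim)
  k <- 1
  tries <- 0
  while (k <= n_walkers) {
    cand <- init * exp(stats::rnorm(dim, 0, 0.15))
    if (is.finite(log_post(cand))) {
      pos[k, ] <- cand
      k <- k + 1
    }
    tries <- tries + 1
    if (tries > 200 * n_walkers) {
      stop("could not initialize walkers at finite posterior density; ",
           "check init / prior bounds against the data")
    }
  }

  res <- stretch_sampler(log_post, pos, n_steps,
                         seed = as.integer((as.numeric(seed) + 104729) %% 2147483647))
  if (res$acceptance < 0.1 || res$acceptance > 0.9) {
    warning(sprintf("ensemble acceptance fraction %.2f outside [0.1, 0.9]",
                    res$acceptance))
  }
  if (is.null(burn_in)) burn_in <- n_steps %/% 2
  tau <- vapply(seq_len(dim), function(j) {
    .tau_int(rowMeans(res$chain[, , j]))
  }, numeric(1))
  ess <- (n_steps - burn_in) * n_walkers / (2 * pmax(tau, 0.5))
  out <- list(chain = res$chain, log_prob = res$log_prob,
              par_names = pn, burn_in = burn_in,
              acceptance = res$acceptance, tau_int = tau, ess = ess,
              variant = variant, seed = as.integer(seed),
              prior_bounds = prior_bounds)
  class(out) <- "posterior_samples"
  out
}

#' Post-burn-in samples as a matrix
#'
#' @param post a `posterior_samples`.
#' @return matrix (draws x parameters) of post-burn-in samples.
#' @export
posterior_matrix <- function(post) {
  stopifnot(inherits(post, "posterior_samples"))
  keep <- seq(post$burn_in + 1, dim(post$chain)[1])
  if (!length(keep)) stop("empty post-burn-in chain")
  m <- apply(post$chain[keep, , , drop = FALSE], 3, identity)
  colnames(m) <- post$par_names
  m
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$chain)
  cat(sprintf("posterior samples (%s variant): %d steps x %d walkers x %d params\n",
              x$variant, d[1], d[2], d[3]))
  cat(sprintf("  acceptance %.2f, burn-in %d; min ESS %.0f\n",
              x$acceptance, x$burn_in, min(x$ess)))
  invisible(x)
}

#' Posterior summary: mean, SD, correlations, marginals
#'
#' @param post a `posterior_samples`.
#' @param breaks number of bins for the serialized marginal histograms.
#' @return list with `table` (data.frame: parameter, mean, sd),
#'   `correlation` (matrix), `marginals` (per-parameter histogram with
#'   `mids` and `density`), `n_samples`.
#' @export
summarize_posterior <- function(post, breaks = 40) {
  m <- posterior_matrix(post)
  tb <- data.frame(parameter = colnames(m),
                   mean = colMeans(m),
                   sd = apply(m, 2, stats::sd),
                   row.names = NULL)
  marg <- lapply(seq_len(ncol(m)), function(j) {
    h <- graphics::hist(m[, j], breaks = breaks, plot = FALSE)
    list(mids = h$mids, density = h$density)
  })
  names(marg) <- colnames(m)
  list(table = tb, correlation = stats::cor(m), marginals = marg,
       n_samples = nrow(m))
}

#' Fit the Kuhn-length degeneracy ridge
#'
#' In the coil regime the likelihood constrains only the combination
#' `K_nm ~ kappa * K_bp^nu`, so the joint posterior of `(K_bp, K_nm)`
#' concentrates along a power-law ridge. This fits that ridge by total least
#' squares in log-log space (first principal component of the centered
#' `(ln K_bp, ln K_nm)` cloud) and returns `(kappa, exponent)` with
#' bootstrap standard errors. If the log-space correlation is weak
#' (`|r| < 0.5`), the posterior is not ridge-degenerate and a warning is
#' issued: the marginal means are then the meaningful summary, not the
#' ridge.
#'
#' @param post a `posterior_samples`, or a two-column matrix/data.frame of
#'   `(K_bp, K_nm)` samples.
#' @param n_boot bootstrap replicates.
#' @param seed optional seed for the bootstrap.
#' @return list with `kappa`, `exponent`, `kappa_se`, `exponent_se`,
#'   `log_correlation`.
#' @export
fit_ridge <- function(post, n_boot = 200, seed = NULL) {
  if (inherits(post, "posterior_samples")) {
    m <- posterior_matrix(post)[, c("K_bp", "K_nm")]
  } else {
    m <- as.matrix(post)
    stopifnot(ncol(m) == 2)
    colnames(m) <- c("K_bp", "K_nm")
  }
  lx <- log(m[, "K_bp"]); ly <- log(m[, "K_nm"])
  r <- stats::cor(lx, ly)
  if (abs(r) < 0.5) {
    warning(sprintf("log-space correlation %.2f < 0.5: posterior is not ", r),
            "ridge-degenerate; ridge parameters are not meaningful")
  }
  tls <- function(lx, ly) {
    v <- eigen(stats::cov(cbind(lx, ly)))$vectors[, 1]
    slope <- v[2] / v[1]
    c(exponent = slope, kappa = exp(mean(ly) - slope * mean(lx)))
  }
  est <- tls(lx, ly)
  if (!is.null(seed)) set.seed(as.integer(seed))
  boot <- t(vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(lx), replace = TRUE)
    tls(lx[idx], ly[idx])
  }, numeric(2)))
  list(kappa = unname(est["kappa"]), exponent = unname(est["exponent"]),
       kappa_se = stats::sd(boot[, "kappa"]),
       exponent_se = stats::sd(boot[, "exponent"]),
       log_correlation = r)
}
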