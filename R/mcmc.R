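#' Affine-invariant ensemble sampler (stretch moves)
#'
#' Goodman-Weare ensemble MCMC: an ensemble of walkers explores the target
#' by "stretch" proposals, each walker moving along the line through itself
#' and a randomly chosen walker of the complementary half-ensemble, with the
#' scale drawn from g(z) ∝ 1/sqrt(z) on [1/a, a]. Affine invariance makes
#' the sampler insensitive to strong linear correlations between parameters
#' (such as the Kuhn-length degeneracy ridge). Walkers are updated in two
#' half-ensemble sweeps per step so that proposals use fixed complementary
#' positions.
#'
#' @param log_post function taking a parameter vector, returning the log
#'   posterior density (may return `-Inf`).
#' @param init matrix `n_walkers x dim` of starting positions.
#' @param n_steps number of ensemble steps.
#' @param seed integer seed; chains are deterministic given the seed.
#' @param a stretch scale parameter (default 2).
#' @return list with `chain` (array `n_steps x n_walkers x dim`), `log_prob`
#'   (`n_steps x n_walkers`), `acceptance` (overall fraction).
#' @export
stretch_sampler <- function(log_post, init, n_steps, seed, a = 2) {
  stopifnot(is.matrix(init), nrow(init) >= 4, n_steps >= 1)
  n_walkers <- nrow(init)
  dim <- ncol(init)
  if (n_walkers < 2 * dim) stop("need at least 2*dim walkers")
  if (n_walkers %% 2 != 0) stop("n_walkers must be even")
  set.seed(as.integer(seed))
  pos <- init
  lp <- apply(pos, 1, log_post)
  if (any(!is.finite(lp))) {
    stop("some walkers start at zero posterior density; adjust init")
  }
  chain <- array(NA_real_, dim = c(n_steps, n_walkers, dim))
  lp_out <- matrix(NA_real_, n_steps, n_walkers)
  half <- n_walkers / 2
  sets <- list(seq_len(half), half + seq_len(half))
  n_acc <- 0
  for (s in seq_len(n_steps)) {
    for (h in 1:2) {
      act <- sets[[h]]
      oth <- sets[[3 - h]]
      for (k in act) {
        j <- oth[sample.int(half, 1)]
        z <- (1 + (a - 1) * stats::runif(1))^2 / a
        prop <- pos[j, ] + z * (pos[k, ] - pos[j, ])
        lp_prop <- log_post(prop)
        log_acc <- (dim - 1) * log(z) + lp_prop - lp[k]
        if (is.finite(lp_prop) && log(stats::runif(1)) < log_acc) {
          pos[k, ] <- prop
          lp[k] <- lp_prop
          n_acc <- n_acc + 1
        }
      }
    }
    chain[s, , ] <- pos
    lp_out[s, ] <- lp
  }
  list(chain = chain, log_prob = lp_out,
       acceptance = n_acc / (n_steps * n_walkers))
}
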