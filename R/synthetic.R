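#' Sample observed squared gyration radii from the generative model
#'
#' Draws single-polymer `Rg^2` by inverse-CDF sampling from the dimensional
#' finite-size density and adds an independent exponential bundle term with
#' spread `sigma(L/K_bp)` — the generative counterpart of the likelihood.
#'
#' @param L domain length in bp.
#' @param params a [model_params].
#' @param bundle a [bundle_params] or `NULL` (haploid samples).
#' @param coeffs a [coefficient_set].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of observed `Rg^2` in nm^2.
#' @export
sample_rg2 <- function(L, params, bundle, coeffs = default_coefficients(),
                       n = 1, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  N <- L / params$K_bp
  if (N < 2) stop(sprintf("L = %g bp gives N = %.2f < 2", L, N))
  if (!is.null(seed)) set.seed(as.integer(seed))
  single <- sample_rg2_adim(n, N, params$eps, coeffs) * params$K_nm^2
  if (is.null(bundle)) return(single)
  sigma <- sigma_of_N(N, bundle)
  single + stats::rexp(n, rate = 1 / sigma^2)
}

#' Specification of a synthetic multi-domain study
#'
#' Defaults emulate the design of the super-resolution study the model is
#' built for: three epigenetic colors with 23 (active), 14 (inactive) and 11
#' (repressed) domains, each observed in a uniform 20-100 cells, domain
#' lengths log-uniform in 15-500 kb, and per-color generating parameters set
#' to the headline fitted values (active: eps 0.10 kT, K_bp 1300 bp, K_nm
#' 35 nm, bundle 130/290/630; inactive: 0.32, 3900, 60, bundle 93/170/10;
#' repressed: 0.44, 1500, 37, constant bundle a0 = 94 nm).
#'
#' @param colors named list per color with entries `params` ([model_params]),
#'   `bundle` ([bundle_params]), `n_domains`.
#' @param length_range domain length range (bp) for the log-uniform sampler.
#' @param cells_range integer range of cells per domain.
#' @param seed master seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(colors = NULL,
                           length_range = c(15e3, 500e3),
                           cells_range = c(20L, 100L),
                           seed = 1L) {
  if (is.null(colors)) {
    colors <- list(
      active = list(params = model_params(0.10, 1300, 35),
                    bundle = bundle_params(130, 290, 630),
                    n_domains = 23L),
      inactive = list(params = model_params(0.32, 3900, 60),
                      bundle = bundle_params(93, 170, 10),
                      n_domains = 14L),
      repressed = list(params = model_params(0.44, 1500, 37),
                       bundle = bundle_params(94),
                       n_domains = 11L))
  }
  for (cl in names(colors)) {
    stopifnot(inherits(colors[[cl]]$params, "model_params"),
              inherits(colors[[cl]]$bundle, "bundle_params"),
              colors[[cl]]$n_domains >= 1)
    if (length_range[1] / colors[[cl]]$params$K_bp < 2) {
      stop(sprintf("color %s: shortest length %g bp gives N < 2", cl,
                   length_range[1]))
    }
  }
  structure(list(colors = colors, length_range = length_range,
                 cells_range = cells_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws domain lengths, cell counts and per-cell observed `Rg^2` for every
#' color of the [synthetic_spec]. The same spec and seed always produce the
#' identical dataset. The ground-truth generating parameters are returned
#' alongside (and may be written as a JSON sidecar) for parameter-recovery
#' scoring; fitting code must never read them.
#'
#' @param spec a [synthetic_spec].
#' @param coeffs a [coefficient_set].
#' @return list with `dataset` (a [gyration_dataset]) and `truth` (named
#'   list per color of generating parameters).
#' @export
generate_dataset <- function(spec, coeffs = default_coefficients()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- list()
  truth <- list()
  for (cl in names(spec$colors)) {
    cfg <- spec$colors[[cl]]
    nd <- cfg$n_domains
    Ls <- round(exp(stats::runif(nd, log(spec$length_range[1]),
                                 log(spec$length_range[2]))))
    cells <- sample(seq(spec$cells_range[1], spec$cells_range[2]), nd,
                    replace = TRUE)
    dseeds <- sapply(seq_len(nd), function(i) {
      as.integer((as.numeric(spec$seed) + 15485863 * match(cl, names(spec$colors)) +
                    32452843 * i) %% 2147483647)
    })
    for (i in seq_len(nd)) {
      id <- sprintf("%s_%02d", cl, i)
      rg2 <- sample_rg2(Ls[i], cfg$params, cfg$bundle, coeffs,
                        n = cells[i], seed = dseeds[i])
      rows[[id]] <- data.frame(domain_id = id, color = cl,
                               length_bp = Ls[i],
                               cell_id = seq_len(cells[i]),
                               rg2_nm2 = rg2)
    }
    truth[[cl]] <- list(eps = cfg$params$eps, K_bp = cfg$params$K_bp,
                        K_nm = cfg$params$K_nm,
                        a0 = cfg$bundle$a0, a_inf = cfg$bundle$a_inf,
                        N0 = cfg$bundle$N0,
                        constant_section = cfg$bundle$constant_section,
                        lengths_bp = Ls, cells = cells)
  }
  list(dataset = gyration_dataset(do.call(rbind, c(rows, make.row.names = FALSE))),
       truth = truth)
}

#' Write the ground-truth sidecar
#'
#' @param truth the `truth` element from [generate_dataset()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic marker-enrichment trace over domains
#'
#' Binned boxcar enrichment over a set of non-overlapping domain intervals
#' plus i.i.d. Gaussian noise — the input expected by the moving-average
#' domain caller.
#'
#' @param domains data.frame with 0-based half-open `start`, `end` (bp).
#' @param genome_length trace extent (bp).
#' @param bin_size bin width (bp).
#' @param enrichment boxcar height over domains.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional seed.
#' @return data.frame with `start`, `end`, `value` (one row per bin).
#' @export
generate_enrichment_trace <- function(domains, genome_length, bin_size = 1000,
                                      enrichment = 1, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(all(domains$end > domains$start))
  o <- domains[order(domains$start), ]
  if (nrow(o) > 1 && any(o$start[-1] < o$end[-nrow(o)])) {
    stop("domain intervals overlap")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  starts <- seq(0, genome_length - 1, by = bin_size)
  ends <- pmin(starts + bin_size, genome_length)
  mids <- (starts + ends) / 2
  value <- numeric(length(starts))
  for (i in seq_len(nrow(o))) {
    value[mids >= o$start[i] & mids < o$end[i]] <- enrichment
  }
  if (noise_sd > 0) value <- value + stats::rnorm(length(value), 0, noise_sd)
  data.frame(start = starts, end = ends, value = value)
}

#' Call candidate domains by moving-average filtering
#'
#' Applies a moving-average filter whose window equals the candidate domain
#' length `L` (the window is by definition the domain length, never a free
#' parameter) to the binned enrichment trace, then reports maximal runs of
#' bins whose filtered value exceeds the threshold as candidate intervals
#' (0-based half-open, bp).
#'
#' @param trace data.frame from [generate_enrichment_trace()] (or any binned
#'   trace with `start`, `end`, `value`).
#' @param L candidate domain length in bp; must be at least one bin.
#' @param threshold filtered-enrichment threshold.
#' @return data.frame with `start`, `end` (bp) of candidate domains.
#' @export
call_domains <- function(trace, L, threshold = 0.5) {
  bin_size <- trace$end[1] - trace$start[1]
  if (L < bin_size) stop("window L is shorter than one bin")
  w <- max(1L, round(L / bin_size))
  filt <- as.numeric(stats::filter(trace$value, rep(1 / w, w), sides = 2))
  above <- !is.na(filt) & filt > threshold
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = trace$start[starts_idx[keep]],
             end = trace$end[ends_idx[keep]])
}
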