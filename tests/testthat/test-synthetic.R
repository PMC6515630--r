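test_that("generative sampling matches the convolved model", {
  cs <- toy_coeffs()
  pm <- model_params(0.32, 3900, 60)
  bp <- bundle_params(93, 170, 10)
  L <- 2.5e5
  x <- sample_rg2(L, pm, bp, cs, n = 1e5, seed = 33)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - convolved_mean_rg2(L, pm, bp, cs)), 3 * se)
  # identical seed, identical draws
  expect_identical(sample_rg2(L, pm, bp, cs, n = 50, seed = 33),
                   sample_rg2(L, pm, bp, cs, n = 50, seed = 33))
  # sigma = 0 variant: distribution passes a KS test against the bare model
  x0 <- sample_rg2(L, pm, NULL, cs, n = 3000, seed = 34)
  g <- chromocoil:::.pdf_grid_adim(L / pm$K_bp, pm$eps, cs)
  model_cdf <- function(q) {
    stats::approx(g$rg2 * pm$K_nm^2, g$cdf, xout = q, rule = 2)$y
  }
  D <- max(abs(stats::ecdf(x0)(sort(x0)) - model_cdf(sort(x0))))
  expect_lt(D, 1.63 / sqrt(3000))    # 1% KS critical value
})

test_that("generated datasets follow the study design and are reproducible", {
  cs <- toy_coeffs()
  spec <- synthetic_spec(seed = 77)
  out <- generate_dataset(spec, cs)
  df <- as.data.frame(out$dataset)
  dom <- unique(df[, c("domain_id", "color")])
  counts <- table(dom$color)
  expect_equal(unname(counts["active"]), 23)
  expect_equal(unname(counts["inactive"]), 14)
  expect_equal(unname(counts["repressed"]), 11)
  cells <- table(df$domain_id)
  expect_true(all(cells >= 20 & cells <= 100))
  expect_true(all(df$length_bp >= 15e3 & df$length_bp <= 500e3))
  # determinism from spec + seed
  out2 <- generate_dataset(synthetic_spec(seed = 77), cs)
  expect_identical(df, as.data.frame(out2$dataset))
  # ground truth records the generating parameters
  expect_equal(out$truth$repressed$eps, 0.44)
  expect_true(out$truth$repressed$constant_section)
  p <- tempfile(fileext = ".json")
  write_ground_truth(out$truth, p)
  expect_equal(jsonlite::read_json(p, simplifyVector = TRUE)$active$K_bp, 1300)
})

test_that("enrichment traces and the moving-average caller round-trip planted domains", {
  doms <- data.frame(start = c(100e3, 400e3), end = c(160e3, 460e3))
  tr <- generate_enrichment_trace(doms, genome_length = 6e5, bin_size = 1e3,
                                  enrichment = 1, noise_sd = 0)
  # zero noise: trace is the indicator function
  mids <- (tr$start + tr$end) / 2
  inside <- (mids >= 1e5 & mids < 1.6e5) | (mids >= 4e5 & mids < 4.6e5)
  expect_true(all(tr$value[inside] == 1))
  expect_true(all(tr$value[!inside] == 0))
  called <- call_domains(tr, L = 60e3, threshold = 0.5)
  expect_equal(nrow(called), 2)
  # half-window edge effects at most
  expect_lt(max(abs(called$start - doms$start)), 31e3)
  expect_lt(max(abs(called$end - doms$end)), 31e3)
  # noisy trace still recovers both domains
  trn <- generate_enrichment_trace(doms, 6e5, 1e3, 1, noise_sd = 0.3, seed = 5)
  expect_gt(mean(trn$value[inside]), mean(trn$value[!inside]))
  calledn <- call_domains(trn, L = 60e3, threshold = 0.5)
  expect_gte(nrow(calledn), 2)
  expect_error(generate_enrichment_trace(
    data.frame(start = c(0, 5e4), end = c(6e4, 9e4)), 1e5), "overlap")
  expect_error(call_domains(tr, L = 10), "bin")
})

test_that("average likelihood is maximized near the generating parameters", {
  # generative/likelihood duality on a local grid around the truth
  cs <- toy_coeffs()
  pm <- model_params(0.44, 1500, 37)
  bp <- bundle_params(94)
  ds <- make_color_data(cs, pm, bp, n_domains = 5, n_cells = 60, seed = 19)
  at <- function(f) total_log_likelihood(ds, c(0.44 * f[1], 1500 * f[2],
                                               37 * f[3], 94 * f[4]),
                                         cs, "constant_bundle")
  ll0 <- at(c(1, 1, 1, 1))
  for (j in 1:4) {
    for (d in c(0.7, 1.4)) {
      f <- rep(1, 4); f[j] <- d
      expect_lt(at(f), ll0)
    }
  }
})
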