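#' Read per-cell gyration-radius measurements
#'
#' Reads a TSV/CSV table with header columns `domain_id`, `color`,
#' `length_bp`, `cell_id` and exactly one radius column: either `rg_nm`
#' (radius, nm) or `rg2_nm2` (squared radius, nm^2); the unit is carried by
#' the column name, so ambiguity (both or neither present) is an error.
#' Radii are converted to squared radii internally.
#'
#' @param path file path; tab- or comma-separated, sniffed from the header.
#' @return a [gyration_dataset].
#' @export
read_measurements <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  has_rg <- "rg_nm" %in% names(df)
  has_rg2 <- "rg2_nm2" %in% names(df)
  if (has_rg == has_rg2) {
    stop("measurement file must have exactly one of the columns rg_nm or rg2_nm2")
  }
  for (col in c("length_bp", if (has_rg) "rg_nm" else "rg2_nm2")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive or missing %s in row(s) %s of %s", col,
                   paste(head(bad, 5), collapse = ", "), path))
    }
  }
  if (has_rg) {
    df$rg2_nm2 <- df$rg_nm^2
    df$rg_nm <- NULL
  }
  gyration_dataset(df)
}

#' Write measurements
#'
#' @param dataset a [gyration_dataset].
#' @param path output path (TSV).
#' @param unit write squared radii (`"rg2_nm2"`, default) or radii
#'   (`"rg_nm"`).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path, unit = c("rg2_nm2", "rg_nm")) {
  unit <- match.arg(unit)
  df <- as.data.frame(dataset)
  if (unit == "rg_nm") {
    df$rg_nm <- sqrt(df$rg2_nm2)
    df$rg2_nm2 <- NULL
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write domain intervals (BED)
#'
#' Domains are genomic intervals in BED convention (0-based, half-open).
#' Backed by `rtracklayer`; the returned data.frame carries `chrom`,
#' `start`, `end` and optional `name`.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `name`.
#' @export
read_domains_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' @rdname read_domains_bed
#' @param domains data.frame with `chrom`, `start` (0-based), `end`,
#'   optional `name`.
#' @export
write_domains_bed <- function(domains, path) {
  if (any(domains$end <= domains$start)) {
    stop("invalid interval(s): end <= start")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(start = domains$start + 1L, end = domains$end))
  if (!is.null(domains$name)) gr$name <- domains$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write an enrichment trace (bedGraph)
#'
#' @param path bedGraph file path.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `value`.
#' @export
read_trace_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score,
             stringsAsFactors = FALSE)
}

#' @rdname read_trace_bedgraph
#' @param trace data.frame with `chrom`, `start` (0-based), `end`, `value`.
#' @export
write_trace_bedgraph <- function(trace, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = trace$chrom,
    ranges = IRanges::IRanges(start = trace$start + 1L, end = trace$end),
    score = trace$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write / read posterior chains (CSV)
#'
#' Chains are flattened to a long table with `step`, `walker` and one column
#' per parameter; reading reconstructs the chain array, so summaries
#' recomputed from a reloaded file match the originals exactly.
#'
#' @param post a `posterior_samples`.
#' @param path CSV path.
#' @return `write_posterior_chains`: `path`, invisibly;
#'   `read_posterior_chains`: a `posterior_samples` (without diagnostics
#'   that are not stored, such as acceptance).
#' @export
write_posterior_chains <- function(post, path) {
  stopifnot(inherits(post, "posterior_samples"))
  d <- dim(post$chain)
  df <- data.frame(step = rep(seq_len(d[1]), d[2]),
                   walker = rep(seq_len(d[2]), each = d[1]))
  for (j in seq_along(post$par_names)) {
    # full binary precision so reloaded chains summarize identically
    df[[post$par_names[j]]] <- sprintf("%.17g", as.vector(post$chain[, , j]))
  }
  df$.burn_in <- post$burn_in
  df$.variant <- post$variant
  df$.seed <- post$seed
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_chains
#' @export
read_posterior_chains <- function(path) {
  df <- utils::read.delim(path, sep = ",", stringsAsFactors = FALSE)
  pn <- setdiff(names(df), c("step", "walker", ".burn_in", ".variant", ".seed"))
  n_steps <- max(df$step)
  n_walkers <- max(df$walker)
  chain <- array(NA_real_, c(n_steps, n_walkers, length(pn)))
  ord <- order(df$walker, df$step)
  for (j in seq_along(pn)) {
    chain[, , j] <- matrix(df[[pn[j]]][ord], n_steps, n_walkers)
  }
  out <- list(chain = chain, log_prob = NULL, par_names = pn,
              burn_in = df$.burn_in[1], acceptance = NA_real_,
              tau_int = rep(NA_real_, length(pn)),
              ess = rep(NA_real_, length(pn)),
              variant = df$.variant[1], seed = df$.seed[1],
              prior_bounds = NULL)
  class(out) <- "posterior_samples"
  out
}

#' Write a per-color fit summary (JSON)
#'
#' Serializes the posterior summary in the shape of the headline parameter
#' table: per-color fitted parameters as mean and SD, plus the derived
#' compaction block computed at the stated nucleosome repeat length.
#'
#' @param summary result of [summarize_posterior()].
#' @param color epigenetic color label.
#' @param NRL nucleosome repeat length used for the derived block.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, color, NRL, path) {
  tb <- summary$table
  fitted <- lapply(seq_len(nrow(tb)), function(i) {
    list(mean = tb$mean[i], sd = tb$sd[i])
  })
  names(fitted) <- tb$parameter
  pm <- model_params(fitted$eps$mean, fitted$K_bp$mean, fitted$K_nm$mean)
  der <- derived_chromatin_params(pm, NRL)
  obj <- list(color = color,
              variant = if ("a_inf" %in% tb$parameter) "full" else "constant_bundle",
              fitted = fitted,
              derived = list(c_lin = der$c_lin, c10 = der$c10, C = der$C,
                             NRL = NRL))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
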