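#' Specify a synthetic enhancer signal landscape
#'
#' Models the heavy-tailed distribution of active-chromatin (H3K27ac-like)
#' signal over enhancers: a log-normal bulk plus a small super-enhancer
#' tail component carrying a known multiple of the bulk median. The tail
#' membership of every region is recorded as ground truth.
#'
#' @param n_enhancers Number of non-overlapping enhancer intervals.
#' @param bulk_meanlog,bulk_sdlog Log-normal parameters of the bulk signal.
#' @param tail_fraction Probability that a region is drawn from the SE tail
#'   component (SEs are a small minority of enhancers, ~4%).
#' @param tail_multiplier Tail signal scale, as a multiple of the bulk
#'   median.
#' @param tail_sdlog Log-scale spread of the tail component.
#' @param chrom Chromosome name for placement.
#' @param span_bp Genome span available for placement.
#' @param width_range Enhancer widths are drawn uniformly from this range.
#' @param seed Optional integer seed.
#' @return A `landscape_spec` object.
#' @export
landscape_spec <- function(n_enhancers = 1000L, bulk_meanlog = log(50),
                           bulk_sdlog = 0.8, tail_fraction = 0.04,
                           tail_multiplier = 20, tail_sdlog = 0.25,
                           chrom = "chr1", span_bp = 2e8,
                           width_range = c(500L, 5000L), seed = NULL) {
  if (n_enhancers < 1) abort("n_enhancers must be >= 1")
  if (tail_fraction < 0 || tail_fraction > 1) {
    abort("tail_fraction must be in [0, 1]")
  }
  if (tail_multiplier <= 0) abort("tail_multiplier must be > 0")
  if (length(width_range) != 2 || any(width_range < 1) ||
      diff(width_range) < 0) {
    abort("width_range must be an increasing positive pair")
  }
  structure(
    list(n_enhancers = as.integer(n_enhancers), bulk_meanlog = bulk_meanlog,
         bulk_sdlog = bulk_sdlog, tail_fraction = tail_fraction,
         tail_multiplier = tail_multiplier, tail_sdlog = tail_sdlog,
         chrom = chrom, span_bp = span_bp, width_range = width_range,
         seed = seed),
    class = "landscape_spec"
  )
}

#' Simulate an enhancer signal track with ground-truth SE flags
#'
#' Places non-overlapping intervals across the spec's span and assigns each
#' a signal from the bulk or tail component.
#'
#' @param spec A [landscape_spec()].
#' @return A tibble with columns `chrom`, `start`, `end`, `signal` and the
#'   ground-truth flag `truth_se`.
#' @examples
#' land <- sim_enhancer_landscape(landscape_spec(n_enhancers = 100, seed = 1))
#' mean(land$truth_se)
#' @export
sim_enhancer_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- spec$n_enhancers
  with_optional_seed(spec$seed, {
    widths <- floor(runif(n, spec$width_range[[1]],
                          spec$width_range[[2]] + 1))
    if (sum(widths) + n + 1 > spec$span_bp) {
      abort("span_bp too small to place the requested enhancers")
    }
    free <- spec$span_bp - sum(widths) - (n + 1)
    gp <- runif(n + 1)
    gaps <- 1 + floor(gp / sum(gp) * free)
    starts <- cumsum(gaps[seq_len(n)] + c(0, widths[-n]))
    is_tail <- runif(n) < spec$tail_fraction
    signal <- rlnorm(n, spec$bulk_meanlog, spec$bulk_sdlog)
    n_tail <- sum(is_tail)
    if (n_tail > 0) {
      signal[is_tail] <- exp(spec$bulk_meanlog) * spec$tail_multiplier *
        rlnorm(n_tail, 0, spec$tail_sdlog)
    }
    tibble(
      chrom = spec$chrom,
      start = as.integer(starts),
      end = as.integer(starts + widths),
      signal = signal,
      truth_se = is_tail
    )
  })
}

#' Validate and normalize a CTCF site table
#'
#' CTCF orientations are axis-relative: `"forward"` means the motif points
#' toward increasing coordinates. Sites are passed through with validation
#' (no motif scanning is performed; orientations are inputs).
#'
#' @param sites A data frame with columns `chrom`, `position`,
#'   `orientation` and optionally `label`.
#' @return A sorted tibble of validated sites.
#' @export
ctcf_site_map <- function(sites) {
  check_columns(sites, c("chrom", "position", "orientation"), "CTCF sites")
  if (any(!sites$orientation %in% c("forward", "reverse"))) {
    abort("orientation must be 'forward' or 'reverse' for every site")
  }
  dup <- duplicated(sites[c("chrom", "position")])
  if (any(dup)) {
    abort(paste0("duplicate CTCF site at ", sites$chrom[dup][[1]], ":",
                 sites$position[dup][[1]]))
  }
  out <- as_tibble(sites) %>% arrange(.data$chrom, .data$position)
  if (!"label" %in% names(out)) {
    out$label <- sprintf("ctcf_%02d", seq_len(nrow(out)))
  }
  out
}
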