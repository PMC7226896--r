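#' Stitch enhancer peaks into regions
#'
#' Merges peaks lying within `gap` bp of one another (ROSE-style stitching,
#' default 12.5 kb) into regions; each region's signal is the sum of its
#' constituent peak signals (rank-by-load convention). Peaks overlapping an
#' optional TSS exclusion set are dropped before stitching so that strong
#' promoter peaks do not nucleate spurious super enhancers.
#'
#' @param peaks Tibble with columns `chrom`, `start`, `end`, `signal`
#'   (0-based half-open, BED-like).
#' @param gap Maximum stitching distance in bp (>= 0).
#' @param tss_exclude Optional tibble of `chrom`, `start`, `end` intervals.
#' @return Tibble of stitched regions: `chrom`, `start`, `end`, `signal`,
#'   `n_peaks`, sorted by position. Stitching is idempotent: re-stitching
#'   the output is a no-op.
#' @export
stitch_enhancers <- function(peaks, gap = 12500, tss_exclude = NULL) {
  check_columns(peaks, c("chrom", "start", "end", "signal"), "peaks")
  if (gap < 0) abort("gap must be >= 0")
  if (any(peaks$end <= peaks$start)) abort("peaks must have start < end")
  if (any(peaks$signal < 0)) abort("signals must be >= 0")
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end)
  )
  if (!is.null(tss_exclude) && nrow(tss_exclude) > 0) {
    excl <- GenomicRanges::GRanges(
      tss_exclude$chrom,
      IRanges::IRanges(tss_exclude$start + 1, tss_exclude$end)
    )
    keep <- !IRanges::overlapsAny(gr, excl)
    gr <- gr[keep]
    peaks <- peaks[keep, ]
    if (nrow(peaks) == 0) {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), signal = numeric(),
                    n_peaks = integer()))
    }
  }
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  region_of <- factor(
    S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))],
    levels = seq_along(merged)
  )
  tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    signal = as.numeric(tapply(peaks$signal, region_of, sum)),
    n_peaks = as.integer(tapply(peaks$signal, region_of, length))
  ) %>%
    arrange(.data$chrom, .data$start)
}

#' Rank stitched regions and call super enhancers
#'
#' Sorts regions by ascending signal, min-max scales both rank and signal
#' to \[0, 1\], and places the cutoff at the point where a line of slope 1
#' is tangent to the rank curve (the argmin of scaled signal minus scaled
#' rank; beyond it the curve rises faster than the diagonal). Regions with
#' signal above the cutoff are flagged as super enhancers — the small
#' heavy-tail minority with outlier signal load. Ranks are unique (1 =
#' highest signal) with ties broken by genomic position; the percentile is
#' `100 * (N - rank + 1) / N`.
#'
#' @param regions Stitched regions from [stitch_enhancers()] (needs
#'   `chrom`, `start`, `end`, `signal`; at least 3 rows).
#' @return A tibble of class `miswire_ranked` with `rank`, `percentile`
#'   and `se_flag` columns, ordered by rank; the cutoff signal is stored
#'   in `attr(, "cutoff_signal")`. All-equal signals yield zero SEs with a
#'   warning.
#' @examples
#' regions <- tibble::tibble(
#'   chrom = "chr1", start = 0:3 * 1000L, end = 0:3 * 1000L + 500L,
#'   signal = c(1, 1, 1, 100)
#' )
#' call_superenhancers(regions)
#' @export
call_superenhancers <- function(regions) {
  check_columns(regions, c("chrom", "start", "end", "signal"), "regions")
  n <- nrow(regions)
  if (n < 3) abort("need at least 3 regions to place a cutoff")
  asc <- regions %>% arrange(.data$signal, .data$chrom, .data$start)
  rng <- range(asc$signal)
  if (diff(rng) == 0) {
    warn("all signals equal; no super enhancers called")
    cutoff <- Inf
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (asc$signal - rng[[1]]) / diff(rng)
    cutoff <- asc$signal[[which.min(y - x)]]
  }
  out <- regions %>%
    arrange(desc(.data$signal), .data$chrom, .data$start) %>%
    mutate(
      rank = row_number(),
      percentile = 100 * (n - .data$rank + 1) / n,
      se_flag = .data$signal > cutoff
    )
  class(out) <- c("miswire_ranked", class(out))
  attr(out, "cutoff_signal") <- cutoff
  out
}

#' Rank percentile of a query locus across samples
#'
#' Looks up the enhancer-rank percentile of the stitched region best
#' overlapping a query interval (any shared base counts as overlap; the
#' region with the largest overlap wins) in each sample's ranked set —
#' the cross-sample view used to ask whether a locus's enhancer has risen
#' in rank in one condition.
#'
#' @param ranked A ranked table from [call_superenhancers()], or a named
#'   list of them (one per sample).
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Tibble with one row per sample: `sample_id`, `present`,
#'   `percentile`, `rank`, `signal` and the matched region coordinates.
#'   Samples with no overlapping region are reported with
#'   `present = FALSE`.
#' @export
rank_percentile <- function(ranked, chrom, start, end) {
  if (is.data.frame(ranked)) ranked <- list(sample = ranked)
  if (is.null(names(ranked)) || any(!nzchar(names(ranked)))) {
    abort("ranked list must be named by sample")
  }
  purrr::imap(ranked, function(rk, sid) {
    ov <- rk %>%
      filter(.data$chrom == !!chrom, .data$start < !!end,
             .data$end > !!start) %>%
      mutate(overlap = pmin(.data$end, !!end) - pmax(.data$start, !!start)) %>%
      arrange(desc(.data$overlap), desc(.data$signal)) %>%
      head(1)
    if (nrow(ov) == 0) {
      tibble(sample_id = sid, present = FALSE, percentile = NA_real_,
             rank = NA_integer_, signal = NA_real_,
             region_start = NA_integer_, region_end = NA_integer_)
    } else {
      tibble(sample_id = sid, present = TRUE, percentile = ov$percentile,
             rank = ov$rank, signal = ov$signal,
             region_start = ov$start, region_end = ov$end)
    }
  }) %>% bind_rows()
}

#' Spike-in (reference-adjusted) normalization of binned counts
#'
#' ChIP-Rx style normalization: reads per bin scaled by the total number
#' of reads mapping to the exogenous spike-in genome,
#' `rrpm = count * 1e6 / spike_in_total`. Unlike per-library RPM this
#' preserves genuine global signal loss between conditions.
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `count`.
#' @param spike_in_total Total spike-in reads (> 0).
#' @return The bins with an `rrpm` column; `spike_in_total` kept as an
#'   attribute.
#' @export
rx_normalize <- function(bins, spike_in_total) {
  check_columns(bins, c("chrom", "start", "end", "count"), "bins")
  if (length(spike_in_total) != 1 || spike_in_total <= 0) {
    abort("spike_in_total must be a single positive number")
  }
  out <- bins %>% mutate(rrpm = .data$count * 1e6 / spike_in_total)
  attr(out, "spike_in_total") <- spike_in_total
  out
}

#' Signed difference between two spike-in-normalized tracks
#'
#' @param treated,control Tracks from [rx_normalize()] over identical bins.
#' @return Tibble `chrom`, `start`, `end`, `delta_rrpm`
#'   (treated - control).
#' @export
delta_rrpm <- function(treated, control) {
  check_columns(treated, c("chrom", "start", "end", "rrpm"), "treated")
  check_columns(control, c("chrom", "start", "end", "rrpm"), "control")
  t_sorted <- treated %>% arrange(.data$chrom, .data$start)
  c_sorted <- control %>% arrange(.data$chrom, .data$start)
  if (nrow(t_sorted) != nrow(c_sorted) ||
      !identical(t_sorted[c("chrom", "start", "end")],
                 c_sorted[c("chrom", "start", "end")])) {
    abort("treated and control tracks must share identical bins")
  }
  t_sorted %>%
    mutate(delta_rrpm = .data$rrpm - c_sorted$rrpm) %>%
    select("chrom", "start", "end", "delta_rrpm")
}
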