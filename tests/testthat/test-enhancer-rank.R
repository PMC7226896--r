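test_that("stitching merges within the gap and sums signal", {
  two <- tibble::tibble(
    chrom = "chr1", start = c(0L, 10500L), end = c(500L, 11000L),
    signal = c(3, 4)
  )
  # 10 kb apart, 12.5 kb gap -> one region carrying the summed load
  one <- stitch_enhancers(two, gap = 12500)
  expect_equal(nrow(one), 1)
  expect_equal(one$signal, 7)
  expect_equal(one$n_peaks, 2L)

  # 20 kb apart -> two regions
  far <- dplyr::mutate(two, start = c(0L, 20500L), end = c(500L, 21000L))
  expect_equal(nrow(stitch_enhancers(far, gap = 12500)), 2)

  expect_error(stitch_enhancers(two, gap = -1), ">= 0")
})

test_that("stitching equals the transitive-closure merge oracle", {
  set.seed(81)
  for (i in seq_len(200)) {
    n <- sample(3:25, 1)
    starts <- sort(sample(0:50000, n))
    peaks <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = starts, end = starts + sample(100:800, n, replace = TRUE),
      signal = runif(n, 0, 10)
    ) |>
      dplyr::distinct(chrom, start, .keep_all = TRUE)
    gap <- sample(c(0, 500, 2000, 12500), 1)
    got <- stitch_enhancers(peaks, gap = gap)
    # oracle treats overlap/adjacency through the same distance rule
    want <- bf_stitch(peaks, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$signal, want$signal, tolerance = 1e-9)
  }
})

test_that("stitching is idempotent", {
  set.seed(82)
  starts <- sort(sample(0:100000, 40))
  peaks <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + 300L, signal = runif(40))
  once <- stitch_enhancers(peaks, gap = 12500)
  twice <- stitch_enhancers(once, gap = 12500) |>
    dplyr::select(-n_peaks)
  expect_equal(dplyr::select(once, -n_peaks), twice)
})

test_that("TSS exclusion removes promoter peaks before stitching", {
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L),
    signal = c(100, 1)
  )
  kept <- stitch_enhancers(
    peaks, gap = 0,
    tss_exclude = tibble::tibble(chrom = "chr1", start = 0L, end = 600L)
  )
  expect_equal(nrow(kept), 1)
  expect_equal(kept$signal, 1)
})

test_that("the tangent cutoff isolates outlier signal", {
  regions <- tibble::tibble(
    chrom = "chr1", start = (0:3) * 10000L, end = (0:3) * 10000L + 500L,
    signal = c(1, 1, 1, 100)
  )
  ranked <- call_superenhancers(regions)
  expect_equal(ranked$se_flag[ranked$signal == 100], TRUE)
  expect_equal(sum(ranked$se_flag), 1)
  expect_equal(ranked$rank[ranked$signal == 100], 1L)
  expect_equal(ranked$percentile[ranked$signal == 100], 100)

  expect_warning(
    flat <- call_superenhancers(dplyr::mutate(regions, signal = 5)),
    "all signals equal"
  )
  expect_equal(sum(flat$se_flag), 0)

  expect_error(call_superenhancers(regions[1:2, ]), "at least 3")
})

test_that("ranks are deterministic under ties and percentiles span (0,100]", {
  regions <- tibble::tibble(
    chrom = "chr1", start = c(3000L, 1000L, 2000L),
    end = c(3500L, 1500L, 2500L), signal = c(5, 5, 9)
  )
  ranked <- call_superenhancers(regions)
  expect_equal(ranked$rank, 1:3)
  # tie broken by genomic position: start 1000 ranks ahead of 3000
  expect_equal(ranked$start[2:3], c(1000L, 3000L))
  expect_true(all(ranked$percentile > 0 & ranked$percentile <= 100))
})

test_that("the SE set is invariant under uniform signal scaling", {
  land <- sim_enhancer_landscape(landscape_spec(n_enhancers = 300, seed = 5))
  r1 <- call_superenhancers(stitch_enhancers(land))
  r2 <- call_superenhancers(
    stitch_enhancers(dplyr::mutate(land, signal = signal * 37))
  )
  expect_equal(r1$se_flag, r2$se_flag)
  expect_equal(r1$rank, r2$rank)
})

test_that("truth super enhancers are recovered from the heavy tail", {
  recalls <- vapply(1:3, function(s) {
    land <- sim_enhancer_landscape(landscape_spec(seed = 300 + s))
    ranked <- call_superenhancers(stitch_enhancers(land))
    se_regions <- dplyr::filter(ranked, se_flag)
    truth <- dplyr::filter(land, truth_se)
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      any(se_regions$chrom == truth$chrom[[i]] &
            se_regions$start < truth$end[[i]] &
            se_regions$end > truth$start[[i]])
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gt(min(recalls), 0.8)
})

test_that("query percentiles follow signal across samples", {
  set.seed(83)
  starts <- (0:99) * 50000L
  regions <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + 1000L,
                            signal = sample(1:100))
  ranked <- call_superenhancers(regions)
  top <- dplyr::filter(ranked, rank == 1)
  bottom <- dplyr::filter(ranked, rank == 100)
  expect_equal(
    rank_percentile(ranked, "chr1", top$start, top$end)$percentile, 100
  )
  expect_equal(
    rank_percentile(ranked, "chr1", bottom$start, bottom$end)$percentile, 1
  )

  # boosting one region's signal 10x raises its percentile
  boosted <- regions
  i <- which(regions$signal == 50)
  boosted$signal[i] <- boosted$signal[i] * 10
  both <- rank_percentile(
    list(s1 = ranked, s2 = call_superenhancers(boosted)),
    "chr1", regions$start[[i]], regions$end[[i]]
  )
  expect_gt(both$percentile[both$sample_id == "s2"],
            both$percentile[both$sample_id == "s1"])

  # absence is explicit, not an error
  none <- rank_percentile(ranked, "chrX", 0, 100)
  expect_false(none$present)
  expect_true(is.na(none$percentile))
})

test_that("spike-in normalization is exact arithmetic", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                         end = c(100L, 200L), count = c(10, 20))
  rx <- rx_normalize(bins, 2e6)
  expect_equal(rx$rrpm, c(5, 10))
  # halving the spike-in total doubles RRPM
  expect_equal(rx_normalize(bins, 1e6)$rrpm, c(10, 20))

  expect_equal(delta_rrpm(rx, rx)$delta_rrpm, c(0, 0))
  treated <- rx_normalize(dplyr::mutate(bins, count = c(30, 20)), 2e6)
  expect_equal(delta_rrpm(treated, rx)$delta_rrpm, c(10, 0))

  expect_error(rx_normalize(bins, 0), "positive")
  shifted <- rx_normalize(dplyr::mutate(bins, start = start + 1L), 2e6)
  expect_error(delta_rrpm(rx, shifted), "identical bins")
})
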