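test_that("normalization implements log2 RPKM with pseudocount", {
  counts <- tibble::tibble(
    gene_id = "G", exon_index = 1:2, length = c(1000L, 500L),
    s1 = c(1000, 0)
  )
  # count 1000, L = 1000 bp, N = 1e6 reads, pseudocount 0 -> log2(1000)
  expr <- normalize_exon_counts(counts, pseudocount = 0,
                                library_sizes = c(s1 = 1e6))
  expect_equal(expr$s1[[1]], log2(1000), tolerance = 1e-12)

  # all-zero counts with pseudocount 1 -> expression 0
  zeros <- dplyr::mutate(counts, s1 = 0)
  expr0 <- normalize_exon_counts(zeros, library_sizes = c(s1 = 1e6))
  expect_true(all(expr0$s1 == 0))

  # depth invariance: doubling counts and the library size is a no-op
  expr_a <- normalize_exon_counts(counts, pseudocount = 0,
                                  library_sizes = c(s1 = 1e6))
  expr_b <- normalize_exon_counts(dplyr::mutate(counts, s1 = s1 * 2),
                                  pseudocount = 0,
                                  library_sizes = c(s1 = 2e6))
  expect_equal(expr_a$s1, expr_b$s1)

  expect_error(
    normalize_exon_counts(counts, library_sizes = c(s1 = 0)),
    "zero library"
  )
  expect_error(
    normalize_exon_counts(dplyr::mutate(counts, length = 0L)),
    "length"
  )
})

test_that("exon z-scores standardize and handle degenerate vectors", {
  expect_equal(exon_zscores(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(exon_zscores(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(exon_zscores(7), 0)
  set.seed(1)
  z <- exon_zscores(rnorm(9))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(exon_zscores(numeric(0)), "empty")
})

test_that("the imbalance score is the largest absolute z", {
  expect_equal(imbalance_score(c(0, 0, 0)), 0)
  expect_equal(imbalance_score(c(-1, 0, 1)), 1)
  expect_error(imbalance_score(numeric(0)), "empty")
})

test_that("scaling a sample's counts leaves z, Z* and delta unchanged", {
  sim <- sim_exon_counts(cohort_spec(
    groups = c(FN = 6L, P3F = 4L), seed = 21
  ))
  scaled <- sim$counts
  smp <- sim$samples$sample_id
  scaled[smp] <- scaled[smp] * 5
  expr_a <- normalize_exon_counts(sim$counts, pseudocount = 0)
  expr_b <- normalize_exon_counts(scaled, pseudocount = 0)
  # library sizes are column sums, so RPKM (and everything downstream)
  # is exactly invariant
  expect_equal(expr_a[smp], expr_b[smp], tolerance = 1e-12)
  za <- imbalance_table(expr_a, sim$samples)
  zb <- imbalance_table(expr_b, sim$samples)
  expect_equal(za$z_star, zb$z_star, tolerance = 1e-12)
})

test_that("the within-sample statistic matches its vector operations", {
  sim <- sim_exon_counts(cohort_spec(groups = c(FN = 3L), fusions = list(),
                                     r = 0, seed = 31))
  expr <- normalize_exon_counts(sim$counts)
  tab <- imbalance_table(expr, method = "within")
  g <- dplyr::filter(expr, gene_id == "PAX3")
  manual <- imbalance_score(exon_zscores(g$FN_01))
  got <- dplyr::filter(tab, gene_id == "PAX3", sample_id == "FN_01")
  expect_equal(got$z_star, manual)
})

test_that("the breakpoint contrast standardizes the retained-lost gap", {
  flat <- breakpoint_contrast(rep(3, 9), retained = 1:7)
  expect_equal(flat$delta, 0)
  expect_equal(flat$call, "balanced")

  # retained centered at 10, lost at 0, pooled sd exactly 1
  a <- 1 / sqrt(2)
  x <- c(10 - a, 10 + a, -a, a)
  ct <- breakpoint_contrast(x, retained = 1:2)
  expect_equal(ct$delta, 10)
  expect_equal(ct$call, "imbalanced_5p")

  # mirrored role: retained suffix overexpressed -> imbalanced_3p
  ct3 <- breakpoint_contrast(x, retained = 1:2, role = "three_prime")
  expect_equal(ct3$call, "imbalanced_3p")

  # constant but different halves: signed infinity
  ct_inf <- breakpoint_contrast(c(1, 1, 0, 0), retained = 1:2)
  expect_equal(ct_inf$delta, Inf)

  expect_error(breakpoint_contrast(1:5, integer(0)), "proper")
  expect_error(breakpoint_contrast(1:5, 1:5), "proper")
})

test_that("contrast direction recovers the simulated overexpressed side", {
  spec <- cohort_spec(groups = c(P3F = 200L),
                      fusions = list(P3F = "PAX3-FOXO1"), seed = 41)
  sim <- sim_exon_counts(
    spec, models = dplyr::filter(toy_gene_models(), gene_id == "PAX3")
  )
  expr <- normalize_exon_counts(sim$counts)
  ct <- breakpoint_contrast_table(expr, "PAX3", retained = 1:7)
  expect_gte(mean(ct$delta > 0), 0.99)
  expect_gte(mean(ct$call == "imbalanced_5p"), 0.99)
})

test_that("Welch comparison behaves at its reference points", {
  d <- tibble::tibble(z_star = rep(c(1, 2, 3), 2),
                      group = rep(c("A", "B"), each = 3))
  cmp <- compare_groups(d, "A", "B")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  shifted <- tibble::tibble(z_star = c(1, 2, 3, 11, 12, 13),
                            group = rep(c("A", "B"), each = 3))
  cmp2 <- compare_groups(shifted, "B", "A")
  expect_gt(abs(cmp2$statistic), 10)
  expect_lt(cmp2$p_value, 0.01)

  td <- tidy(cmp2)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, 10)

  expect_error(
    compare_groups(shifted[c(1, 4:6), ], "A", "B"),
    "at least 2"
  )
})

test_that("Welch p-values track a permutation oracle", {
  set.seed(51)
  diffs <- vapply(1:20, function(i) {
    a <- rnorm(20, mean = sample(c(0, 0.5, 1), 1))
    b <- rnorm(20)
    d <- tibble::tibble(z_star = c(a, b),
                        group = rep(c("A", "B"), each = 20))
    p_welch <- compare_groups(d, "A", "B")$p_value
    p_perm <- perm_welch_p(a, b, n_perm = 4000)
    abs(p_welch - p_perm)
  }, numeric(1))
  expect_lt(max(diffs), 0.06)
})

test_that("the Welch test keeps its nominal size", {
  set.seed(61)
  pvals <- vapply(1:1000, function(i) {
    d <- tibble::tibble(
      z_star = rnorm(84), group = rep(c("FN", "P3F"), c(61, 23))
    )
    compare_groups(d, "P3F", "FN")$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a fusion-positive sample outscores a fusion-negative one", {
  models <- dplyr::filter(toy_gene_models(), gene_id == "PAX3")
  wins <- vapply(1:100, function(i) {
    sim <- sim_exon_counts(
      cohort_spec(groups = c(FN = 20L, P3F = 8L), seed = 80000 + i),
      models = models
    )
    scores <- sim$counts |>
      normalize_exon_counts() |>
      imbalance_table(sim$samples)
    fp <- sample(scores$z_star[scores$group == "P3F"], 1)
    fn <- sample(scores$z_star[scores$group == "FN"], 1)
    fp > fn
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("expected imbalance grows with the simulated ratio r", {
  models <- dplyr::filter(toy_gene_models(), gene_id == "PAX3")
  mean_zstar <- vapply(c(1, 2, 5, 10, 50), function(r) {
    zs <- vapply(1:25, function(i) {
      spec <- cohort_spec(
        groups = c(FN = 40L, P3F = 20L), r = r, silenced_wt = 1,
        seed = 70000 + r * 100 + i
      )
      sim <- sim_exon_counts(spec, models = models)
      scores <- sim$counts |>
        normalize_exon_counts() |>
        imbalance_table(sim$samples)
      mean(scores$z_star[scores$group == "P3F"])
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_zstar) > 0))
})
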