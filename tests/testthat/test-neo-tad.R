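test_that("derivative remapping is offset arithmetic with provenance", {
  locus <- build_derivative_locus(
    five = list(chrom = "chr2", start = 0, end = 1000),
    three = list(chrom = "chr13", start = 5000, end = 7000),
    features = tibble::tibble(chrom = "chr13", position = 5500, name = "f")
  )
  expect_equal(locus$length, 3000)
  expect_equal(locus$features$derivative_pos, 1500)
  expect_equal(locus$features$segment, "three_prime")
})

test_that("flipped segments mirror positions and reverse orientations", {
  locus <- build_derivative_locus(
    five = list(chrom = "chr2", start = 0, end = 1000),
    three = list(chrom = "chr13", start = 5000, end = 7000, flipped = TRUE),
    features = tibble::tibble(chrom = "chr13", position = 5500,
                              orientation = "forward", name = "f")
  )
  # mirror arithmetic: 1000 + (7000 - 5500) = 2500
  expect_equal(locus$features$derivative_pos, 2500)
  expect_equal(locus$features$orientation, "reverse")
  back <- derivative_to_source(locus, 2500)
  expect_equal(back$chrom, "chr13")
  expect_equal(back$source_pos, 5500)
})

test_that("features outside both segments are dropped with a warning", {
  expect_warning(
    locus <- build_derivative_locus(
      five = list(chrom = "chr2", start = 0, end = 1000),
      three = list(chrom = "chr13", start = 5000, end = 7000),
      features = tibble::tibble(chrom = c("chr13", "chr9"),
                                position = c(5500, 100),
                                name = c("in", "out"))
    ),
    "dropped"
  )
  expect_equal(nrow(locus$features), 1)
})

test_that("overlapping source segments mapping a feature twice error", {
  expect_error(
    build_derivative_locus(
      five = list(chrom = "chr2", start = 0, end = 1000),
      three = list(chrom = "chr2", start = 500, end = 2000),
      features = tibble::tibble(chrom = "chr2", position = 700, name = "f")
    ),
    "twice"
  )
})

test_that("derivative-source round trips are exact on random loci", {
  set.seed(91)
  for (i in seq_len(100)) {
    flip5 <- sample(c(TRUE, FALSE), 1)
    flip3 <- sample(c(TRUE, FALSE), 1)
    feats <- tibble::tibble(
      chrom = sample(c("chrA", "chrB"), 20, replace = TRUE),
      position = c(sample(100:9900, 10), sample(20100:29900, 10)),
      name = sprintf("f%02d", 1:20)
    )
    suppressWarnings(
      locus <- build_derivative_locus(
        five = list(chrom = "chrA", start = 100, end = 10000,
                    flipped = flip5),
        three = list(chrom = "chrB", start = 20000, end = 30000,
                     flipped = flip3),
        features = feats
      )
    )
    back <- derivative_to_source(locus, locus$features$derivative_pos)
    expect_equal(back$chrom, locus$features$source_chrom)
    expect_equal(back$source_pos, locus$features$source_pos)
  }
})

test_that("convergent pairs require forward-then-reverse orientation", {
  one <- convergent_pairs(tibble::tibble(
    position = c(100, 500), orientation = c("forward", "reverse")
  ))
  expect_equal(nrow(one), 1)
  expect_equal(one$span, 400)

  none <- convergent_pairs(tibble::tibble(
    position = c(100, 500), orientation = c("reverse", "forward")
  ))
  expect_equal(nrow(none), 0)

  expect_error(
    convergent_pairs(tibble::tibble(position = c(1, 2),
                                    orientation = c("forward", NA))),
    "orientation"
  )
})

test_that("pair enumeration equals the brute-force oracle", {
  set.seed(92)
  for (i in seq_len(500)) {
    n <- sample(2:8, 1)
    sites <- tibble::tibble(
      position = sample(1:10000, n),
      orientation = sample(c("forward", "reverse"), n, replace = TRUE)
    )
    got <- convergent_pairs(sites)
    want <- bf_convergent(sites)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$left_pos, want$left_pos)
    expect_equal(got$right_pos, want$right_pos)
  }
})

test_that("reflecting the axis maps permissive pairs onto permissive pairs", {
  set.seed(93)
  for (i in seq_len(100)) {
    n <- sample(3:8, 1)
    sites <- tibble::tibble(
      position = sample(1:10000, n),
      orientation = sample(c("forward", "reverse"), n, replace = TRUE)
    )
    reflected <- tibble::tibble(
      position = 20000 - sites$position,
      orientation = ifelse(sites$orientation == "forward",
                           "reverse", "forward")
    )
    a <- convergent_pairs(sites)
    b <- convergent_pairs(reflected)
    expect_equal(nrow(a), nrow(b))
    expect_setequal(
      paste(a$left_pos, a$right_pos),
      paste(20000 - b$right_pos, 20000 - b$left_pos)
    )
  }
})

test_that("the toy fusion locus yields two promoter-anchored pairs", {
  toy <- toy_fusion_locus()
  nbhd <- define_neighborhood(toy$sites, toy$anchor)
  expect_true(nbhd$found)
  expect_equal(nrow(nbhd$pairs), 2)
  expect_setequal(nbhd$pairs$right_label,
                  c("FOXO1_site1", "FOXO1_site3"))
  expect_true(all(nbhd$pairs$left_label == "PAX3_boundary"))
  # innermost pair defines the neighborhood; outermost reported alongside
  expect_equal(nbhd$right$label, "FOXO1_site3")
  expect_equal(nbhd$outermost$right_label, "FOXO1_site1")
})

test_that("anchor and boundary conventions are strict", {
  toy <- toy_fusion_locus()
  # anchor outside every pair -> explicit no-neighborhood result
  far <- define_neighborhood(toy$sites, 190000)
  expect_false(far$found)

  # removing the reverse member of every spanning pair loses the domain
  lost <- define_neighborhood(
    dplyr::filter(toy$sites, !label %in% c("FOXO1_site1", "FOXO1_site3")),
    toy$anchor
  )
  expect_false(lost$found)

  nbhd <- define_neighborhood(toy$sites, toy$anchor)
  at_boundary <- classify_elements(
    nbhd, tibble::tibble(class = "SE", position = nbhd$right$position)
  )
  expect_false(at_boundary$intra_tad)
})

test_that("element classification composes class and TAD membership", {
  toy <- toy_fusion_locus()
  nbhd <- define_neighborhood(toy$sites, toy$anchor)
  ann <- classify_elements(nbhd, toy$elements)
  expect_equal(
    ann$label[ann$name == "FOXO1_SE"], "intra-TAD SE"
  )
  expect_equal(
    ann$label[ann$name == "distal_SE"], "SE outside TAD"
  )
  expect_equal(
    ann$label[ann$name == "intronic_enhancer"],
    "intra-TAD typical enhancer"
  )
  # hand enumeration: inside = strictly between 10000 and 90000
  expect_equal(ann$intra_tad,
               ann$position > 10000 & ann$position < 90000)

  expect_error(
    classify_elements(nbhd, tibble::tibble(class = "SE",
                                           position = NA_real_)),
    "coordinates"
  )
})
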