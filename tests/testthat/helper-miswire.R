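# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a gene-model tibble directly (bypassing GTF parsing).
make_gene <- function(gene_id, n_exons, strand = "+", chrom = "chrT",
                      offset = 0, exon_width = 200, gap = 800) {
  step <- exon_width + gap
  starts <- offset + step * seq_len(n_exons)
  if (strand == "-") starts <- rev(starts)
  tibble::tibble(
    gene_id = gene_id,
    exon_index = seq_len(n_exons),
    chrom = chrom,
    start = starts,
    end = starts + exon_width,
    strand = strand
  )
}

# Random single-gene model with irregular widths and gaps.
random_gene <- function(gene_id = "G") {
  n <- sample(2:12, 1)
  widths <- sample(50:300, n, replace = TRUE)
  gaps <- sample(100:1000, n, replace = TRUE)
  starts <- cumsum(gaps + c(0, widths[-n])) + sample(0:10000, 1)
  strand <- sample(c("+", "-"), 1)
  idx <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  tibble::tibble(
    gene_id = gene_id, exon_index = idx, chrom = "chrR",
    start = starts, end = starts + widths, strand = strand
  ) |>
    dplyr::arrange(exon_index)
}

# Pick an intronic breakpoint after transcription-order exon k (k in 0..n);
# returns the genomic coordinate. k = 0 puts it upstream of exon 1.
breakpoint_after_exon <- function(gene, k) {
  g <- dplyr::arrange(gene, exon_index)
  n <- nrow(g)
  fwd <- g$strand[[1]] == "+"
  if (k == 0) {
    if (fwd) g$start[[1]] - 50 else g$end[[1]] + 50
  } else if (k == n) {
    if (fwd) g$end[[n]] + 50 else g$start[[n]] - 50
  } else {
    if (fwd) (g$end[[k]] + g$start[[k + 1]]) %/% 2
    else (g$end[[k + 1]] + g$start[[k]]) %/% 2
  }
}

# Write a minimal GTF for the given models tibble (1-based coordinates).
write_test_gtf <- function(models, path) {
  lines <- sprintf(
    "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t\";",
    models$chrom, models$start + 1L, models$end, models$strand,
    models$gene_id, models$gene_id
  )
  writeLines(lines, path)
  path
}

# Transitive-closure merge oracle for enhancer stitching: repeatedly merge
# any two intervals (same chrom) within `gap` until stable.
bf_stitch <- function(peaks, gap) {
  regions <- lapply(seq_len(nrow(peaks)), function(i) peaks[i, ])
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i >= j) next
        a <- regions[[i]]; b <- regions[[j]]
        if (is.null(a) || is.null(b) || a$chrom != b$chrom) next
        d <- max(a$start, b$start) - min(a$end, b$end)
        if (d <= gap) {
          regions[[i]] <- tibble::tibble(
            chrom = a$chrom, start = min(a$start, b$start),
            end = max(a$end, b$end), signal = a$signal + b$signal
          )
          regions[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  dplyr::arrange(dplyr::bind_rows(regions), chrom, start)
}

# O(n^2) oracle for convergent CTCF pair enumeration.
bf_convergent <- function(sites) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(sites))) {
      a <- sites[i, ]; b <- sites[j, ]
      if (a$position < b$position &&
          a$orientation == "forward" && b$orientation == "reverse") {
        out[[length(out) + 1]] <- tibble::tibble(
          left_pos = a$position, right_pos = b$position
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(left_pos = numeric(), right_pos = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), right_pos - left_pos, left_pos)
}

# Two-sided permutation p-value for the Welch t statistic.
perm_welch_p <- function(a, b, n_perm = 4000) {
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  }
  obs <- abs(welch_t(a, b))
  pool <- c(a, b)
  na <- length(a)
  hits <- replicate(n_perm, {
    idx <- sample(length(pool), na)
    abs(welch_t(pool[idx], pool[-idx])) >= obs
  })
  (sum(hits) + 1) / (n_perm + 1)
}
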