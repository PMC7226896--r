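#' Length- and depth-normalize an exon count table
#'
#' Converts raw exon counts to log2 RPKM-like expression:
#' \eqn{x_{ij} = \log_2(c_{ij} / (L_i/10^3) / (N_j/10^6) + pseudocount)}
#' with \eqn{L_i} the exon length in bp and \eqn{N_j} the library size
#' (column sum unless supplied).
#'
#' @param counts Tibble with columns `gene_id`, `exon_index`, `length` and
#'   one numeric column per sample.
#' @param pseudocount Added inside the log (default 1, so all-zero counts
#'   map to expression 0).
#' @param library_sizes Optional named vector of per-sample library sizes;
#'   defaults to column sums.
#' @return A tibble of the same shape with expression values.
#' @export
normalize_exon_counts <- function(counts, pseudocount = 1,
                                  library_sizes = NULL) {
  meta <- c("gene_id", "exon_index", "length")
  check_columns(counts, meta, "exon counts")
  smp <- sample_columns(counts, meta)
  if (length(smp) == 0) abort("exon count table has no sample columns")
  if (any(counts$length <= 0)) abort("exon lengths must be > 0")
  cm <- as.matrix(counts[smp])
  if (any(cm < 0)) abort("counts must be non-negative")
  if (is.null(library_sizes)) {
    n <- colSums(cm)
  } else {
    missing <- setdiff(smp, names(library_sizes))
    if (length(missing) > 0) {
      abort(paste0("library_sizes missing sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    n <- library_sizes[smp]
  }
  if (any(n == 0)) abort("zero library size")
  rpkm <- sweep(cm / (counts$length / 1e3), 2, n / 1e6, "/")
  out <- counts
  out[smp] <- as.data.frame(log2(rpkm + pseudocount))
  out
}

#' Z-score an expression vector across a gene's exons
#'
#' Standardizes one gene's exon expression within one sample using the
#' sample (n-1) standard deviation. Degenerate vectors (a single exon, or
#' zero spread as for a silent gene) return all-zero z rather than NaN.
#'
#' @param x Numeric expression vector, one value per exon.
#' @return Numeric vector of z-scores with mean 0 and sd 1 whenever the
#'   input has positive spread and more than one exon.
#' @examples
#' exon_zscores(c(1, 2, 3))
#' @export
exon_zscores <- function(x) {
  if (length(x) == 0) abort("empty expression vector")
  if (length(x) == 1) return(0)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Summarize a z vector into the scalar imbalance score
#'
#' The headline exonic-imbalance statistic is the largest absolute
#' z-score across a gene's exons: a balanced gene (all exons tracking the
#' same allele activity) stays low, while a gene whose leading exons are
#' driven by a hijacked enhancer on only one allele shows an outlier exon
#' block and a high score.
#'
#' @param z Numeric z-score vector (see [exon_zscores()]).
#' @return Non-negative scalar `max(abs(z))`.
#' @export
imbalance_score <- function(z) {
  if (length(z) == 0) abort("empty z vector")
  max(abs(z))
}

#' Per-sample exonic-imbalance scores for every gene
#'
#' Computes the imbalance statistic Z* for each gene x sample pair. With
#' `method = "cohort"` (default) each exon is first standardized across
#' samples using robust location/scale (median and MAD, falling back to
#' the standard deviation when the MAD is zero), and a sample's Z* is its
#' largest absolute standardized deviation across the gene's exons. This
#' asks "which exons of this sample are outliers against the cohort?" and
#' its separation grows without bound with the imbalance effect.
#'
#' With `method = "within"` the z-scores are computed within each sample
#' across the gene's exons ([exon_zscores()]). This variant needs no
#' cohort, but its score is bounded by \eqn{(n-1)/\sqrt{n}} for n exons
#' regardless of effect size, which limits power for genes where the
#' imbalanced exon block is a minority of exons.
#'
#' @param expr Normalized expression table from [normalize_exon_counts()].
#' @param samples Optional sample sheet (`sample_id`, `group`) joined onto
#'   the result.
#' @param method `"cohort"` (default) or `"within"`.
#' @return A tibble of class `imbalance_scores`: `gene_id`, `sample_id`,
#'   `z_star` (and `group` when `samples` is given).
#' @examples
#' sim <- sim_exon_counts(cohort_spec(seed = 1))
#' sim$counts |>
#'   normalize_exon_counts() |>
#'   imbalance_table(sim$samples) |>
#'   head()
#' @export
imbalance_table <- function(expr, samples = NULL,
                            method = c("cohort", "within")) {
  method <- arg_match(method)
  meta <- c("gene_id", "exon_index", "length")
  check_columns(expr, meta, "expression table")
  smp <- sample_columns(expr, meta)
  scores <- expr %>%
    split(expr$gene_id) %>%
    purrr::imap(function(g, gid) {
      x <- as.matrix(g[smp])
      z <- switch(method,
        within = apply(x, 2, exon_zscores),
        cohort = {
          loc <- apply(x, 1, median)
          scl <- apply(x, 1, mad)
          fallback <- scl == 0
          if (any(fallback)) scl[fallback] <- apply(x, 1, sd)[fallback]
          scl[!is.finite(scl) | scl == 0] <- 1
          (x - loc) / scl
        }
      )
      z <- matrix(z, nrow = nrow(g))  # single-exon genes: keep shape
      tibble(gene_id = gid, sample_id = smp,
             z_star = apply(abs(z), 2, max))
    }) %>%
    bind_rows()
  if (!is.null(samples)) {
    check_columns(samples, c("sample_id", "group"), "sample sheet")
    scores <- scores %>%
      left_join(samples %>% select("sample_id", "group"), by = "sample_id")
  }
  class(scores) <- c("imbalance_scores", class(scores))
  attr(scores, "method") <- method
  scores
}

#' Breakpoint-aware contrast between retained and lost exons
#'
#' The second, breakpoint-informed imbalance statistic: the standardized
#' difference between mean expression over the fusion-retained exons and
#' over the lost exons,
#' \eqn{\Delta = (\bar{x}_{retained} - \bar{x}_{lost}) / s_{pooled}}.
#' An allele-specific epistate call is made against the threshold `tau`:
#' `balanced` when \eqn{|\Delta| \le \tau}, otherwise the overexpressed
#' side is named (`imbalanced_5p` when the 5' end of the gene dominates,
#' `imbalanced_3p` for the 3' end). For a 5' fusion partner the retained
#' exons are the gene's 5' prefix, so \eqn{\Delta > \tau} means
#' `imbalanced_5p`; for a 3' partner the roles are mirrored.
#'
#' When both exon groups are exactly constant but different, the pooled sd
#' is zero and \eqn{\Delta} is reported as signed infinity.
#'
#' @param x Expression vector for one gene in one sample.
#' @param retained Exon indices retained in the fusion; must be a proper,
#'   non-empty subset of `seq_along(x)`.
#' @param tau Epistate call threshold (default 1.5).
#' @param role Which fusion side this gene contributes
#'   (`"five_prime"`/`"three_prime"`).
#' @return A one-row tibble with `delta` and `call`.
#' @export
breakpoint_contrast <- function(x, retained, tau = 1.5,
                                role = c("five_prime", "three_prime")) {
  role <- arg_match(role)
  idx <- seq_along(x)
  if (length(retained) == 0 || length(setdiff(idx, retained)) == 0) {
    abort("retained must be a proper non-empty subset of the exons")
  }
  if (any(!retained %in% idx)) abort("retained indices out of range")
  a <- x[retained]
  b <- x[setdiff(idx, retained)]
  va <- if (length(a) > 1) stats::var(a) else 0
  vb <- if (length(b) > 1) stats::var(b) else 0
  df <- length(a) + length(b) - 2
  sp <- if (df > 0) sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) / df)
        else 0
  dm <- mean(a) - mean(b)
  delta <- if (sp > 0) dm / sp else if (dm == 0) 0 else sign(dm) * Inf
  call <- if (abs(delta) <= tau) {
    "balanced"
  } else {
    over_retained <- delta > 0
    retained_end <- if (role == "five_prime") "5p" else "3p"
    lost_end <- if (role == "five_prime") "3p" else "5p"
    paste0("imbalanced_", if (over_retained) retained_end else lost_end)
  }
  tibble(delta = delta, call = call)
}

#' Breakpoint contrasts for every sample of one gene
#'
#' @param expr Normalized expression table.
#' @param gene_id Gene to contrast.
#' @param retained Retained exon indices for this gene's fusion side.
#' @inheritParams breakpoint_contrast
#' @return Tibble with one row per sample: `sample_id`, `delta`, `call`.
#' @export
breakpoint_contrast_table <- function(expr, gene_id, retained, tau = 1.5,
                                      role = c("five_prime",
                                               "three_prime")) {
  role <- arg_match(role)
  meta <- c("gene_id", "exon_index", "length")
  check_columns(expr, meta, "expression table")
  g <- expr %>%
    filter(.data$gene_id == !!gene_id) %>%
    arrange(.data$exon_index)
  if (nrow(g) == 0) abort(paste0("gene '", gene_id, "' not in table"))
  smp <- sample_columns(expr, meta)
  purrr::map(smp, function(s) {
    breakpoint_contrast(g[[s]], retained, tau = tau, role = role) %>%
      mutate(sample_id = s, .before = 1)
  }) %>% bind_rows()
}

#' Welch two-sample comparison of per-sample scores
#'
#' Compares a score (by default the imbalance statistic `z_star`) between
#' two sample groups with Welch's unequal-variance t test, two-tailed.
#'
#' @param data Tibble of per-sample scores.
#' @param group_a,group_b Group labels to compare (`group_a` minus
#'   `group_b`).
#' @param value Column holding the score (default `z_star`).
#' @param group Column holding group labels (default `group`).
#' @return A `welch_comparison` object; see [tidy.welch_comparison()].
#' @examples
#' sim <- sim_exon_counts(cohort_spec(seed = 1))
#' scores <- sim$counts |>
#'   normalize_exon_counts() |>
#'   imbalance_table(sim$samples) |>
#'   dplyr::filter(gene_id == "PAX3")
#' compare_groups(scores, "P3F", "FN")
#' @export
compare_groups <- function(data, group_a, group_b, value = "z_star",
                           group = "group") {
  check_columns(data, c(value, group), "score table")
  a <- data[[value]][data[[group]] == group_a]
  b <- data[[value]][data[[group]] == group_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 samples for a Welch comparison")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  structure(
    list(
      group_a = group_a, group_b = group_b, value = value,
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value
    ),
    class = "welch_comparison"
  )
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat("<welch_comparison> ", x$value, ": ", x$group_a, " (n=", x$n_a,
      ", mean=", signif(x$mean_a, 4), ") vs ", x$group_b, " (n=", x$n_b,
      ", mean=", signif(x$mean_b, 4), ")\n", sep = "")
  cat("  t = ", signif(x$statistic, 4), ", df = ", signif(x$df, 4),
      ", two-tailed p = ", format.pval(x$p_value, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a Welch comparison
#'
#' @param x A `welch_comparison`.
#' @param ... Unused.
#' @return One-row tibble with groups, means, Welch t, df and p.
#' @export
#' @exportS3Method generics::tidy
tidy.welch_comparison <- function(x, ...) {
  tibble(
    value = x$value, group_a = x$group_a, group_b = x$group_b,
    n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
    estimate = x$mean_a - x$mean_b, statistic = x$statistic, df = x$df,
    p_value = x$p_value
  )
}

#' @rdname tidy.welch_comparison
#' @export
#' @exportS3Method generics::glance
glance.welch_comparison <- function(x, ...) tidy(x)
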