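#' Normalize screen counts to per-timepoint relative abundance
#'
#' Converts sgRNA counts to counts-per-million within each timepoint
#' column after adding a pseudocount: abundances in each column sum to
#' 1e6. The pseudocount (default 0.5) keeps fully dropped-out guides off
#' negative infinity on the log scale.
#'
#' @param counts Screen count tibble: `sgrna_id` plus annotation columns
#'   and one `day_<t>` column per timepoint.
#' @param pseudocount Added to every count before normalization.
#' @return Tibble of the same shape with CPM values.
#' @export
normalize_screen <- function(counts, pseudocount = 0.5) {
  check_columns(counts, "sgrna_id", "screen counts")
  day_cols <- grep("^day_", names(counts), value = TRUE)
  if (length(day_cols) == 0) abort("no day_<t> columns found")
  if (nrow(counts) == 0) abort("empty screen count matrix")
  if (anyDuplicated(counts$sgrna_id) > 0) {
    abort("duplicate sgRNA identifiers")
  }
  out <- counts
  for (col in day_cols) {
    v <- counts[[col]] + pseudocount
    total <- sum(v)
    if (total <= 0) abort(paste0("column ", col, " has zero total"))
    out[[col]] <- v / total * 1e6
  }
  out
}

#' Per-sgRNA log2 fold changes against the reference timepoint
#'
#' `LFC = log2(abundance_t / abundance_ref)` for every timepoint, with the
#' earliest sampled day as the default reference (a plasmid-pool style
#' reference can be supplied as any other day).
#'
#' @param cpm Normalized abundances from [normalize_screen()].
#' @param ref_day Reference day (numeric); default is the earliest.
#' @return Long tibble: annotation columns, `day`, `lfc`.
#' @export
sgrna_lfc <- function(cpm, ref_day = NULL) {
  day_cols <- grep("^day_", names(cpm), value = TRUE)
  days <- as.numeric(sub("^day_", "", day_cols))
  if (is.null(ref_day)) ref_day <- min(days)
  ref_col <- paste0("day_", ref_day)
  if (!ref_col %in% day_cols) {
    abort(paste0("reference day ", ref_day, " not present"))
  }
  if (any(cpm[[ref_col]] <= 0)) {
    abort("zero reference abundance; use a positive pseudocount")
  }
  ann_cols <- setdiff(names(cpm), day_cols)
  cpm %>%
    tidyr::pivot_longer(all_of(day_cols), names_to = "day",
                        names_prefix = "day_", names_transform = as.numeric,
                        values_to = "abundance") %>%
    mutate(lfc = log2(.data$abundance / cpm[[ref_col]][
      match(.data$sgrna_id, cpm$sgrna_id)])) %>%
    select(all_of(ann_cols), "day", "lfc")
}

#' Aggregate sgRNA fold changes to element scores
#'
#' Summarizes the sgRNAs tiling each regulatory element into a
#' per-element, per-timepoint log2 fold change, using the median by
#' default for robustness to single outlier guides.
#'
#' @param lfc Long LFC table from [sgrna_lfc()] (needs `element_id`,
#'   `class`, `day`, `lfc`; `intra_tad` is carried through if present).
#' @param method `"median"` (default) or `"mean"`.
#' @return Tibble: `element_id`, `class` (and `intra_tad`), `day`,
#'   `element_lfc`, `n_sgrna`.
#' @export
aggregate_elements <- function(lfc, method = c("median", "mean")) {
  method <- arg_match(method)
  check_columns(lfc, c("element_id", "class", "day", "lfc"), "LFC table")
  agg <- if (method == "median") median else mean
  grp <- intersect(c("element_id", "class", "intra_tad", "day"),
                   names(lfc))
  lfc %>%
    group_by(across(all_of(grp))) %>%
    summarise(element_lfc = agg(.data$lfc), n_sgrna = n(),
              .groups = "drop")
}

#' Terminal (last-timepoint) element scores
#'
#' @param scores Output of [aggregate_elements()].
#' @return The rows for the latest day.
#' @export
terminal_scores <- function(scores) {
  check_columns(scores, c("day", "element_lfc"), "element scores")
  scores %>% filter(.data$day == max(.data$day))
}

#' Compare negative selection between two element classes
#'
#' Tests whether one regulatory-element class is under stronger negative
#' selection than another by comparing per-element log2 fold changes with
#' both Welch's t test and the Mann-Whitney rank-sum test (two-tailed).
#'
#' @param scores Per-element scores (typically [terminal_scores()]).
#' @param class_a,class_b Element classes to compare.
#' @param value Score column (default `element_lfc`).
#' @param class_col Class column (default `class`).
#' @return A `class_comparison` object bundling both tests; see
#'   [tidy.class_comparison()].
#' @export
compare_element_classes <- function(scores, class_a, class_b,
                                    value = "element_lfc",
                                    class_col = "class") {
  check_columns(scores, c(value, class_col), "element scores")
  a <- scores[[value]][scores[[class_col]] == class_a]
  b <- scores[[value]][scores[[class_col]] == class_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("each class needs at least 2 elements")
  }
  welch <- compare_groups(
    tibble(value = c(a, b),
           group = rep(c(class_a, class_b), c(length(a), length(b)))),
    class_a, class_b, value = "value"
  )
  mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
  structure(
    list(
      class_a = class_a, class_b = class_b,
      n_a = length(a), n_b = length(b),
      median_a = median(a), median_b = median(b),
      welch = welch,
      u_statistic = unname(mw$statistic),
      auc = unname(mw$statistic) / (length(a) * length(b)),
      u_p_value = mw$p.value
    ),
    class = "class_comparison"
  )
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("<class_comparison> ", x$class_a, " (n=", x$n_a, ", median=",
      signif(x$median_a, 4), ") vs ", x$class_b, " (n=", x$n_b,
      ", median=", signif(x$median_b, 4), ")\n", sep = "")
  cat("  Welch t = ", signif(x$welch$statistic, 4), ", p = ",
      format.pval(x$welch$p_value, digits = 3), "\n", sep = "")
  cat("  Mann-Whitney U = ", x$u_statistic, " (U/n1n2 = ",
      signif(x$auc, 3), "), p = ",
      format.pval(x$u_p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a two-test class comparison
#'
#' @param x A `class_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per test (`welch`, `mann_whitney`).
#' @export
#' @exportS3Method generics::tidy
tidy.class_comparison <- function(x, ...) {
  tibble(
    class_a = x$class_a, class_b = x$class_b,
    n_a = x$n_a, n_b = x$n_b,
    test = c("welch", "mann_whitney"),
    statistic = c(x$welch$statistic, x$u_statistic),
    p_value = c(x$welch$p_value, x$u_p_value)
  )
}

#' @rdname tidy.class_comparison
#' @export
#' @exportS3Method generics::glance
glance.class_comparison <- function(x, ...) {
  tibble(
    class_a = x$class_a, class_b = x$class_b,
    median_a = x$median_a, median_b = x$median_b,
    welch_t = x$welch$statistic, welch_p = x$welch$p_value,
    u_statistic = x$u_statistic, auc = x$auc, u_p = x$u_p_value
  )
}
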