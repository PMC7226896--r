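#' Configure a full synthetic study run
#'
#' Bundles generator specs and analysis options for [run_all()]. Stage
#' seeds are derived deterministically from the master `seed` unless a
#' generator spec carries its own.
#'
#' @param seed Master seed for the run.
#' @param cohort,landscape,screen Generator specs ([cohort_spec()],
#'   [landscape_spec()], [screen_spec()]).
#' @param zstar_method Imbalance statistic variant (see
#'   [imbalance_table()]).
#' @param tau Epistate call threshold for [breakpoint_contrast_table()].
#' @param se_gap Enhancer stitching gap in bp.
#' @param ref_day Screen reference day (default: earliest).
#' @param boost_factor Signal boost applied to one SE region to build the
#'   second, "fusion-like" landscape sample for the rank-percentile
#'   contrast.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, cohort = cohort_spec(),
                       landscape = landscape_spec(),
                       screen = screen_spec(),
                       zstar_method = "cohort", tau = 1.5,
                       se_gap = 12500, ref_day = NULL,
                       boost_factor = 10, out_dir = NULL) {
  structure(
    list(seed = as.integer(seed), cohort = cohort, landscape = landscape,
         screen = screen, zstar_method = zstar_method, tau = tau,
         se_gap = se_gap, ref_day = ref_day, boost_factor = boost_factor,
         out_dir = out_dir),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full synthetic study end to end
#'
#' Executes simulate-then-analyze for every module and returns one report
#' bundle: (1) the cohort imbalance table with fusion-vs-FN group
#' comparisons and breakpoint contrasts; (2) SE calls plus a two-sample
#' rank-percentile contrast at a boosted locus; (3) the toy derivative
#' locus with its insulated neighborhood and element classification;
#' (4) screen element scores with class comparisons. With `out_dir` set,
#' every table is written as TSV alongside a JSON manifest recording
#' parameters, seeds and output checksums; a rerun with the same config
#' is bit-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (overrides the config's).
#' @return Invisibly, a named list of result tables and fitted
#'   comparisons.
#' @export
run_all <- function(config = run_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  seed_for <- function(spec, stage) {
    if (!is.null(spec$seed)) spec$seed else derive_seed(config$seed, stage)
  }

  # -- cohort imbalance -------------------------------------------------
  cohort <- run_stage("cohort", {
    spec <- config$cohort
    spec$seed <- seed_for(spec, 1L)
    sim <- sim_exon_counts(spec)
    expr <- normalize_exon_counts(sim$counts)
    scores <- imbalance_table(expr, sim$samples,
                              method = config$zstar_method)
    fp_groups <- names(spec$fusions)
    comparisons <- purrr::map(fp_groups, function(g) {
      n_g <- sum(sim$samples$group == g)
      if (n_g < 2 || !"FN" %in% sim$samples$group) return(NULL)
      gene <- sim$truth %>%
        filter(.data$group == g, .data$role == "five_prime") %>%
        pull("gene_id")
      if (length(gene) == 0) return(NULL)
      gene_scores <- scores %>% filter(.data$gene_id == gene[[1]])
      tidy(compare_groups(gene_scores, g, "FN")) %>%
        mutate(gene_id = gene[[1]], .before = 1)
    }) %>% bind_rows()
    contrasts <- purrr::map(fp_groups, function(g) {
      tr <- sim$truth %>%
        filter(.data$group == g, .data$role == "five_prime")
      if (nrow(tr) == 0) return(NULL)
      ids <- sim$samples$sample_id[sim$samples$group == g]
      breakpoint_contrast_table(
        expr %>% select(all_of(c("gene_id", "exon_index", "length", ids))),
        tr$gene_id[[1]], tr$retained[[1]], tau = config$tau
      ) %>%
        mutate(group = g, gene_id = tr$gene_id[[1]])
    }) %>% bind_rows()
    list(sim = sim, scores = scores, comparisons = comparisons,
         contrasts = contrasts)
  })

  # -- enhancer landscape / SE calls ------------------------------------
  enhancers <- run_stage("landscape", {
    spec <- config$landscape
    spec$seed <- seed_for(spec, 2L)
    land <- sim_enhancer_landscape(spec)
    stitched <- stitch_enhancers(land, gap = config$se_gap)
    ranked <- call_superenhancers(stitched)
    # second "sample": boost the first ground-truth SE region to emulate
    # an enhancer gaining rank in the fusion condition
    boosted_land <- land
    target <- which(land$truth_se)[1]
    if (!is.na(target)) {
      boosted_land$signal[target] <-
        boosted_land$signal[target] * config$boost_factor
      query <- land[target, ]
    } else {
      query <- land[which.max(land$signal), ]
    }
    ranked_boost <- call_superenhancers(
      stitch_enhancers(boosted_land, gap = config$se_gap)
    )
    percentiles <- rank_percentile(
      list(baseline = ranked, boosted = ranked_boost),
      query$chrom, query$start, query$end
    )
    list(landscape = land, ranked = ranked, percentiles = percentiles,
         summary = tibble(
           n_regions = nrow(ranked), n_se = sum(ranked$se_flag),
           se_fraction = mean(ranked$se_flag),
           cutoff_signal = attr(ranked, "cutoff_signal")
         ))
  })

  # -- neo-TAD reconstruction -------------------------------------------
  neotad <- run_stage("neo_tad", {
    toy <- toy_fusion_locus()
    nbhd <- define_neighborhood(toy$sites, toy$anchor)
    annotated <- classify_elements(nbhd, toy$elements)
    list(locus = toy$locus, neighborhood = nbhd, elements = annotated)
  })

  # -- CRISPR screen ----------------------------------------------------
  screen <- run_stage("screen", {
    spec <- config$screen
    spec$seed <- seed_for(spec, 3L)
    sim <- sim_screen_counts(spec)
    lfc <- sim$counts %>%
      normalize_screen() %>%
      sgrna_lfc(ref_day = config$ref_day)
    scores <- aggregate_elements(lfc)
    term <- terminal_scores(scores)
    comparisons <- bind_rows(
      tidy(compare_element_classes(term, "promoter", "control")),
      tidy(compare_element_classes(term, "intra_tad_se",
                                   "typical_enhancer")),
      tidy(compare_element_classes(term, "intra_tad_se",
                                   "outside_tad_se"))
    )
    list(sim = sim, scores = scores, terminal = term,
         comparisons = comparisons)
  })

  results <- list(
    imbalance_scores = cohort$scores,
    imbalance_comparisons = cohort$comparisons,
    breakpoint_contrasts = cohort$contrasts,
    ranked_enhancers = enhancers$ranked,
    se_summary = enhancers$summary,
    locus_percentiles = enhancers$percentiles,
    neighborhood = neotad$neighborhood,
    tad_elements = neotad$elements,
    screen_scores = screen$scores,
    screen_comparisons = screen$comparisons
  )

  if (!is.null(out_dir)) {
    run_stage("write_outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tables <- list(
        imbalance_scores = cohort$scores,
        imbalance_comparisons = cohort$comparisons,
        breakpoint_contrasts = cohort$contrasts,
        ranked_enhancers = enhancers$ranked,
        se_summary = enhancers$summary,
        locus_percentiles = enhancers$percentiles,
        tad_elements = neotad$elements,
        screen_terminal_scores = screen$terminal,
        screen_comparisons = screen$comparisons
      )
      paths <- purrr::imap_chr(tables, function(tb, nm) {
        p <- file.path(out_dir, paste0(nm, ".tsv"))
        readr::write_tsv(as_tibble(tb), p)
        p
      })
      manifest <- list(
        package = "miswire",
        version = as.character(utils::packageVersion("miswire")),
        seed = config$seed,
        parameters = list(
          zstar_method = config$zstar_method, tau = config$tau,
          se_gap = config$se_gap, boost_factor = config$boost_factor,
          cohort = unclass(config$cohort)[
            c("groups", "r", "phi", "base_rate", "silenced_wt")],
          landscape = unclass(config$landscape)[
            c("n_enhancers", "tail_fraction", "tail_multiplier")],
          screen = list(timepoints = config$screen$timepoints,
                        depth = config$screen$depth)
        ),
        outputs = as.list(setNames(unname(tools::md5sum(unname(paths))),
                                   basename(unname(paths))))
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
    results$out_dir <- out_dir
  }
  invisible(results)
}
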