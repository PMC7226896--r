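#' Specify a synthetic pooled CRISPR tiling screen
#'
#' Emulates negative selection in a tiling screen over the regulatory
#' elements of a fusion-driven locus. Each element class depletes its
#' latent abundance exponentially at `delta` per day; sequencing at each
#' timepoint is a multinomial sample of fixed depth from the latent pool.
#' The default library mimics a tiling design: a small number of strongly
#' selected elements (promoter, intra-TAD super enhancers, TAD-boundary
#' CTCF sites), weakly selected typical enhancers and outside-TAD SEs, and
#' a majority of neutral controls.
#'
#' @param classes A tibble with columns `class`, `n_elements`,
#'   `sgrnas_per_element`, `delta` (depletion rate per day, >= 0) and
#'   `intra_tad`.
#' @param timepoints Sampling days, strictly increasing; the first is the
#'   reference.
#' @param depth Sequencing depth per timepoint.
#' @param sgrna_sdlog Log-normal spread of initial sgRNA abundances.
#' @param seed Optional integer seed.
#' @return A `screen_spec` object.
#' @export
screen_spec <- function(classes = default_screen_classes(),
                        timepoints = c(2, 5, 7, 10, 13, 17, 20, 25),
                        depth = 1e6, sgrna_sdlog = 0.25, seed = NULL) {
  check_columns(classes, c("class", "n_elements", "sgrnas_per_element",
                           "delta", "intra_tad"), "classes")
  if (any(diff(timepoints) <= 0)) {
    abort("timepoints must be strictly increasing")
  }
  if (any(classes$delta < 0)) abort("depletion rates must be >= 0")
  if (depth <= 0) abort("depth must be > 0")
  structure(
    list(classes = as_tibble(classes), timepoints = timepoints,
         depth = depth, sgrna_sdlog = sgrna_sdlog, seed = seed),
    class = "screen_spec"
  )
}

#' @rdname screen_spec
#' @export
default_screen_classes <- function() {
  tibble(
    class = c("promoter", "intra_tad_se", "boundary_ctcf",
              "typical_enhancer", "outside_tad_se", "control"),
    n_elements = c(4L, 8L, 8L, 20L, 8L, 152L),
    sgrnas_per_element = 5L,
    delta = c(0.30, 0.15, 0.08, 0.01, 0.01, 0),
    intra_tad = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Simulate sgRNA counts over a dropout time course
#'
#' The latent abundance of sgRNA g at day t is
#' \eqn{a_g(t) = a_g(t_0)\, e^{-\delta_{class} (t - t_0)}} with \eqn{t_0}
#' the first timepoint; observed counts at each timepoint are a multinomial
#' draw of `depth` reads over all sgRNAs proportional to latent abundance.
#'
#' @param spec A [screen_spec()].
#' @return A list of class `screen_sim` with `counts` (tibble: `sgrna_id`,
#'   `element_id`, `class`, `intra_tad`, one `day_<t>` column per
#'   timepoint) and `truth` (the class table with depletion rates).
#' @examples
#' sim <- sim_screen_counts(screen_spec(seed = 1))
#' sim$counts[1:3, 1:6]
#' @export
sim_screen_counts <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  cl <- spec$classes
  ann <- purrr::pmap(cl, function(class, n_elements, sgrnas_per_element,
                                  delta, intra_tad) {
    el <- rep(sprintf("%s_e%03d", class, seq_len(n_elements)),
              each = sgrnas_per_element)
    tibble(
      sgrna_id = sprintf("%s_g%d", el,
                         rep(seq_len(sgrnas_per_element), n_elements)),
      element_id = el, class = class, intra_tad = intra_tad, delta = delta
    )
  }) %>% bind_rows()
  if (anyDuplicated(ann$sgrna_id) > 0) {
    abort("duplicate sgRNA identifiers in screen design")
  }
  with_optional_seed(spec$seed, {
    a0 <- rlnorm(nrow(ann), 0, spec$sgrna_sdlog)
    t0 <- spec$timepoints[[1]]
    counts <- ann %>% select(-"delta")
    for (t in spec$timepoints) {
      latent <- a0 * exp(-ann$delta * (t - t0))
      counts[[paste0("day_", t)]] <-
        as.integer(rmultinom(1, size = spec$depth,
                             prob = latent / sum(latent)))
    }
    structure(list(counts = counts, truth = cl), class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim>", nrow(x$counts), "sgRNAs x",
      sum(startsWith(names(x$counts), "day_")), "timepoints\n")
  invisible(x)
}
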