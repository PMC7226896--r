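#' Load single-transcript gene models from a GTF/GFF file
#'
#' Reads exon records and returns one canonical exon chain per gene, ordered
#' in transcription order (exon 1 first: leftmost exon for forward-strand
#' genes, rightmost for reverse-strand genes). GTF 1-based closed
#' coordinates are converted to the package-internal 0-based half-open
#' convention on read; BED-style inputs elsewhere are used natively.
#'
#' @param path Path to a GTF/GFF file whose exon features carry `gene_id`
#'   attributes.
#' @return A tibble with columns `gene_id`, `exon_index`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand` (`"+"`/`"-"`), one row per exon,
#'   sorted by gene and transcription order.
#' @examples
#' models <- toy_gene_models()
#' dplyr::count(models, gene_id)
#' @seealso [map_breakpoint_to_exons()], [build_fusion_transcript()]
#' @export
load_gene_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) {
      abort(paste0("failed to parse gene model file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  if (!is.null(gr$type)) {
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
  }
  if (length(gr) == 0) {
    abort(paste0("no exon records found in '", path, "'"))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    abort("exon records must carry a gene_id attribute")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("every exon must have an explicit strand (+ or -)")
  }
  exons <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF 1-based -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand
  )
  order_gene_models(exons)
}

# Assign transcription-order exon indices and validate per-gene invariants.
order_gene_models <- function(exons) {
  out <- exons %>%
    group_by(.data$gene_id) %>%
    arrange(
      if_else(.data$strand == "+", 1L, -1L) * .data$start,
      .by_group = TRUE
    ) %>%
    mutate(exon_index = row_number()) %>%
    ungroup() %>%
    select("gene_id", "exon_index", "chrom", "start", "end", "strand")
  bad <- out %>% filter(.data$end <= .data$start)
  if (nrow(bad) > 0) {
    abort(paste0("exon with end <= start in gene ", bad$gene_id[[1]]))
  }
  multi <- out %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_strand = dplyr::n_distinct(.data$strand),
      n_chrom = dplyr::n_distinct(.data$chrom),
      .groups = "drop"
    ) %>%
    filter(.data$n_strand > 1 | .data$n_chrom > 1)
  if (nrow(multi) > 0) {
    abort(paste0("gene ", multi$gene_id[[1]],
                 " mixes strands or chromosomes"))
  }
  overlaps <- out %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(bad = any(.data$start < lag(.data$end), na.rm = TRUE),
              .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(overlaps) > 0) {
    abort(paste0("overlapping exons in gene ", overlaps$gene_id[[1]]))
  }
  out
}

#' Packaged toy gene models for the five recurrent PAX-fusion partners
#'
#' Loads the small GTF shipped with the package: PAX3-like and PAX7-like
#' 9-exon genes, a FOXO1-like 3-exon gene, an INO80D-like 11-exon gene and
#' an NCOA1-like 22-exon gene. Exon k of each gene spans
#' `[offset + 1000k, offset + 1000k + 200)` in 0-based coordinates (mirrored
#' for the reverse-strand PAX7 model), so every intron hosts an
#' unambiguous breakpoint position.
#'
#' @return A gene-model tibble as produced by [load_gene_models()].
#' @export
toy_gene_models <- function() {
  load_gene_models(
    system.file("extdata", "toy_gene_models.gtf", package = "miswire")
  )
}

#' Packaged breakpoint coordinates for the recurrent PAX fusions
#'
#' Breakpoint positions (0-based, intronic) on the toy gene models of
#' [toy_gene_models()], chosen so the resulting fusion transcripts carry the
#' clinically described exon architectures: PAX3-FOXO1 joins PAX3 exons 1-7
#' to FOXO1 exons 2-3; PAX3-INO80D joins exons 1-7 to INO80D exons 9-11;
#' PAX3-NCOA1 type 1 joins exons 1-6 to NCOA1 exons 13-22 and type 2 joins
#' exons 1-7 to exons 12-22; PAX7-FOXO1 joins PAX7 exons 1-7 to FOXO1
#' exons 2-3.
#'
#' @return A tibble with columns `fusion`, `five_gene`, `five_pos`,
#'   `three_gene`, `three_pos`.
#' @export
toy_fusion_breakpoints <- function() {
  readr::read_tsv(
    system.file("extdata", "toy_fusion_breakpoints.tsv", package = "miswire"),
    col_types = readr::cols(
      fusion = readr::col_character(),
      five_gene = readr::col_character(),
      five_pos = readr::col_integer(),
      three_gene = readr::col_character(),
      three_pos = readr::col_integer()
    )
  )
}

#' Map a genomic breakpoint to retained and lost exons
#'
#' For a `five_prime` partner the retained exons are those transcriptionally
#' upstream of the breakpoint (the fusion keeps the gene's own promoter and
#' leading exons); for a `three_prime` partner the retained exons are those
#' downstream. Retained and lost sets partition the gene's exons.
#'
#' Breakpoints are expected to be intronic. A breakpoint inside an exon is
#' an error unless `allow_exonic = TRUE`, in which case the containing exon
#' is counted as retained (truncated at the breakpoint). A breakpoint
#' outside the gene span is allowed with a warning and yields the boundary
#' result (an empty or complete retained set).
#'
#' @param models Gene-model tibble (see [load_gene_models()]).
#' @param gene_id Gene to map the breakpoint onto.
#' @param position Breakpoint coordinate (0-based).
#' @param role `"five_prime"` or `"three_prime"`: which side of the fusion
#'   this gene contributes.
#' @param chrom Optional chromosome check against the gene model.
#' @param allow_exonic Permit exonic breakpoints (truncating the exon).
#' @return A list with integer vectors `retained` and `lost` of exon
#'   indices (transcription order).
#' @examples
#' models <- toy_gene_models()
#' map_breakpoint_to_exons(models, "PAX3", 7500, "five_prime")
#' @export
map_breakpoint_to_exons <- function(models, gene_id, position,
                                    role = c("five_prime", "three_prime"),
                                    chrom = NULL, allow_exonic = FALSE) {
  role <- arg_match(role)
  check_columns(models, c("gene_id", "exon_index", "chrom", "start", "end",
                          "strand"), "gene models")
  gene <- models %>%
    filter(.data$gene_id == !!gene_id) %>%
    arrange(.data$exon_index)
  if (nrow(gene) == 0) {
    abort(paste0("gene '", gene_id, "' not found in models"))
  }
  if (!is.null(chrom) && chrom != gene$chrom[[1]]) {
    abort(paste0("breakpoint chromosome ", chrom,
                 " does not match gene ", gene_id))
  }
  inside <- gene$start < position & position < gene$end
  if (any(inside) && !allow_exonic) {
    abort(paste0(
      "exonic breakpoint: position ", position, " falls inside exon ",
      gene$exon_index[inside][[1]], " of ", gene_id,
      " (use allow_exonic = TRUE to truncate)"
    ))
  }
  if (position < min(gene$start) || position > max(gene$end)) {
    warn(paste0("breakpoint ", position, " lies outside the span of ",
                gene_id, "; retained set is a boundary case"))
  }
  upstream <- if (gene$strand[[1]] == "+") {
    gene$end <= position
  } else {
    gene$start >= position
  }
  retained_mask <- if (role == "five_prime") upstream | inside else !upstream
  list(
    retained = sort(gene$exon_index[retained_mask]),
    lost = sort(gene$exon_index[!retained_mask])
  )
}

#' Construct a fusion transcript from two breakpoints
#'
#' Joins the transcriptionally leading exons of the 5' partner (a contiguous
#' prefix `1..k`) to the trailing exons of the 3' partner (a contiguous
#' suffix `m..N`). An empty 5' retained set yields a promoterless fusion
#' and a warning, not an error.
#'
#' @param models Gene-model tibble.
#' @param five_gene,five_pos 5' partner gene and its breakpoint position.
#' @param three_gene,three_pos 3' partner gene and its breakpoint position.
#' @param allow_exonic Passed to [map_breakpoint_to_exons()].
#' @return A `fusion_transcript` object; use [tidy()] for the per-exon
#'   report or [write_fusion_report()] to export it as TSV.
#' @examples
#' models <- toy_gene_models()
#' ft <- build_fusion_transcript(models, "PAX3", 7500, "FOXO1", 1500)
#' ft
#' tidy(ft)
#' @export
build_fusion_transcript <- function(models, five_gene, five_pos,
                                    three_gene, three_pos,
                                    allow_exonic = FALSE) {
  m5 <- map_breakpoint_to_exons(models, five_gene, five_pos, "five_prime",
                                allow_exonic = allow_exonic)
  m3 <- map_breakpoint_to_exons(models, three_gene, three_pos, "three_prime",
                                allow_exonic = allow_exonic)
  n5 <- models %>% filter(.data$gene_id == five_gene) %>% nrow()
  n3 <- models %>% filter(.data$gene_id == three_gene) %>% nrow()
  if (!identical(m5$retained, seq_len(length(m5$retained)))) {
    abort("internal error: 5' retained exons are not a contiguous prefix")
  }
  if (length(m3$retained) > 0 &&
      !identical(m3$retained, seq.int(min(m3$retained), n3))) {
    abort("internal error: 3' retained exons are not a contiguous suffix")
  }
  if (length(m5$retained) == 0) {
    warn(paste0("promoterless fusion: no ", five_gene,
                " exons upstream of breakpoint ", five_pos))
  }
  structure(
    list(
      five_gene = five_gene, five_pos = five_pos,
      retained_5p = m5$retained, lost_5p = m5$lost,
      three_gene = three_gene, three_pos = three_pos,
      retained_3p = m3$retained, lost_3p = m3$lost,
      n_exons = length(m5$retained) + length(m3$retained),
      exons = models %>%
        filter(.data$gene_id %in% c(five_gene, three_gene))
    ),
    class = "fusion_transcript"
  )
}

#' @export
print.fusion_transcript <- function(x, ...) {
  fmt <- function(idx) {
    if (length(idx) == 0) "none" else paste0(min(idx), "-", max(idx))
  }
  cat("<fusion_transcript> ", x$five_gene, "-", x$three_gene, "\n", sep = "")
  cat("  5' ", x$five_gene, " exons ", fmt(x$retained_5p),
      " (breakpoint ", x$five_pos, ")\n", sep = "")
  cat("  3' ", x$three_gene, " exons ", fmt(x$retained_3p),
      " (breakpoint ", x$three_pos, ")\n", sep = "")
  cat("  ", x$n_exons, " exons total\n", sep = "")
  invisible(x)
}

#' Tidy a fusion transcript into a per-exon report
#'
#' @param x A `fusion_transcript`.
#' @param ... Unused.
#' @return A tibble with one row per exon of both partner genes: `segment`
#'   (`"five_prime"`/`"three_prime"`), `gene_id`, `exon_index`, `chrom`,
#'   `start`, `end`, `strand` and a logical `retained` flag.
#' @export
#' @exportS3Method generics::tidy
tidy.fusion_transcript <- function(x, ...) {
  bind_rows(
    x$exons %>%
      filter(.data$gene_id == x$five_gene) %>%
      mutate(segment = "five_prime",
             retained = .data$exon_index %in% x$retained_5p),
    x$exons %>%
      filter(.data$gene_id == x$three_gene) %>%
      mutate(segment = "three_prime",
             retained = .data$exon_index %in% x$retained_3p)
  ) %>%
    select("segment", "gene_id", "exon_index", "chrom", "start", "end",
           "strand", "retained")
}

#' @rdname tidy.fusion_transcript
#' @param path Output TSV path.
#' @export
write_fusion_report <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
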