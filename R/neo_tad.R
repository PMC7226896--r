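#' Reconstruct the derivative (translocated) locus
#'
#' Concatenates the 5' and 3' source segments of a translocation onto a
#' single derivative coordinate axis (5' segment first) and remaps
#' point features (CTCF sites, enhancers, promoters) onto it with full
#' provenance. On a non-flipped segment `[s, e)` with derivative offset
#' `o`, a source position `p` maps to `o + (p - s)`; on a flipped segment
#' it maps to the mirror position `o + (e - p)` and any motif orientation
#' is reversed. The mapping is exactly invertible
#' ([derivative_to_source()]).
#'
#' @param five,three Segment specs: lists with `chrom`, `start`, `end`
#'   (0-based half-open) and optional `flipped` (default `FALSE`).
#' @param features Optional tibble of point features with columns `chrom`,
#'   `position`, and optionally `orientation`, `name`, `class`. Features
#'   outside both segments are dropped with a warning; a feature falling
#'   inside two overlapping source segments is an error.
#' @return A `derivative_locus` object with `segments` and remapped
#'   `features` tibbles and the total derivative `length`.
#' @examples
#' locus <- build_derivative_locus(
#'   five = list(chrom = "chr2", start = 0, end = 1000),
#'   three = list(chrom = "chr13", start = 5000, end = 7000),
#'   features = tibble::tibble(chrom = "chr13", position = 5500,
#'                             name = "site")
#' )
#' locus$features
#' @export
build_derivative_locus <- function(five, three, features = NULL) {
  seg <- function(spec, role, offset) {
    stopifnot(all(c("chrom", "start", "end") %in% names(spec)))
    if (spec$end <= spec$start) abort("segment must have start < end")
    tibble(
      segment = role, chrom = spec$chrom,
      start = as.numeric(spec$start), end = as.numeric(spec$end),
      flipped = isTRUE(spec$flipped), offset = offset,
      length = as.numeric(spec$end - spec$start)
    )
  }
  s5 <- seg(five, "five_prime", 0)
  s3 <- seg(three, "three_prime", s5$length)
  segments <- bind_rows(s5, s3)

  mapped <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    check_columns(features, c("chrom", "position"), "features")
    hits <- purrr::map(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      in_seg <- segments$chrom == f$chrom &
        segments$start <= f$position & f$position < segments$end
      if (sum(in_seg) > 1) {
        abort("overlapping source segments map a feature twice")
      }
      if (!any(in_seg)) return(NULL)
      sg <- segments[in_seg, ]
      dpos <- if (sg$flipped) sg$offset + (sg$end - f$position)
              else sg$offset + (f$position - sg$start)
      ori <- if ("orientation" %in% names(f) && !is.na(f$orientation)) {
        if (sg$flipped) flip_orientation(f$orientation) else f$orientation
      } else {
        NA_character_
      }
      f %>%
        rename(source_chrom = "chrom", source_pos = "position") %>%
        mutate(segment = sg$segment, derivative_pos = dpos,
               orientation = ori)
    })
    dropped <- sum(purrr::map_lgl(hits, is.null))
    if (dropped > 0) {
      warn(paste0(dropped,
                  " feature(s) outside both segments were dropped"))
    }
    mapped <- bind_rows(hits)
    if (!is.null(mapped) && nrow(mapped) > 0) {
      mapped <- mapped %>% arrange(.data$derivative_pos)
    }
  }
  structure(
    list(segments = segments, features = mapped,
         length = sum(segments$length)),
    class = "derivative_locus"
  )
}

#' @export
print.derivative_locus <- function(x, ...) {
  cat("<derivative_locus> length", x$length, "bp\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat("  ", s$segment, ": ", s$chrom, ":", s$start, "-", s$end,
        if (s$flipped) " (flipped)" else "", " -> [", s$offset, ", ",
        s$offset + s$length, ")\n", sep = "")
  }
  if (!is.null(x$features)) {
    cat(" ", nrow(x$features), "mapped feature(s)\n")
  }
  invisible(x)
}

#' Map derivative coordinates back to source coordinates
#'
#' Exact inverse of the remapping performed by
#' [build_derivative_locus()].
#'
#' @param locus A `derivative_locus`.
#' @param derivative_pos Numeric vector of derivative-axis positions.
#' @return Tibble with `derivative_pos`, `segment`, `chrom`,
#'   `source_pos`.
#' @export
derivative_to_source <- function(locus, derivative_pos) {
  stopifnot(inherits(locus, "derivative_locus"))
  purrr::map(derivative_pos, function(d) {
    segs <- locus$segments
    in_seg <- ifelse(
      segs$flipped,
      segs$offset < d & d <= segs$offset + segs$length,
      segs$offset <= d & d < segs$offset + segs$length
    )
    if (!any(in_seg)) {
      abort(paste0("derivative position ", d, " outside the locus"))
    }
    sg <- segs[which(in_seg)[[1]], ]
    src <- if (sg$flipped) sg$end - (d - sg$offset)
           else sg$start + (d - sg$offset)
    tibble(derivative_pos = d, segment = sg$segment, chrom = sg$chrom,
           source_pos = src)
  }) %>% bind_rows()
}

#' Enumerate loop-permissive convergent CTCF pairs
#'
#' Cohesin-extrusion loops form preferentially between CTCF sites whose
#' motifs are antiparallel and point toward each other. On a single axis,
#' the pair (i, j) with `position_i < position_j` is permissive exactly
#' when site i is `forward` and site j is `reverse`.
#'
#' @param sites Tibble with `position`, `orientation`
#'   (`"forward"`/`"reverse"`) and optionally `label`.
#' @return Tibble of permissive pairs (`left_label`, `left_pos`,
#'   `right_label`, `right_pos`, `span`), sorted by increasing span.
#' @examples
#' convergent_pairs(tibble::tibble(
#'   position = c(100, 500),
#'   orientation = c("forward", "reverse")
#' ))
#' @export
convergent_pairs <- function(sites) {
  check_columns(sites, c("position", "orientation"), "CTCF sites")
  if (anyNA(sites$orientation) ||
      any(!sites$orientation %in% c("forward", "reverse"))) {
    abort("every site needs an orientation of 'forward' or 'reverse'")
  }
  if (!"label" %in% names(sites)) {
    sites$label <- sprintf("site_%02d", seq_len(nrow(sites)))
  }
  s <- sites %>% arrange(.data$position)
  fwd <- which(s$orientation == "forward")
  rev_ <- which(s$orientation == "reverse")
  pairs <- expand.grid(i = fwd, j = rev_) %>%
    filter(s$position[.data$i] < s$position[.data$j])
  tibble(
    left_label = s$label[pairs$i], left_pos = s$position[pairs$i],
    right_label = s$label[pairs$j], right_pos = s$position[pairs$j]
  ) %>%
    mutate(span = .data$right_pos - .data$left_pos) %>%
    arrange(.data$span, .data$left_pos)
}

#' Define the insulated neighborhood around an anchor
#'
#' The neighborhood containing a promoter anchor is the
#' smallest-span convergent CTCF pair strictly containing it — the
#' innermost loop is taken as the operative regulatory unit. The
#' outermost spanning pair (the TAD-boundary candidate) is reported
#' alongside for comparison. When no permissive pair spans the anchor the
#' result is an explicit "no neighborhood", not an error.
#'
#' @param sites CTCF site tibble (see [convergent_pairs()]).
#' @param anchor Anchor position (e.g. the fusion promoter) on the same
#'   axis.
#' @return A `neighborhood` object with `found`, `left`/`right` boundary
#'   rows, `outermost` pair and the anchored pair table.
#' @export
define_neighborhood <- function(sites, anchor) {
  pairs <- convergent_pairs(sites)
  spanning <- pairs %>%
    filter(.data$left_pos < anchor, anchor < .data$right_pos)
  if (nrow(spanning) == 0) {
    return(structure(
      list(found = FALSE, anchor = anchor, pairs = spanning,
           left = NULL, right = NULL, outermost = NULL),
      class = "neighborhood"
    ))
  }
  inner <- spanning %>% slice(1)
  outer <- spanning %>% arrange(desc(.data$span)) %>% slice(1)
  structure(
    list(
      found = TRUE, anchor = anchor, pairs = spanning,
      left = list(label = inner$left_label, position = inner$left_pos),
      right = list(label = inner$right_label, position = inner$right_pos),
      outermost = list(left_label = outer$left_label,
                       left_pos = outer$left_pos,
                       right_label = outer$right_label,
                       right_pos = outer$right_pos)
    ),
    class = "neighborhood"
  )
}

#' @export
print.neighborhood <- function(x, ...) {
  if (!x$found) {
    cat("<neighborhood> none: no convergent pair spans anchor at",
        x$anchor, "\n")
    return(invisible(x))
  }
  cat("<neighborhood> anchor", x$anchor, "inside [", x$left$position, ",",
      x$right$position, "] (", x$left$label, "-", x$right$label, ")\n")
  cat("  outermost spanning pair: [", x$outermost$left_pos, ",",
      x$outermost$right_pos, "] (", x$outermost$left_label, "-",
      x$outermost$right_label, ")\n")
  cat(" ", nrow(x$pairs), "anchored permissive pair(s)\n")
  invisible(x)
}

#' Classify regulatory elements as intra-TAD or outside
#'
#' Flags each element by strict containment between the neighborhood
#' boundaries (an element exactly at a boundary position is outside) and
#' builds the composite class label used by the screen analysis, e.g.
#' `"intra-TAD SE"` or `"SE outside TAD"`.
#'
#' @param neighborhood A [define_neighborhood()] result.
#' @param elements Tibble with `class` and either `position` or
#'   `start`/`end` (midpoint used) columns.
#' @return The elements with `position`, `intra_tad` and `label` columns.
#' @export
classify_elements <- function(neighborhood, elements) {
  stopifnot(inherits(neighborhood, "neighborhood"))
  check_columns(elements, "class", "elements")
  el <- as_tibble(elements)
  if (!"position" %in% names(el)) {
    if (!all(c("start", "end") %in% names(el))) {
      abort("elements need a position (or start/end) column")
    }
    el$position <- (el$start + el$end) / 2
  }
  if (anyNA(el$position)) abort("element without coordinates")
  inside <- if (neighborhood$found) {
    neighborhood$left$position < el$position &
      el$position < neighborhood$right$position
  } else {
    rep(FALSE, nrow(el))
  }
  el %>%
    mutate(
      intra_tad = inside,
      label = if_else(.data$intra_tad,
                      paste0("intra-TAD ", .data$class),
                      paste0(.data$class, " outside TAD"))
    )
}

#' Toy fusion-locus model with convergent CTCF geometry
#'
#' A compact derivative-locus model of the translocation: a 5' segment
#' carrying the PAX3-side boundary CTCF site (forward motif) and the
#' fusion promoter, joined to a 3' segment carrying the FOXO1 super
#' enhancer and three distal CTCF sites of which the first and third
#' (reading outward; labels `FOXO1_site3`, `FOXO1_site2`, `FOXO1_site1`
#' in axis order with `site1` outermost) are reverse-oriented —
#' antiparallel to the promoter-side motif — while the middle site points
#' away. Exactly two promoter-anchored permissive pairs result.
#'
#' @return A list with the `derivative_locus`, the CTCF `sites` on the
#'   derivative axis, the promoter `anchor` position and an `elements`
#'   table (promoter, SEs, typical enhancer) for classification.
#' @export
toy_fusion_locus <- function() {
  locus <- build_derivative_locus(
    five = list(chrom = "chr2", start = 0, end = 50000),
    three = list(chrom = "chr13", start = 100000, end = 250000),
    features = tibble(
      chrom = c("chr2", "chr13", "chr13", "chr13"),
      position = c(10000, 140000, 170000, 200000),
      orientation = c("forward", "reverse", "forward", "reverse"),
      name = c("PAX3_boundary", "FOXO1_site3", "FOXO1_site2",
               "FOXO1_site1"),
      class = "CTCF"
    )
  )
  sites <- locus$features %>%
    select(label = "name", position = "derivative_pos", "orientation")
  elements <- tibble(
    name = c("PAX3_promoter", "FOXO1_SE", "intronic_enhancer",
             "distal_SE"),
    class = c("promoter", "SE", "typical enhancer", "SE"),
    position = c(12000, 70000, 30000, 160000)
  )
  list(locus = locus, sites = sites, anchor = 12000, elements = elements)
}
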