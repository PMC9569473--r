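#' Segmentation schemes
#'
#' A segmentation scheme records the divide-and-conquer bookkeeping of a
#' large protein: named segments at three levels (`subunit`, `domain`,
#' `coil`), each an ordered set of inclusive 1-based residue ranges, plus
#' the mature-sequence span and an optional coverage mask of residues
#' actually present in the models (unmodeled stretches stay in the scheme
#' but are excluded from measurement).
#'
#' @param segments Data frame with columns `segment`, `level` (one of
#'   subunit/domain/coil) and `start`, `end` (one row per range; a segment
#'   may own several ranges).
#' @param span `c(first, last)` residue numbers of the mature sequence.
#' @param coverage Optional integer vector of modeled residues; `NULL`
#'   means everything in `span` is modeled.
#' @return An `xl_scheme` object.
#' @export
new_scheme <- function(segments, span, coverage = NULL) {
  segments <- as_tibble(segments)
  needed <- c("segment", "level", "start", "end")
  if (!all(needed %in% names(segments))) {
    abort(paste("Scheme segments need columns:", paste(needed, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  check_ranges(segments$start, segments$end)
  bad_level <- setdiff(unique(segments$level), c("subunit", "domain", "coil"))
  if (length(bad_level)) {
    abort(paste("Unknown segment level(s):", paste(bad_level, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  if (any(segments$start < span[1]) || any(segments$end > span[2])) {
    abort("Segment ranges must lie within the sequence span.",
          class = "xlinkr_range_error")
  }
  # within one level ranges must not overlap
  for (lev in unique(segments$level)) {
    s <- segments[segments$level == lev, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      abort(sprintf("Overlapping ranges at level '%s'.", lev),
            class = "xlinkr_range_error")
    }
  }
  structure(list(segments = segments,
                 span = as.integer(span),
                 coverage = if (is.null(coverage)) NULL else as.integer(coverage)),
            class = "xl_scheme")
}

#' @export
print.xl_scheme <- function(x, ...) {
  cat(sprintf("<xl_scheme> span [%d, %d], %d segments (%d ranges)\n",
              x$span[1], x$span[2], length(unique(x$segments$segment)),
              nrow(x$segments)))
  if (!is.null(x$coverage)) {
    cat(sprintf("  coverage mask: %d of %d residues modeled\n",
                length(x$coverage), x$span[2] - x$span[1] + 1L))
  }
  print(x$segments, n = 12)
  invisible(x)
}

#' @export
as_tibble.xl_scheme <- function(x, ...) x$segments

# integer residues belonging to a segment name
segment_residues <- function(scheme, segment) {
  s <- scheme$segments[scheme$segments$segment == segment, ]
  if (!nrow(s)) {
    abort(sprintf("Segment '%s' is not in the scheme.", segment),
          class = "xlinkr_input_error")
  }
  unlist(purrr::map2(s$start, s$end, seq.int), use.names = FALSE)
}

scheme_coverage <- function(scheme) {
  if (!is.null(scheme$coverage)) scheme$coverage
  else seq.int(scheme$span[1], scheme$span[2])
}

#' Count residues in a set of inclusive ranges
#'
#' @param ranges A data frame with `start`, `end` columns, or a numeric
#'   vector `c(start, end)` for a single range.
#' @return Total residue count, `sum(end - start + 1)`.
#' @examples
#' residue_count(c(28, 1017)) # 990
#' @export
residue_count <- function(ranges) {
  if (is.numeric(ranges) && length(ranges) == 2L) {
    ranges <- tibble(start = ranges[1], end = ranges[2])
  }
  ranges <- as_tibble(ranges)
  check_ranges(ranges$start, ranges$end)
  as.integer(sum(ranges$end - ranges$start + 1))
}

#' Fraction of the sequence covered by a segment
#'
#' @param scheme An [new_scheme()] object.
#' @param segment Segment name.
#' @param digits Rounding of the reported percentage (default 1 decimal).
#' @return Percentage of the sequence span, e.g. 21.8 for a 990-residue
#'   subunit of a 4536-residue mature protein.
#' @export
coverage_fraction <- function(scheme, segment, digits = 1) {
  n <- length(segment_residues(scheme, segment))
  total <- scheme$span[2] - scheme$span[1] + 1L
  round(100 * n / total, digits)
}

#' Locate a residue within the segmentation
#'
#' @param scheme An `xl_scheme`.
#' @param residue Integer residue number(s).
#' @return A tibble with one row per residue: `residue`, `subunit`,
#'   `domain`, `coil` (NA where the residue belongs to no segment at that
#'   level) and `outside` (TRUE when the residue is outside the sequence
#'   span, e.g. in the signal peptide).
#' @export
locate_residue <- function(scheme, residue) {
  residue <- as.integer(residue)
  seg <- scheme$segments
  level_of <- function(res, lev) {
    s <- seg[seg$level == lev, ]
    hit <- s$segment[res >= s$start & res <= s$end]
    if (length(hit)) hit[1] else NA_character_
  }
  purrr::map_dfr(residue, function(res) {
    outside <- res < scheme$span[1] || res > scheme$span[2]
    tibble(residue = res,
           subunit = if (outside) NA_character_ else level_of(res, "subunit"),
           domain = if (outside) NA_character_ else level_of(res, "domain"),
           coil = if (outside) NA_character_ else level_of(res, "coil"),
           outside = outside)
  })
}

#' Classify cross-link topology
#'
#' A link is inter-subunit when its endpoints fall in different subunits,
#' intra-domain when both share one domain-level segment, and intra-subunit
#' otherwise (same subunit, e.g. within a coil or across domains).
#'
#' @param scheme An `xl_scheme`.
#' @param links Data frame with `res_a`, `res_b`.
#' @return `links` with a `topology` factor column added.
#' @export
classify_topology <- function(scheme, links) {
  links <- as_tibble(links)
  la <- locate_residue(scheme, links$res_a)
  lb <- locate_residue(scheme, links$res_b)
  if (any(la$outside | lb$outside)) {
    bad <- which(la$outside | lb$outside)[1]
    abort(sprintf("Link endpoint %d is outside the sequence span.",
                  if (la$outside[bad]) links$res_a[bad] else links$res_b[bad]),
          class = "xlinkr_range_error")
  }
  topo <- dplyr::case_when(
    is.na(la$subunit) | is.na(lb$subunit) ~ NA_character_,
    la$subunit != lb$subunit ~ "inter-subunit",
    !is.na(la$domain) & !is.na(lb$domain) & la$domain == lb$domain ~ "intra-domain",
    TRUE ~ "intra-subunit"
  )
  links$topology <- factor(topo, levels = c("intra-domain", "intra-subunit",
                                            "inter-subunit"))
  links
}

#' Packaged apolipoprotein B-100 segmentation
#'
#' The five-subunit, eleven-domain scheme of mature apoB-100 (residues
#' 28-4563 in preproprotein numbering), including the two long coils and
#' the three-piece subunit IV domain 3. The coverage mask excludes the
#' stretches left out of the subunit IV model (2551-2590 and 4056-4057).
#'
#' @return An `xl_scheme`.
#' @export
apob_scheme <- function() {
  read_scheme(system.file("extdata", "apob_scheme.yaml", package = "xlinkr"))
}
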