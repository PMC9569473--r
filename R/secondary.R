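#' Secondary-structure content per segment
#'
#' Tabulates helix (H), strand (E) and coil (C) content from per-residue
#' assignments. Two conventions are exposed: `"total"` (the default)
#' expresses each cell as a percentage of the whole sequence, so the cells
#' of one class sum to that class's total content across segments;
#' `"segment"` expresses each cell as a percentage of its own segment.
#'
#' @param assignments Per-residue labels over the sequence span: a single
#'   string or character vector of `H`/`E`/`C`, position 1 = first residue
#'   of the span.
#' @param scheme An `xl_scheme`; content is tabulated for its subunit-level
#'   segments plus a `Total` row.
#' @param convention `"total"` or `"segment"` (see above).
#' @param digits Rounding of reported percentages.
#' @return Tibble with columns segment, helix, strand, coil, and a row_sum
#'   consistency column under the `"total"` convention (cells of one row
#'   sum to the segment's share of the sequence).
#' @export
ss_content <- function(assignments, scheme,
                       convention = c("total", "segment"), digits = 1) {
  convention <- match.arg(convention)
  if (length(assignments) == 1L && nchar(assignments[1]) > 1L) {
    assignments <- strsplit(assignments, "")[[1]]
  }
  span_len <- scheme$span[2] - scheme$span[1] + 1L
  if (length(assignments) != span_len) {
    abort(sprintf("Expected %d per-residue labels for span [%d, %d], got %d.",
                  span_len, scheme$span[1], scheme$span[2], length(assignments)),
          class = "xlinkr_input_error")
  }
  bad <- which(!assignments %in% c("H", "E", "C"))
  if (length(bad)) {
    abort(sprintf("Unlabeled or unknown residues at span positions: %s",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "xlinkr_input_error")
  }
  subunits <- unique(scheme$segments$segment[scheme$segments$level == "subunit"])
  rows <- purrr::map_dfr(subunits, function(seg) {
    idx <- segment_residues(scheme, seg) - scheme$span[1] + 1L
    lab <- assignments[idx]
    denom <- if (convention == "total") span_len else length(lab)
    tibble(segment = seg,
           helix = round(100 * sum(lab == "H") / denom, digits),
           strand = round(100 * sum(lab == "E") / denom, digits),
           coil = round(100 * sum(lab == "C") / denom, digits))
  })
  total <- tibble(segment = "Total",
                  helix = round(100 * sum(assignments == "H") / span_len, digits),
                  strand = round(100 * sum(assignments == "E") / span_len, digits),
                  coil = round(100 * sum(assignments == "C") / span_len, digits))
  out <- dplyr::bind_rows(rows, total)
  if (convention == "total") {
    out$row_sum <- round(out$helix + out$strand + out$coil, digits)
  }
  out
}

#' Aggregate a per-segment secondary-structure table
#'
#' Sums percentage-of-total-content cells per class (the column sums give
#' the whole protein's helix/strand/coil content) and emits a row-sum
#' consistency check (all cells should add up to ~100).
#'
#' @param ss_table Tibble with columns `segment`, `helix`, `strand`, `coil`
#'   where each cell is a percentage of the whole sequence.
#' @return One-row tibble with `helix`, `strand`, `coil` totals and
#'   `grand_total`.
#' @export
ss_aggregate <- function(ss_table) {
  ss_table <- as_tibble(ss_table)
  needed <- c("helix", "strand", "coil")
  if (!all(needed %in% names(ss_table))) {
    abort("ss_table needs helix, strand and coil columns.",
          class = "xlinkr_input_error")
  }
  tibble(helix = sum(ss_table$helix),
         strand = sum(ss_table$strand),
         coil = sum(ss_table$coil),
         grand_total = sum(ss_table$helix + ss_table$strand + ss_table$coil))
}

#' Consensus domain boundaries from sliding-window predictions
#'
#' Domain-boundary predictors run on overlapping sequence windows each
#' propose boundary positions; this clusters the proposals across windows
#' (single linkage, link distance <= `tolerance`) and keeps clusters backed
#' by enough distinct windows. A cluster's support requirement is capped at
#' the number of windows actually covering its position, so boundaries near
#' the span edges (seen by a single window) are not penalized. The reported
#' representative is the rounded median of the cluster.
#'
#' @param predictions Tibble with columns `window_start`, `window_end`,
#'   `boundary` (one row per predicted boundary; boundaries lie strictly
#'   inside their window).
#' @param tolerance Positions within this many residues cluster together
#'   (default 10).
#' @param min_support Minimum number of distinct supporting windows
#'   (default 2, capped by coverage).
#' @return Tibble with `boundary`, `support`, `n_covering`.
#' @export
consensus_boundaries <- function(predictions, tolerance = 10, min_support = 2) {
  predictions <- as_tibble(predictions)
  if (nrow(predictions) == 0L) {
    return(tibble(boundary = integer(), support = integer(),
                  n_covering = integer()))
  }
  needed <- c("window_start", "window_end", "boundary")
  if (!all(needed %in% names(predictions))) {
    abort(paste("Predictions need columns:", paste(needed, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  check_number(tolerance, "tolerance", min = 0)
  check_number(min_support, "min_support", min = 1)
  inside <- predictions$boundary > predictions$window_start &
    predictions$boundary < predictions$window_end
  if (!all(inside)) {
    abort("Boundaries must lie strictly inside their window.",
          class = "xlinkr_range_error")
  }
  p <- predictions[order(predictions$boundary), , drop = FALSE]
  # 1-D single linkage: a gap > tolerance splits clusters
  gap <- c(0, diff(p$boundary))
  cluster <- cumsum(gap > tolerance)
  windows <- dplyr::distinct(predictions[, c("window_start", "window_end")])
  out <- purrr::map_dfr(split(p, cluster), function(cl) {
    rep_pos <- as.integer(round(median(cl$boundary)))
    support <- nrow(dplyr::distinct(cl[, c("window_start", "window_end")]))
    n_cov <- sum(windows$window_start < rep_pos & rep_pos < windows$window_end)
    tibble(boundary = rep_pos, support = support, n_covering = n_cov)
  })
  out <- out[out$support >= pmin(min_support, pmax(out$n_covering, 1L)), ,
             drop = FALSE]
  out[order(out$boundary), ]
}
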