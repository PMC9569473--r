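#' Summarize restraint evaluations into a validation report
#'
#' Tallies satisfied / marginal / violated / unmeasurable restraints, the
#' percent within threshold (of those measured), per-segment and
#' per-topology breakdowns when a segmentation scheme is supplied, a
#' fixed-width distance histogram, and a deterministically ordered list of
#' violations (distance descending, then residue index).
#'
#' @param evaluations Evaluation tibble from [evaluate_crosslinks()] /
#'   [evaluate_disulfides()].
#' @param scheme Optional `xl_scheme` for per-segment/topology breakdowns.
#' @param bin_width Histogram bin width in Angstrom (right-open bins from 0).
#' @return An `xl_report` object; see [glance.xl_report()] for the one-row
#'   totals and [tidy.xl_report()] for the per-restraint table.
#' @examples
#' ev <- tibble::tibble(id = "a", res_a = 1L, res_b = 9L, distance = 12,
#'                      category = classify_distance(12),
#'                      atom_a = "CA", atom_b = "CA",
#'                      threshold = 26, grace = 30)
#' glance(summarize_restraints(ev))
#' @export
summarize_restraints <- function(evaluations, scheme = NULL, bin_width = 2) {
  ev <- as_tibble(evaluations)
  if (nrow(ev) && !is.null(scheme)) {
    ev <- classify_topology(scheme, ev)
    loc_a <- locate_residue(scheme, ev$res_a)
    loc_b <- locate_residue(scheme, ev$res_b)
    ev$subunit_a <- loc_a$subunit
    ev$subunit_b <- loc_b$subunit
  }
  n_identified <- nrow(ev)
  counts <- table(factor(ev$category, levels = restraint_categories))
  n_measured <- n_identified - counts[["unmeasurable"]]
  percent <- if (n_measured > 0) 100 * counts[["satisfied"]] / n_measured else 0

  measured <- ev[!is.na(ev$distance), , drop = FALSE]
  histogram <- if (nrow(measured)) {
    bin <- floor(measured$distance / bin_width)
    tab <- table(bin)
    tibble(bin_start = as.numeric(names(tab)) * bin_width,
           bin_end = (as.numeric(names(tab)) + 1) * bin_width,
           n = as.integer(tab))
  } else {
    tibble(bin_start = numeric(), bin_end = numeric(), n = integer())
  }

  viol <- measured[measured$category %in% c("marginal", "violated"), , drop = FALSE]
  viol <- viol[order(-viol$distance, viol$res_a, viol$res_b), , drop = FALSE]

  per_segment <- NULL
  per_topology <- NULL
  if (!is.null(scheme) && nrow(ev)) {
    by_sub <- dplyr::bind_rows(
      tibble(subunit = ev$subunit_a, category = ev$category, id = ev$id),
      tibble(subunit = ev$subunit_b, category = ev$category, id = ev$id)
    )
    by_sub <- dplyr::distinct(by_sub, .data$subunit, .data$id,
                              .keep_all = TRUE)
    per_segment <- by_sub |>
      dplyr::filter(!is.na(.data$subunit)) |>
      dplyr::count(.data$subunit, .data$category, .drop = FALSE) |>
      tidyr::pivot_wider(names_from = "category", values_from = "n",
                         values_fill = 0L)
    per_topology <- ev |>
      dplyr::filter(.data$category != "unmeasurable") |>
      dplyr::count(.data$topology, .drop = FALSE)
  }

  structure(list(
    n_identified = n_identified,
    n_measured = as.integer(n_measured),
    n_satisfied = counts[["satisfied"]],
    n_marginal = counts[["marginal"]],
    n_violated = counts[["violated"]],
    n_unmeasurable = counts[["unmeasurable"]],
    percent_within_threshold = percent,
    per_segment = per_segment,
    per_topology = per_topology,
    histogram = histogram,
    violations = viol,
    evaluations = ev,
    bin_width = bin_width
  ), class = "xl_report")
}

#' @export
print.xl_report <- function(x, ...) {
  cat(sprintf(
    "<xl_report> %d identified, %d measured: %d satisfied (%.1f%%), %d marginal, %d violated\n",
    x$n_identified, x$n_measured, x$n_satisfied,
    x$percent_within_threshold, x$n_marginal, x$n_violated))
  if (nrow(x$violations)) {
    cat("worst restraints:\n")
    print(utils::head(x$violations[, c("id", "distance", "category")], 5))
  }
  invisible(x)
}

#' One-row summary of a validation report
#'
#' @param x An `xl_report`.
#' @param ... Unused.
#' @return A one-row tibble of the totals.
#' @export
glance.xl_report <- function(x, ...) {
  tibble(n_identified = x$n_identified, n_measured = x$n_measured,
         n_satisfied = x$n_satisfied, n_marginal = x$n_marginal,
         n_violated = x$n_violated, n_unmeasurable = x$n_unmeasurable,
         percent_within_threshold = x$percent_within_threshold)
}

#' Per-restraint table of a validation report
#'
#' @param x An `xl_report`.
#' @param ... Unused.
#' @return The evaluation tibble (with topology columns when a scheme was
#'   supplied).
#' @export
tidy.xl_report <- function(x, ...) {
  x$evaluations
}

#' Write a validation report to JSON
#'
#' Field order is fixed so reports diff cleanly.
#'
#' @param report An `xl_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    n_identified = report$n_identified,
    n_measured = report$n_measured,
    n_satisfied = report$n_satisfied,
    n_marginal = report$n_marginal,
    n_violated = report$n_violated,
    n_unmeasurable = report$n_unmeasurable,
    percent_within_threshold = report$percent_within_threshold,
    histogram = report$histogram,
    violations = report$violations[, intersect(
      c("id", "res_a", "res_b", "distance", "category"),
      names(report$violations))]
  )
  if (!is.null(report$per_segment)) out$per_segment <- report$per_segment
  if (!is.null(report$per_topology)) out$per_topology <- report$per_topology
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", factor = "string")
  invisible(path)
}

#' Distance-distribution plot of restraint evaluations
#'
#' Histogram of measured restraint distances in fixed-width bins with the
#' satisfaction threshold and marginal bound drawn as vertical lines.
#'
#' @param evaluations Evaluation tibble, or an `xl_report`.
#' @param bin_width Bin width in Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(evaluations, bin_width = 2) {
  if (inherits(evaluations, "xl_report")) {
    bin_width <- evaluations$bin_width
    evaluations <- evaluations$evaluations
  }
  ev <- evaluations[!is.na(evaluations$distance), , drop = FALSE]
  thr <- ev$threshold[1]
  grc <- ev$grace[1]
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$distance, fill = .data$category)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            closed = "left", color = "grey30") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = grc, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(satisfied = "#4477AA",
                                          marginal = "#EE9944",
                                          violated = "#CC3311",
                                          unmeasurable = "grey70"),
                               drop = FALSE) +
    ggplot2::labs(x = "Cα-Cα distance (Å)", y = "cross-links",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_distribution
#' @param object An `xl_report`.
#' @param ... Unused.
#' @export
autoplot.xl_report <- function(object, ...) {
  plot_distance_distribution(object)
}
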