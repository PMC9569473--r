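#' Read a cross-link TSV
#'
#' Expected columns: `id`, `res_a`, `res_b`, `linker`, optionally `n_csms`
#' and `score`; header required; residue numbers are 1-based full-sequence
#' (preproprotein) numbering. Pairs are canonicalized and deduplicated so
#' the returned rows are unique cross-links.
#'
#' @param path TSV file path.
#' @return Tibble of unique cross-links.
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  known <- c("id", "res_a", "res_b", "linker", "n_csms", "score")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    abort(sprintf("Unknown column(s) in %s: %s (expected %s).",
                  path, paste(unknown, collapse = ", "),
                  paste(known, collapse = ", ")),
          class = "xlinkr_io_error")
  }
  if (!all(c("res_a", "res_b") %in% names(df))) {
    abort(sprintf("%s must have `res_a` and `res_b` columns.", path),
          class = "xlinkr_io_error")
  }
  for (col in c("res_a", "res_b")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (nrow(df) && anyNA(v)) {
      abort(sprintf("Non-integer residue number in column `%s` of %s (row %d).",
                    col, path, which(is.na(v))[1]),
            class = "xlinkr_io_error")
    }
    df[[col]] <- v
  }
  if (nrow(df) == 0L) {
    return(tibble(id = character(), res_a = integer(), res_b = integer()))
  }
  canonicalize_links(df)
}

#' Write a cross-link TSV
#'
#' @param links Cross-link tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  links <- canonicalize_links(links)
  keep <- intersect(c("id", "res_a", "res_b", "linker", "n_csms", "score"),
                    names(links))
  utils::write.table(links[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segmentation scheme from YAML or JSON
#'
#' The file lists the sequence span, segments with their level and ranges,
#' optionally `unmodeled` ranges (converted to a coverage mask) and an
#' `ss_table` of secondary-structure content percentages.
#'
#' @param path Scheme file (`.yaml`/`.yml` or `.json`).
#' @return An `xl_scheme`.
#' @export
read_scheme <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(raw$span) || is.null(raw$segments)) {
    abort(sprintf("Scheme file %s must define `span` and `segments`.", path),
          class = "xlinkr_io_error")
  }
  names_seen <- vapply(raw$segments, function(s) s$segment, character(1))
  if (anyDuplicated(names_seen)) {
    abort(sprintf("Duplicate segment name in %s: '%s'.",
                  path, names_seen[duplicated(names_seen)][1]),
          class = "xlinkr_io_error")
  }
  segments <- purrr::map_dfr(raw$segments, function(s) {
    rng <- purrr::map(s$ranges, unlist)
    tibble(segment = s$segment, level = s$level,
           start = vapply(rng, function(r) as.integer(r[1]), integer(1)),
           end = vapply(rng, function(r) as.integer(r[2]), integer(1)))
  })
  span <- as.integer(unlist(raw$span))
  coverage <- NULL
  if (!is.null(raw$unmodeled)) {
    excl <- unlist(purrr::map(raw$unmodeled, function(r) {
      r <- as.integer(unlist(r)); seq.int(r[1], r[2])
    }))
    coverage <- setdiff(seq.int(span[1], span[2]), excl)
  }
  scheme <- new_scheme(segments, span, coverage)
  if (!is.null(raw$ss_table)) {
    scheme$ss_table <- purrr::map_dfr(raw$ss_table, as_tibble)
  }
  scheme$name <- raw$name
  scheme
}

#' Write a segmentation scheme to YAML or JSON
#'
#' @param scheme An `xl_scheme`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  segs <- split(scheme$segments, factor(scheme$segments$segment,
                                        levels = unique(scheme$segments$segment)))
  out <- list(
    name = scheme$name %||% "scheme",
    span = as.list(scheme$span),
    segments = purrr::map(segs, function(s) {
      list(segment = s$segment[1], level = s$level[1],
           ranges = purrr::map2(s$start, s$end, function(a, b) list(a, b)))
    })
  )
  names(out$segments) <- NULL
  if (!is.null(scheme$coverage)) {
    full <- seq.int(scheme$span[1], scheme$span[2])
    excl <- setdiff(full, scheme$coverage)
    if (length(excl)) {
      brk <- c(0, which(diff(excl) != 1), length(excl))
      out$unmodeled <- purrr::map(seq_len(length(brk) - 1), function(i) {
        list(excl[brk[i] + 1], excl[brk[i + 1]])
      })
    }
  }
  if (!is.null(scheme$ss_table)) {
    out$ss_table <- purrr::transpose(as.list(scheme$ss_table))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Export evaluations as pseudobond lines for molecular viewers
#'
#' One line per measurable restraint:
#' `/<chain>:<res_a>@CA /<chain>:<res_b>@CA <color>` with the color encoding
#' the category (satisfied blue, marginal orange, violated red).
#'
#' @param evaluations Evaluation tibble (see [evaluate_crosslinks()]).
#' @param path Output path.
#' @param chain Chain identifier used in the atom specs.
#' @param colors Named character vector mapping categories to colors.
#' @return `path`, invisibly.
#' @export
write_pseudobonds <- function(evaluations, path, chain = "A",
                              colors = c(satisfied = "cornflower blue",
                                         marginal = "orange",
                                         violated = "red")) {
  ev <- evaluations[evaluations$category != "unmeasurable", , drop = FALSE]
  lines <- sprintf("/%s:%d@%s /%s:%d@%s %s",
                   chain, ev$res_a, ev$atom_a,
                   chain, ev$res_b, ev$atom_b,
                   unname(colors[as.character(ev$category)]))
  writeLines(lines, path)
  invisible(path)
}
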