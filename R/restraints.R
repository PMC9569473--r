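#' Canonicalize a cross-link table
#'
#' Orders every residue pair as (min, max), drops self-links, and collapses
#' duplicates so counts refer to unique cross-links. Numbering is 1-based
#' full-sequence (preproprotein) throughout.
#'
#' @param links A data frame with columns `res_a`, `res_b` and optionally
#'   `id`, `linker` and any extras.
#' @return A tibble of unique canonical links.
#' @export
canonicalize_links <- function(links) {
  links <- as_tibble(links)
  if (!all(c("res_a", "res_b") %in% names(links))) {
    abort("Links need `res_a` and `res_b` columns.", class = "xlinkr_input_error")
  }
  links$res_a <- as.integer(links$res_a)
  links$res_b <- as.integer(links$res_b)
  lo <- pmin(links$res_a, links$res_b)
  hi <- pmax(links$res_a, links$res_b)
  links$res_a <- lo
  links$res_b <- hi
  links <- links[links$res_a != links$res_b, , drop = FALSE]
  links <- links[!duplicated(paste(links$res_a, links$res_b)), , drop = FALSE]
  if (!"id" %in% names(links)) {
    links$id <- sprintf("K%d-K%d", links$res_a, links$res_b)
  }
  dplyr::relocate(links, "id", "res_a", "res_b")
}

#' Classify a measured distance against threshold and grace bands
#'
#' A distance `d <= threshold` is satisfied; `threshold < d <= grace` is
#' marginal ("slightly beyond the limit"); `d > grace` is violated. `NA`
#' distances are unmeasurable. Both bounds are closed on the upper side.
#'
#' @param d Numeric vector of distances (Angstrom); `NA` allowed.
#' @param threshold Satisfaction bound (default the DSSO reported 26 A).
#' @param grace Upper bound of the marginal band (default 30 A).
#' @return Factor with levels satisfied, marginal, violated, unmeasurable.
#' @examples
#' classify_distance(c(24, 26.9, 42.5, NA))
#' @export
classify_distance <- function(d, threshold = 26, grace = 30) {
  check_number(threshold, "threshold", min = 0)
  check_number(grace, "grace", min = threshold)
  if (any(d < 0, na.rm = TRUE)) {
    abort("Distances must be non-negative.", class = "xlinkr_input_error")
  }
  out <- ifelse(is.na(d), "unmeasurable",
                ifelse(d <= threshold, "satisfied",
                       ifelse(d <= grace, "marginal", "violated")))
  factor(out, levels = c("satisfied", "marginal", "violated", "unmeasurable"))
}

restraint_categories <- c("satisfied", "marginal", "violated", "unmeasurable")

#' Evaluate cross-link restraints against a structural model
#'
#' Measures the Calpha-Calpha distance of every unique link and classifies
#' it. Endpoints falling outside the model (or in residues masked as
#' unmodeled by `coverage`) give unmeasurable evaluations, never errors:
#' a link can be identified by MS yet not measurable on a partial model.
#'
#' @param structure Atom table covering the modeled residues (may be the
#'   row-bound union of several placed segments).
#' @param links Cross-link table (canonicalized internally).
#' @param linker A [linker_chemistry()] used to derive the threshold, or
#'   `NULL` to use `threshold` as given.
#' @param threshold,grace Distance bands in Angstrom; by default the
#'   linker's reported threshold and a 30 A marginal bound.
#' @param coverage Optional integer vector of modeled residue numbers; links
#'   touching residues outside it are unmeasurable. Defaults to the residues
#'   present in `structure`.
#' @param sequence_span Optional `c(first, last)` bounds; link endpoints
#'   outside it are an error (they cannot exist in the protein).
#' @param atom_name Atom used for measuring, default `"CA"`.
#' @param use_raw If `TRUE` compare against the raw (unrounded) linker sum.
#' @return A tibble of evaluations: id, res_a, res_b, distance, category,
#'   atom_a, atom_b, threshold, grace.
#' @export
evaluate_crosslinks <- function(structure, links, linker = linker_dsso(),
                                threshold = NULL, grace = 30,
                                coverage = NULL, sequence_span = NULL,
                                atom_name = "CA", use_raw = FALSE) {
  links <- canonicalize_links(links)
  if (is.null(threshold)) {
    if (is.null(linker)) abort("Give either `linker` or `threshold`.",
                               class = "xlinkr_input_error")
    thr <- max_ca_distance(linker, "K", "K")
    threshold <- if (use_raw) thr$raw else thr$reported
  }
  if (!is.null(sequence_span)) {
    bad <- links$res_a < sequence_span[1] | links$res_b > sequence_span[2]
    if (any(bad)) {
      abort(sprintf("Link %s has an endpoint outside the sequence span [%d, %d].",
                    links$id[which(bad)[1]], sequence_span[1], sequence_span[2]),
            class = "xlinkr_range_error")
    }
  }
  if (nrow(links) == 0L) {
    return(tibble(id = character(), res_a = integer(), res_b = integer(),
                  distance = numeric(),
                  category = factor(character(), levels = restraint_categories),
                  atom_a = character(), atom_b = character(),
                  threshold = numeric(), grace = numeric()))
  }
  structure <- as_structure(structure)
  if (is.null(coverage)) coverage <- unique(structure$resno)
  d <- purrr::map2_dbl(links$res_a, links$res_b, function(a, b) {
    if (!(a %in% coverage) || !(b %in% coverage)) return(NA_real_)
    measure_distance(structure, a, b, atom_name)
  })
  tibble(
    id = links$id, res_a = links$res_a, res_b = links$res_b,
    distance = d,
    category = classify_distance(d, threshold, grace),
    atom_a = atom_name, atom_b = atom_name,
    threshold = threshold, grace = grace
  )
}

#' Evaluate disulfide restraints
#'
#' A disulfide is satisfied when the two cysteine sulfurs lie within
#' `max_ss_distance` (default 5.6 A). On Calpha-only models (no SG atoms)
#' the Calpha-Calpha distance is used instead with a wider default bound
#' (7.5 A) and the evaluation is flagged `fallback`.
#'
#' @param structure Atom table.
#' @param pairs Data frame with columns `cys_a`, `cys_b` and optionally
#'   `max_ss_distance`.
#' @param max_ss_distance Default S-S bound, Angstrom.
#' @param ca_fallback_distance Bound used when falling back to Calpha.
#' @return Tibble of evaluations with a `fallback` flag; categories are
#'   satisfied/violated/unmeasurable (no marginal band for bonds).
#' @export
evaluate_disulfides <- function(structure, pairs, max_ss_distance = 5.6,
                                ca_fallback_distance = 7.5) {
  structure <- as_structure(structure)
  pairs <- as_tibble(pairs)
  if (!all(c("cys_a", "cys_b") %in% names(pairs))) {
    abort("Disulfide pairs need `cys_a` and `cys_b` columns.",
          class = "xlinkr_input_error")
  }
  if (!"max_ss_distance" %in% names(pairs)) pairs$max_ss_distance <- max_ss_distance
  check_number(max_ss_distance, "max_ss_distance", min = 1e-9)
  purrr::pmap_dfr(pairs, function(cys_a, cys_b, max_ss_distance, ...) {
    for (res in c(cys_a, cys_b)) {
      rn <- unique(structure$resname[structure$resno == res])
      if (length(rn) && !any(rn %in% "CYS")) {
        abort(sprintf("Residue %d is %s, not CYS; cannot evaluate a disulfide.",
                      res, rn[1]),
              class = "xlinkr_residue_error")
      }
    }
    d <- measure_distance(structure, cys_a, cys_b, "SG")
    fallback <- FALSE
    bound <- max_ss_distance
    if (is.na(d)) {
      d_ca <- measure_distance(structure, cys_a, cys_b, "CA")
      if (!is.na(d_ca)) {
        d <- d_ca
        fallback <- TRUE
        bound <- ca_fallback_distance
      }
    }
    category <- if (is.na(d)) "unmeasurable" else if (d <= bound) "satisfied" else "violated"
    tibble(id = sprintf("C%d-C%d", cys_a, cys_b),
           res_a = as.integer(cys_a), res_b = as.integer(cys_b),
           distance = d,
           category = factor(category, levels = restraint_categories),
           atom_a = if (fallback) "CA" else "SG",
           atom_b = if (fallback) "CA" else "SG",
           threshold = bound, grace = bound, fallback = fallback)
  })
}
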