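#' Paint-positive (surface-exposed) regions from differential peptide detection
#'
#' Protein painting compares tryptic peptides from dye-treated ("painted")
#' and untreated samples: a covalently painted surface region resists
#' digestion, so its peptides disappear from painted samples. A peptide is
#' paint-positive iff it is present in *all* unpainted replicates and
#' absent in *all* painted replicates; the merged residue ranges of
#' paint-positive peptides are the exposed regions.
#'
#' @param observations Tibble with columns `peptide`, `start`, `end`
#'   (1-based inclusive), `replicate`, `condition` (`painted`/`unpainted`);
#'   one row per detection.
#' @param sequence Optional protein sequence; when given, each peptide is
#'   checked against the sequence at its coordinates.
#' @param n_replicates Expected replicates per condition (default 3).
#' @return Tibble of merged exposed ranges (`start`, `end`).
#' @export
paint_regions <- function(observations, sequence = NULL, n_replicates = 3) {
  obs <- as_tibble(observations)
  needed <- c("peptide", "start", "end", "replicate", "condition")
  if (!all(needed %in% names(obs))) {
    abort(paste("Observations need columns:", paste(needed, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  bad_cond <- setdiff(unique(obs$condition), c("painted", "unpainted"))
  if (length(bad_cond)) {
    abort(paste("Unknown condition(s):", paste(bad_cond, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  for (cond in c("painted", "unpainted")) {
    reps <- unique(obs$replicate[obs$condition == cond])
    if (length(reps) > n_replicates) {
      abort(sprintf("Condition '%s' has %d replicates but n_replicates = %d.",
                    cond, length(reps), n_replicates),
            class = "xlinkr_input_error")
    }
  }
  if (!is.null(sequence)) {
    sub <- substring(sequence, obs$start, obs$end)
    bad <- which(sub != obs$peptide)
    if (length(bad)) {
      abort(sprintf("Peptide '%s' does not match the sequence at [%d, %d].",
                    obs$peptide[bad[1]], obs$start[bad[1]], obs$end[bad[1]]),
            class = "xlinkr_input_error")
    }
  }
  key <- paste(obs$peptide, obs$start, obs$end)
  pep <- dplyr::distinct(tibble(key = key, peptide = obs$peptide,
                                start = obs$start, end = obs$end))
  n_unp <- vapply(pep$key, function(k) {
    length(unique(obs$replicate[key == k & obs$condition == "unpainted"]))
  }, integer(1))
  n_pnt <- vapply(pep$key, function(k) {
    length(unique(obs$replicate[key == k & obs$condition == "painted"]))
  }, integer(1))
  positive <- pep[n_unp == n_replicates & n_pnt == 0L, , drop = FALSE]
  merge_ranges(positive[, c("start", "end")])
}

# union of inclusive integer ranges
merge_ranges <- function(ranges) {
  ranges <- as_tibble(ranges)
  if (nrow(ranges) == 0L) return(tibble(start = integer(), end = integer()))
  ranges <- ranges[order(ranges$start, ranges$end), ]
  out_start <- ranges$start[1]
  out_end <- ranges$end[1]
  starts <- ends <- integer()
  for (i in seq_len(nrow(ranges))[-1]) {
    if (ranges$start[i] <= out_end + 1L) {
      out_end <- max(out_end, ranges$end[i])
    } else {
      starts <- c(starts, out_start)
      ends <- c(ends, out_end)
      out_start <- ranges$start[i]
      out_end <- ranges$end[i]
    }
  }
  tibble(start = as.integer(c(starts, out_start)),
         end = as.integer(c(ends, out_end)))
}

#' Concordance of hydrolyzed mono-link sites with painted regions
#'
#' Hydrolyzed (dead-end) cross-linker sites mark solvent-exposed lysines;
#' this reports what fraction of them fall inside the paint-positive
#' ranges. With no sites the fraction is undefined (`NA`).
#'
#' @param monolink_residues Integer vector of mono-link residue positions.
#' @param painted_ranges Tibble of ranges (`start`, `end`).
#' @return Fraction in `[0, 1]`, or `NA_real_` when there are no sites.
#' @export
monolink_concordance <- function(monolink_residues, painted_ranges) {
  sites <- unique(as.integer(monolink_residues))
  if (length(sites) == 0L) return(NA_real_)
  ranges <- as_tibble(painted_ranges)
  inside <- vapply(sites, function(r) {
    any(r >= ranges$start & r <= ranges$end)
  }, logical(1))
  mean(inside)
}

#' Read / write painting observation tables and exposed-range files
#'
#' Observations travel as TSV (`peptide`, `start`, `end`, `replicate`,
#' `condition`); exposed ranges as a 3-column name/start/end text file
#' (1-based inclusive coordinates).
#'
#' @param path File path.
#' @return `read_observations()`: observation tibble.
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

#' @rdname read_observations
#' @param observations Observation tibble.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_observations
#' @param ranges Range tibble (`start`, `end`).
#' @param name Region name written in column 1.
#' @export
write_ranges <- function(ranges, path, name = "painted") {
  df <- data.frame(name = name, start = ranges$start, end = ranges$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
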