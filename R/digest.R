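#' In-silico trypsin digestion
#'
#' Cleaves after K or R except when the next residue is P, enumerates
#' peptides with up to `missed_cleavages` internal sites, and filters by
#' length. Defaults mirror typical cross-linking search settings (up to 3
#' missed cleavages, minimum peptide length 5).
#'
#' @param sequence Protein sequence (one-letter codes, single string).
#' @param enzyme Only `"trypsin"` is implemented.
#' @param missed_cleavages Maximum internal missed cleavage sites.
#' @param min_len,max_len Peptide length filter (inclusive).
#' @param on_nonstandard `"error"` (default) or `"keep"`: what to do with
#'   residues outside the 20 standard codes.
#' @return Tibble with `peptide`, `start`, `end` (1-based inclusive) and
#'   `n_missed`.
#' @examples
#' digest("AKRPGK", missed_cleavages = 0, min_len = 1)
#' @export
digest <- function(sequence, enzyme = "trypsin", missed_cleavages = 3,
                   min_len = 5, max_len = Inf,
                   on_nonstandard = c("error", "keep")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (!identical(enzyme, "trypsin")) {
    abort(sprintf("Enzyme '%s' is not implemented (only trypsin).", enzyme),
          class = "xlinkr_input_error")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (on_nonstandard == "error") {
    bad <- which(!aa %in% standard)
    if (length(bad)) {
      abort(sprintf("Non-standard residue '%s' at position %d.",
                    aa[bad[1]], bad[1]),
            class = "xlinkr_residue_error")
    }
  }
  n <- length(aa)
  # cleavage after position i: K/R not followed by P
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n & aa[sites + 1] != "P"]
  bounds <- c(0L, sites, n)            # fragment i spans (bounds[i]+1):bounds[i+1]
  n_frag <- length(bounds) - 1L
  out <- purrr::map_dfr(seq_len(n_frag), function(i) {
    j_max <- min(n_frag, i + missed_cleavages)
    purrr::map_dfr(i:j_max, function(j) {
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      tibble(peptide = paste(aa[start:end], collapse = ""),
             start = start, end = end, n_missed = j - i)
    })
  })
  out <- out[(out$end - out$start + 1L) >= min_len &
               (out$end - out$start + 1L) <= max_len, , drop = FALSE]
  out[order(out$start, out$end), ]
}
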