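## steric clash counting between rigid bodies

# cell-list grid over one body's coordinates; cell edge = cutoff so any
# pair within cutoff shares adjacent cells
grid_build <- function(xyz, cutoff) {
  cell <- floor(xyz / cutoff)
  base <- 4096           # coordinates within +-2e6/cutoff A, ample
  code <- (cell[, 1] + 2048) + base * ((cell[, 2] + 2048) +
                                         base * (cell[, 3] + 2048))
  list(groups = split(seq_len(nrow(xyz)), code), xyz = xyz,
       cutoff = cutoff, base = base)
}

grid_count <- function(grid, xyz_query, cutoff) {
  stopifnot(abs(cutoff - grid$cutoff) < 1e-12)
  cell <- floor(xyz_query / cutoff)
  base <- grid$base
  cut2 <- cutoff^2
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  total <- 0L
  for (k in seq_len(27)) {
    code <- (cell[, 1] + offsets[k, 1] + 2048) +
      base * ((cell[, 2] + offsets[k, 2] + 2048) +
                base * (cell[, 3] + offsets[k, 3] + 2048))
    hit <- grid$groups[as.character(code)]
    has <- !vapply(hit, is.null, logical(1))
    if (!any(has)) next
    qi <- which(has)
    cand <- hit[qi]
    ni <- lengths(cand)
    q_idx <- rep(qi, ni)
    b_idx <- unlist(cand, use.names = FALSE)
    d2 <- rowSums((xyz_query[q_idx, , drop = FALSE] -
                     grid$xyz[b_idx, , drop = FALSE])^2)
    total <- total + sum(d2 < cut2)
  }
  total
}

#' Count steric clashes between two rigid bodies
#'
#' Number of inter-body atom pairs closer than `cutoff` (default 4 A,
#' appropriate for Calpha-Calpha contacts between different rigid bodies).
#' The default spatial-grid method is exactly equivalent to the brute-force
#' all-pairs scan, just faster.
#'
#' @param structure_a,structure_b Atom tables (or bare xyz matrices).
#' @param cutoff Clash distance in Angstrom (> 0).
#' @param method `"grid"` (cell lists) or `"brute"` (all pairs).
#' @return Integer clash count.
#' @export
clash_count <- function(structure_a, structure_b, cutoff = 4,
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  check_number(cutoff, "cutoff", min = 1e-12)
  xa <- if (is.matrix(structure_a)) structure_a else coords(as_structure(structure_a))
  xb <- if (is.matrix(structure_b)) structure_b else coords(as_structure(structure_b))
  if (nrow(xa) == 0L || nrow(xb) == 0L) return(0L)
  if (method == "brute") {
    return(sum(cross_sqdist(xa, xb) < cutoff^2))
  }
  as.integer(grid_count(grid_build(xb, cutoff), xa, cutoff))
}
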