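## solvent accessible surface area (sphere-point sampling)

# element van der Waals radii (A); CA pseudo-atom radius for Calpha-only
# traces is handled in sasa()
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# theoretical maximum accessible areas per residue (A^2), tripeptide
# standard, used for relative accessibility
max_residue_area <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area per residue
#'
#' Sphere-point (Shrake-Rupley style) accessible surface: each atom is
#' inflated by the probe radius, sampled with a deterministic spiral of
#' `n_points`, and the fraction of points not buried in any neighboring
#' inflated atom becomes its accessible area. Areas are summed per residue
#' and a relative accessibility against per-residue reference maxima is
#' reported (clipped to [0, 1.2]; values above the reference are flagged).
#'
#' Calpha-only traces carry no side chains, so their atoms get an enlarged
#' pseudo-atom radius (`ca_only_radius`) to stand in for the residue body.
#'
#' @param structure Atom table.
#' @param probe_radius Solvent probe radius, default 1.4 A (water).
#' @param n_points Sphere sample points per atom, default 960.
#' @param ca_only_radius Pseudo-atom radius used when the structure
#'   contains only CA atoms, default 3.0 A.
#' @return Tibble per residue: `chain`, `resno`, `resname`, `area`
#'   (absolute, A^2), `relative` (vs reference maxima, `NA` for unknown
#'   residue types), `over_reference` flag.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 ca_only_radius = 3.0) {
  s <- as_structure(structure)
  check_number(probe_radius, "probe_radius", min = 0)
  check_number(n_points, "n_points", min = 1)
  ca_only <- all(s$atom == "CA")
  radii <- if (ca_only) {
    rep(ca_only_radius, nrow(s))
  } else {
    r <- vdw_radii[s$element]
    r[is.na(r)] <- 1.70
    unname(r)
  }
  radii <- radii + probe_radius
  xyz <- coords(s)
  pts <- sphere_points(n_points)
  n <- nrow(s)
  area <- numeric(n)
  # neighbor search: atoms whose inflated spheres can intersect
  maxr <- max(radii)
  d2 <- cross_sqdist(xyz, xyz)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    surf <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(neigh)) {
      buried <- rep(FALSE, n_points)
      for (j in neigh) {
        if (all(buried)) break
        dj <- rowSums(sweep(surf, 2, xyz[j, ])^2)
        buried <- buried | dj < radii[j]^2
      }
      frac <- mean(!buried)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * radii[i]^2 * frac
  }
  out <- tibble(chain = s$chain, resno = s$resno, resname = s$resname,
                area = area) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
  ref <- max_residue_area[out$resname]
  rel_raw <- out$area / unname(ref)
  out$relative <- pmin(pmax(rel_raw, 0), 1.2)
  out$over_reference <- !is.na(rel_raw) & rel_raw > 1
  out
}
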