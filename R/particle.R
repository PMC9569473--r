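#' Simplified lipoprotein particle geometries
#'
#' Particles are modeled as a sphere (e.g. a 30 nm VLDL) or a discoid
#' (e.g. a 20 x 20 x 11 nm LDL): an elliptical disc with a rounded rim,
#' i.e. the surface at constant distance `dz/2` from the flat ellipse with
#' semi-axes `dx/2 - dz/2` and `dy/2 - dz/2`, which reproduces the stated
#' bounding dimensions. A shell of thickness `inner_t` inward and
#' `outer_t` outward around the surface is where surface-bound protein is
#' expected to sit.
#'
#' @param diameter Sphere diameter, Angstrom.
#' @param inner_t,outer_t Shell thickness inward / outward of the surface.
#' @return An `xl_particle`.
#' @export
particle_sphere <- function(diameter = 300, inner_t = 20, outer_t = 20) {
  check_number(diameter, "diameter", min = 1e-9)
  structure(list(kind = "sphere", dims = c(diameter = diameter),
                 shell = c(inner_t = inner_t, outer_t = outer_t)),
            class = "xl_particle")
}

#' @rdname particle_sphere
#' @param dx,dy,dz Discoid bounding dimensions, Angstrom (`dz` is the
#'   thickness; `dz <= min(dx, dy)` so the rim radius fits).
#' @export
particle_discoid <- function(dx = 200, dy = 200, dz = 110,
                             inner_t = 20, outer_t = 20) {
  for (v in c(dx, dy, dz)) check_number(v, "dimension", min = 1e-9)
  if (dz > min(dx, dy)) {
    abort("Discoid thickness dz must not exceed dx or dy.",
          class = "xlinkr_input_error")
  }
  structure(list(kind = "discoid", dims = c(dx = dx, dy = dy, dz = dz),
                 shell = c(inner_t = inner_t, outer_t = outer_t)),
            class = "xl_particle")
}

#' @export
print.xl_particle <- function(x, ...) {
  cat(sprintf("<xl_particle> %s (%s A), shell -%g/+%g A\n", x$kind,
              paste(round(x$dims), collapse = " x "),
              x$shell[1], x$shell[2]))
  invisible(x)
}

#' Signed distance to a particle surface
#'
#' Negative inside the particle, positive outside, zero on the surface.
#' The discoid distance is computed numerically by minimizing over the
#' rim parameter (the core-ellipse angle).
#'
#' @param particle An `xl_particle`.
#' @param xyz Numeric matrix (n x 3) of positions, or an atom table.
#' @return Numeric vector of signed distances, Angstrom.
#' @export
surface_distance <- function(particle, xyz) {
  if (is.data.frame(xyz)) xyz <- coords(as_structure(xyz))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  if (particle$kind == "sphere") {
    r <- particle$dims[["diameter"]] / 2
    return(sqrt(rowSums(xyz^2)) - r)
  }
  a <- particle$dims[["dx"]] / 2
  b <- particle$dims[["dy"]] / 2
  h <- particle$dims[["dz"]] / 2
  ae <- a - h
  be <- b - h
  # distance from each point to the filled core ellipse in z = 0, minus h
  vapply(seq_len(nrow(xyz)), function(i) {
    p <- xyz[i, ]
    inside <- ae > 0 && be > 0 && (p[1] / ae)^2 + (p[2] / be)^2 <= 1
    d_core <- if (inside) {
      abs(p[3])
    } else {
      f <- function(th) {
        q <- c(ae * cos(th), be * sin(th), 0)
        sum((p - q)^2)
      }
      # the squared distance over the rim angle can have two local minima;
      # probe coarsely then polish
      th0 <- seq(0, 2 * pi, length.out = 73)[-73]
      vals <- vapply(th0, f, numeric(1))
      k <- which.min(vals)
      opt <- stats::optimize(f, interval = th0[k] + c(-0.1, 0.1) - 2 * pi / 72,
                             tol = 1e-10)
      opt2 <- stats::optimize(f, interval = th0[k] + c(-0.2, 0.2), tol = 1e-10)
      sqrt(min(opt$objective, opt2$objective))
    }
    d_core - h
  }, numeric(1))
}

#' Fraction of Calpha atoms inside a particle shell
#'
#' @param assembly An `xl_assembly`, atom table, or list of atom tables.
#' @param particle An `xl_particle`.
#' @return Fraction in `[0, 1]` of CA atoms whose signed surface distance
#'   lies within `[-inner_t, +outer_t]`.
#' @export
shell_containment <- function(assembly, particle) {
  s <- if (inherits(assembly, "xl_assembly")) {
    assembly_structure(assembly)
  } else if (is.data.frame(assembly)) {
    as_structure(assembly)
  } else {
    as_structure(dplyr::bind_rows(purrr::map(assembly, as_structure)))
  }
  ca <- s[s$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) return(NA_real_)
  d <- surface_distance(particle, coords(ca))
  mean(d >= -particle$shell[["inner_t"]] & d <= particle$shell[["outer_t"]])
}
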