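# shared fixtures, built in code at test time

# a one-row CA atom
ca_atom <- function(resno, x, y, z, chain = "A", resname = "GLY") {
  tibble::tibble(chain = chain, resno = as.integer(resno), resname = resname,
                 atom = "CA", x = x, y = y, z = z, element = "C")
}

# ideal helix parametrization, written independently of make_segment so it
# can serve as a closed-form oracle
helix_point <- function(i, radius = 2.3, rise = 1.5, twist = 100) {
  ang <- (i - 1) * twist * pi / 180
  c(radius * cos(ang), radius * sin(ang), rise * (i - 1))
}

# two-helix pose-recovery setup: fixed 60-mer, mobile 40-mer placed beside
# it, 8 planted tight restraints
recovery_fixture <- function(link_seed = 3) {
  fixed <- make_segment("helix", 60, start_resno = 1, chain = "A")
  mob <- make_segment("helix", 40, start_resno = 101, chain = "B")
  xyz <- as.matrix(mob[, c("x", "y", "z")])
  xyz[, 1] <- xyz[, 1] + 12
  xyz[, 3] <- xyz[, 3] + 8
  mob[, c("x", "y", "z")] <- xyz
  links <- plant_crosslinks(list(f = fixed, m = mob),
                            mix = c(satisfied = 8), seed = link_seed,
                            tight = TRUE)
  list(fixed = fixed, mobile_truth = mob, links = links)
}

# minimal PDB text written to a temp file
write_pdb_lines <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, atom, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f  0.00           C",
          serial, atom, alt, resname, chain, resno, icode, x, y, z, occ)
}
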