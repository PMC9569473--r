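#' Atom-table structures
#'
#' A structure is a tibble of atom records with columns `chain`, `resno`
#' (residue number in full-sequence numbering), `resname` (3-letter code),
#' `atom` (atom name, e.g. "CA"), `x`, `y`, `z` (Angstrom) and `element`.
#' `as_structure()` validates a data frame and stamps the `xl_structure`
#' class; all coordinate-consuming functions accept any data frame with
#' these columns.
#'
#' @param df A data frame of atom records.
#' @return A tibble of class `xl_structure`.
#' @export
as_structure <- function(df) {
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("Structure is missing columns: ", paste(missing, collapse = ", ")),
          class = "xlinkr_structure_error")
  }
  df <- as_tibble(df)
  if (!"element" %in% names(df)) {
    df$element <- substr(df$atom, 1, 1)
  }
  df$resno <- as.integer(df$resno)
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("Duplicate atom record (chain residue atom): %s", dup),
          class = "xlinkr_structure_error")
  }
  class(df) <- unique(c("xl_structure", class(df)))
  df
}

#' @export
print.xl_structure <- function(x, ...) {
  cat(sprintf("<xl_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(x$resno)),
              paste(unique(x$chain), collapse = " ")))
  NextMethod()
}

coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

# rows of `structure` matching residue + atom name; resno is the join key
# (chains are segment bookkeeping, numbering is global)
atom_rows <- function(structure, resno, atom = "CA") {
  which(structure$resno == resno & structure$atom == atom)
}

#' Distance between two named atoms
#'
#' Euclidean distance between atom `atom_name` of residues `res_a` and
#' `res_b`. Missing residues or atoms (e.g. unmodeled gaps) yield `NA`,
#' never an error, so restraints into unmodeled regions can be reported as
#' unmeasurable downstream.
#'
#' @param structure An atom table (see [as_structure()]).
#' @param res_a,res_b Residue numbers (full-sequence numbering).
#' @param atom_name Atom name; default `"CA"` (use `"SG"` for disulfides).
#' @return Distance in Angstrom, or `NA_real_` if either atom is absent.
#' @examples
#' s <- tibble::tibble(chain = "A", resno = 1:2, resname = "GLY",
#'                     atom = "CA", x = c(0, 3), y = c(0, 4), z = 0)
#' measure_distance(s, 1, 2) # 5
#' @export
measure_distance <- function(structure, res_a, res_b, atom_name = "CA") {
  ia <- atom_rows(structure, res_a, atom_name)
  ib <- atom_rows(structure, res_b, atom_name)
  if (length(ia) != 1L || length(ib) != 1L) return(NA_real_)
  sqrt(sum((unlist(structure[ia, c("x", "y", "z")]) -
              unlist(structure[ib, c("x", "y", "z")]))^2))
}

#' Root-mean-square deviation between matched atoms
#'
#' Atoms are matched by (chain, resno, atom); both structures must contain
#' the same atom set. No superposition is performed: this is the RMSD of
#' the coordinates as given, the natural score for "did the optimizer put
#' the rigid body back where it belongs".
#'
#' @param a,b Atom tables.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  key <- function(s) paste(s$chain, s$resno, s$atom)
  ka <- key(a); kb <- key(b)
  m <- match(ka, kb)
  if (anyNA(m)) {
    abort("Structures do not contain the same atoms; cannot compute RMSD.",
          class = "xlinkr_structure_error")
  }
  d2 <- rowSums((coords(a) - coords(b)[m, , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Read a PDB coordinate file into an atom table
#'
#' Parses ATOM/HETATM records (via bio3d). Multi-model files keep model 1
#' with a warning; alternate locations keep the highest-occupancy conformer;
#' insertion codes are rejected (full-sequence numbering must be unambiguous).
#'
#' @param path Path to a PDB file.
#' @param offset Added to every residue number after reading; lets domain
#'   models numbered from 1 be lifted into full-sequence numbering.
#' @return An [as_structure()] tibble.
#' @export
read_pdb <- function(path, offset = 0L) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path), class = "xlinkr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    val <- substr(lines[is_atom], fld[1], fld[2])
    bad <- is.na(suppressWarnings(as.numeric(val)))
    if (any(bad)) {
      ln <- which(is_atom)[which(bad)[1]]
      abort(sprintf("Malformed coordinate field at line %d of %s: '%s'",
                    ln, path, val[which(bad)[1]]),
            class = "xlinkr_io_error")
    }
  }
  n_models <- sum(grepl("^MODEL ", lines))
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (n_models > 1) {
    warn(sprintf("%s contains %d models; keeping model 1.", path, n_models))
  }
  if (any(!is.na(at$insert))) {
    abort(sprintf("%s contains insertion codes (e.g. residue %s%s); renumber first.",
                  path, at$resno[!is.na(at$insert)][1],
                  at$insert[!is.na(at$insert)][1]),
          class = "xlinkr_io_error")
  }
  if (any(!is.na(at$alt))) {
    # keep the highest-occupancy altloc per (chain, resno, atom)
    at$o[is.na(at$o)] <- 1
    grp <- paste(at$chain, at$resno, at$elety)
    ord <- order(grp, -at$o)
    at <- at[ord, ][!duplicated(grp[ord]), ]
    at <- at[order(at$eleno), ]
  }
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  as_structure(tibble(
    chain = chain,
    resno = as.integer(at$resno) + as.integer(offset),
    resname = at$resid,
    atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "", substr(at$elety, 1, 1), at$elesy)
  ))
}

#' Write an atom table to a PDB file
#'
#' @param structure An atom table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  s <- as_structure(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(s))),
    resno = s$resno,
    resid = s$resname,
    elety = s$atom,
    chain = s$chain,
    elesy = s$element
  )
  invisible(path)
}

#' Read a protein sequence from FASTA
#'
#' Returns the first record as a plain character string of one-letter codes.
#' Uses Biostrings when available, otherwise a minimal line reader.
#'
#' @param path FASTA file path.
#' @return Character scalar sequence.
#' @export
read_fasta_sequence <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    return(as.character(set[[1]]))
  }
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (!length(headers)) abort("Not a FASTA file (no '>' header).", class = "xlinkr_io_error")
  to <- if (length(headers) > 1) headers[2] - 1 else length(lines)
  paste(lines[(headers[1] + 1):to], collapse = "")
}
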