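#' Idealized Calpha-trace segments
#'
#' Fixture generator for testable geometry without external structures.
#' Helices use the standard alpha-helix idealization (radius 2.3 A, rise
#' 1.5 A/residue, twist 100 degrees/residue), strands a 3.8 A/residue
#' near-linear trace with an alternating 10 degree zigzag, and coils a
#' self-avoiding random walk with 3.8 A steps and 3.5 A minimum
#' separation.
#'
#' @param type `"helix"`, `"strand"` or `"coil"`.
#' @param length Number of residues (>= 2).
#' @param seed RNG seed (only the coil uses randomness).
#' @param start_resno First residue number (full-sequence numbering).
#' @param chain Chain id.
#' @param resname Residue name stamped on every residue.
#' @param max_attempts Coil restarts before giving up.
#' @return An atom table of CA atoms.
#' @export
make_segment <- function(type = c("helix", "strand", "coil"), length, seed = 1,
                         start_resno = 1L, chain = "A", resname = "GLY",
                         max_attempts = 200) {
  type <- match.arg(type)
  check_number(length, "length", min = 2)
  n <- as.integer(length)
  xyz <- switch(type,
    helix = {
      i <- seq_len(n) - 1
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    strand = {
      i <- seq_len(n) - 1
      # step direction alternates +-5 degrees off the axis (10 degree zigzag)
      off <- 5 * pi / 180
      dirs <- cbind(cos(off), ifelse(i[-1] %% 2 == 1, sin(off), -sin(off)), 0)
      apply(rbind(c(0, 0, 0), 3.8 * dirs), 2, cumsum)
    },
    coil = with_seed_or_not(seed, {
      for (attempt in seq_len(max_attempts)) {
        p <- matrix(0, n, 3)
        ok <- TRUE
        for (k in seq_len(n - 1)) {
          placed <- FALSE
          for (try in seq_len(50)) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
            cand <- p[k, ] + 3.8 * u
            if (k < 2 ||
                min(rowSums(sweep(p[seq_len(k - 1), , drop = FALSE], 2,
                                  cand)^2)) >= 3.5^2) {
              p[k + 1, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            ok <- FALSE
            break
          }
        }
        if (ok) break
      }
      if (!ok) {
        abort("Coil generation failed; try fewer residues or more attempts.",
              class = "xlinkr_synthetic_error")
      }
      p
    })
  )
  as_structure(tibble(chain = chain,
                      resno = start_resno + seq_len(n) - 1L,
                      resname = resname, atom = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = "C"))
}

#' Plant cross-links with known ground-truth distances
#'
#' Samples residue pairs from a (placed) assembly whose true Calpha
#' distances fall in requested category bands, so downstream evaluation
#' has an exact expected outcome. Sampled endpoints are relabeled LYS
#' (DSSO links lysines).
#'
#' @param structures A placed atom table or named list of placed segments.
#' @param mix Named counts per band, e.g. `c(satisfied = 56, marginal = 3,
#'   violated = 5)`.
#' @param threshold,grace Category bands (defaults 26 / 30 A).
#' @param seed RNG seed.
#' @param between Optional character pair restricting sampling to links
#'   bridging two named segments; `NULL` samples inter-segment pairs when
#'   a list is given, any pair otherwise.
#' @param min_residue_sep Minimum |res_a - res_b| (avoids trivial
#'   neighbors), default 5.
#' @param tight If `TRUE`, also record each link's true distance in a
#'   `target` column so fitting can use two-sided restraints.
#' @return Tibble of links: id, res_a, res_b, d_max, truth_distance, band
#'   (and `target` when `tight`).
#' @export
plant_crosslinks <- function(structures, mix = c(satisfied = 10),
                             threshold = 26, grace = 30, seed = 1,
                             between = NULL, min_residue_sep = 5,
                             tight = FALSE) {
  single <- is.data.frame(structures)
  if (single) structures <- list(seg = as_structure(structures))
  structures <- purrr::map(structures, as_structure)
  cas <- purrr::imap_dfr(structures, function(s, nm) {
    ca <- s[s$atom == "CA", c("resno", "x", "y", "z")]
    ca$segment <- nm
    ca
  })
  if (!is.null(between)) {
    cas <- cas[cas$segment %in% between, , drop = FALSE]
  }
  xyz <- as.matrix(cas[, c("x", "y", "z")])
  d <- sqrt(cross_sqdist(xyz, xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- abs(cas$resno[idx[, 1]] - cas$resno[idx[, 2]]) >= min_residue_sep
  if (length(unique(cas$segment)) > 1) {
    # multiple segments: plant only bridging links
    keep <- keep & cas$segment[idx[, 1]] != cas$segment[idx[, 2]]
  }
  idx <- idx[keep, , drop = FALSE]
  dist_all <- d[cbind(idx[, 1], idx[, 2])]
  band_of <- ifelse(dist_all <= threshold, "satisfied",
                    ifelse(dist_all <= grace, "marginal", "violated"))
  with_seed_or_not(seed, {
    picks <- purrr::imap_dfr(as.list(mix), function(n_want, band) {
      if (n_want == 0) return(tibble())
      pool <- which(band_of == band & dist_all >= 4)
      if (length(pool) < n_want) {
        abort(sprintf("Only %d candidate pairs in band '%s' (%d requested).",
                      length(pool), band, n_want),
              class = "xlinkr_synthetic_error")
      }
      chosen <- sample(pool, n_want)
      tibble(res_a = cas$resno[idx[chosen, 1]],
             res_b = cas$resno[idx[chosen, 2]],
             truth_distance = dist_all[chosen],
             band = band)
    })
    picks <- picks[!duplicated(paste(pmin(picks$res_a, picks$res_b),
                                     pmax(picks$res_a, picks$res_b))), ]
    picks$id <- sprintf("K%d-K%d", pmin(picks$res_a, picks$res_b),
                        pmax(picks$res_a, picks$res_b))
    picks$d_max <- threshold
    if (tight) picks$target <- picks$truth_distance
    dplyr::relocate(canonicalize_links(picks), "id")
  })
}

#' Randomly displace (and optionally mirror) a segment
#'
#' Applies a uniform random rotation and a bounded random translation --
#' and, when `mirror = TRUE`, a reflection first -- to a placed segment.
#' The pose that undoes the displacement is recorded so pose-recovery
#' tests have exact ground truth.
#'
#' @param structure Placed atom table (the truth).
#' @param seed RNG seed.
#' @param mirror Reflect before displacing.
#' @param max_translation Translation magnitude bound, A.
#' @return List: `structure` (displaced), `truth_pose` (maps displaced back
#'   onto the truth), `applied_pose`.
#' @export
scramble_segment <- function(structure, seed = 1, mirror = FALSE,
                             max_translation = 30) {
  s <- as_structure(structure)
  with_seed_or_not(seed, {
    R <- random_rotation()
    if (mirror) R <- R %*% reflection_matrix(c(0, 0, 1))
    t_vec <- stats::runif(3, -max_translation, max_translation)
    applied <- pose(R, t_vec)
    displaced <- transform_structure(s, applied)
    # orthogonal (possibly improper) R: inverse is the transpose
    inv <- pose(t(R), -as.vector(t(R) %*% t_vec))
    list(structure = displaced, truth_pose = inv, applied_pose = applied)
  })
}

#' Five-segment toy assembly echoing a large multi-subunit protein
#'
#' Five idealized helical segments at one tenth of the apoB-100 subunit
#' lengths (99, 106, 48, 151, 51 residues over a contiguous 1-455 span),
#' placed as a parallel bundle with inter-axis spacings that admit a
#' clash-free, fully satisfiable set of 13 planted inter-segment
#' cross-links (4 + 3 + 3 + 3 along the default assembly order S1, S2,
#' S3, S5, S4).
#'
#' @param seed RNG seed for link planting and scrambling.
#' @param tight Record ground-truth distances as two-sided targets
#'   (default `TRUE`; the fixture knows its truth, and fitting against it
#'   keeps the greedy assembly well-posed).
#' @return List: `truth` (named list of placed segments), `segments`
#'   (scrambled local-frame copies to assemble), `truth_poses`, `links`,
#'   `scheme`, `order`, `threshold`.
#' @export
toy_apob <- function(seed = 42, tight = TRUE) {
  lengths <- c(S1 = 99L, S2 = 106L, S3 = 48L, S4 = 151L, S5 = 51L)
  starts <- c(S1 = 1L, S2 = 100L, S3 = 206L, S4 = 254L, S5 = 405L)
  offsets <- list(S1 = c(0, 0), S2 = c(13, 0), S3 = c(6.5, 11.5),
                  S4 = c(19.5, 11.5), S5 = c(13, 23))
  chains <- c(S1 = "A", S2 = "B", S3 = "C", S4 = "D", S5 = "E")
  truth <- purrr::imap(lengths, function(len, nm) {
    seg <- make_segment("helix", len, start_resno = starts[[nm]],
                        chain = chains[[nm]])
    xyz <- coords(seg)
    xyz[, 3] <- xyz[, 3] - mean(xyz[, 3])   # center each axis on z = 0
    xyz[, 1] <- xyz[, 1] + offsets[[nm]][1]
    xyz[, 2] <- xyz[, 2] + offsets[[nm]][2]
    set_coords(seg, xyz)
  })
  interfaces <- list(
    list(pair = c("S1", "S2"), n = 4),
    list(pair = c("S1", "S3"), n = 1),
    list(pair = c("S2", "S3"), n = 2),
    list(pair = c("S3", "S5"), n = 2),
    list(pair = c("S2", "S5"), n = 1),
    list(pair = c("S4", "S5"), n = 2),
    list(pair = c("S3", "S4"), n = 1)
  )
  links <- purrr::imap_dfr(interfaces, function(iface, i) {
    plant_crosslinks(truth, mix = c(satisfied = iface$n), seed = seed + i,
                     between = iface$pair, tight = tight)
  })
  links <- canonicalize_links(links)
  scheme <- new_scheme(
    tibble(segment = names(lengths), level = "subunit",
           start = unname(starts),
           end = unname(starts + lengths - 1L)),
    span = c(1L, 455L)
  )
  scrambled <- purrr::imap(truth, function(s, nm) {
    scramble_segment(s, seed = seed + match(nm, names(truth)) * 101)
  })
  list(truth = truth,
       segments = purrr::map(scrambled, "structure"),
       truth_poses = purrr::map(scrambled, "truth_pose"),
       links = links,
       scheme = scheme,
       order = c("S1", "S2", "S3", "S5", "S4"),
       threshold = 26)
}

#' Two-segment fixture whose restraints require a mirror image
#'
#' Builds a satisfiable two-segment truth, then records restraint target
#' distances measured with the mobile segment *reflected*. Fitting the
#' unreflected mobile against those targets can only succeed through an
#' improper (chirality-inverting) transform -- the classic mirror-image
#' ambiguity of distance-only restraints.
#'
#' @param seed RNG seed.
#' @param n_links Planted restraints (default 8).
#' @return List: `fixed`, `mobile` (local frame), `links` (with mirrored
#'   targets), `threshold`.
#' @export
mirror_fixture <- function(seed = 7, n_links = 12) {
  # coils on both sides: their anchor clouds are chirality-rich, so no
  # proper rotation can mimic the reflection (a lone ideal helix is nearly
  # mirror-symmetric at the Calpha level and would blur the two branches)
  fixed <- make_segment("coil", 60, seed = seed, start_resno = 1L, chain = "A")
  mobile_truth <- make_segment("coil", 40, seed = seed + 1, start_resno = 101L,
                               chain = "B")
  base <- sweep(coords(mobile_truth), 2, colMeans(coords(mobile_truth)))
  fc <- colMeans(coords(fixed))
  # slide the mobile out along +x until both the truth and its mirror are
  # clash-free against the fixed body (the planted links must be realizable
  # by the improper pose without steric penalty)
  for (offset in seq(16, 60, by = 2)) {
    xyz <- base
    xyz[, 1] <- xyz[, 1] + fc[1] + offset
    xyz[, 2] <- xyz[, 2] + fc[2]
    xyz[, 3] <- xyz[, 3] + fc[3]
    mobile_truth <- set_coords(mobile_truth, xyz)
    mobile_mirrored <- mirror_structure(mobile_truth,
                                        point = colMeans(xyz),
                                        normal = c(0, 1, 0))
    if (clash_count(fixed, mobile_truth) == 0L &&
        clash_count(fixed, mobile_mirrored) == 0L) break
  }
  links <- plant_crosslinks(list(fixed = fixed, mobile = mobile_mirrored),
                            mix = c(satisfied = n_links), seed = seed,
                            tight = TRUE)
  list(fixed = fixed, mobile = mobile_truth, links = links, threshold = 26)
}

#' Synthetic protein-painting dataset
#'
#' Digests the sequence, then simulates detection: peptides overlapping an
#' exposed (painted) range are absent from painted replicates; everything
#' else is present in both conditions; `dropout` removes each remaining
#' detection independently at random.
#'
#' @param sequence Protein sequence.
#' @param exposed_ranges Tibble of exposed ranges (`start`, `end`).
#' @param n_replicates Replicates per condition (default 3).
#' @param dropout Per-detection dropout probability.
#' @param seed RNG seed.
#' @param missed_cleavages,min_len Digestion settings for the simulated
#'   peptide map (defaults 0 and 1: maximal coverage).
#' @return Observation tibble for [paint_regions()].
#' @export
make_painting_dataset <- function(sequence, exposed_ranges, n_replicates = 3,
                                  dropout = 0, seed = 1,
                                  missed_cleavages = 0, min_len = 1) {
  peps <- digest(sequence, missed_cleavages = missed_cleavages,
                 min_len = min_len)
  exposed_ranges <- as_tibble(exposed_ranges)
  overlaps <- vapply(seq_len(nrow(peps)), function(i) {
    any(peps$start[i] <= exposed_ranges$end &
          peps$end[i] >= exposed_ranges$start)
  }, logical(1))
  grid <- tidyr::expand_grid(pep = seq_len(nrow(peps)),
                             replicate = seq_len(n_replicates),
                             condition = c("unpainted", "painted"))
  grid$present <- !(grid$condition == "painted" & overlaps[grid$pep])
  with_seed_or_not(seed, {
    if (dropout > 0) {
      grid$present <- grid$present &
        stats::runif(nrow(grid)) >= dropout
    }
    obs <- grid[grid$present, , drop = FALSE]
    tibble(peptide = peps$peptide[obs$pep],
           start = peps$start[obs$pep],
           end = peps$end[obs$pep],
           replicate = obs$replicate,
           condition = obs$condition)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the toy assembly as PDB (one chain per segment), the planted
#' links as TSV, the scheme as YAML, and the ground truth (poses and
#' distances) as JSON -- the `simulate` CLI subcommand calls this.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
simulate_fixture <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- toy_apob(seed = seed)
  write_pdb(dplyr::bind_rows(toy$truth), file.path(dir, "truth.pdb"))
  for (nm in names(toy$segments)) {
    write_pdb(toy$segments[[nm]], file.path(dir, paste0(nm, ".pdb")))
  }
  write_links(toy$links, file.path(dir, "links.tsv"))
  write_scheme(toy$scheme, file.path(dir, "scheme.yaml"))
  truth <- list(
    seed = seed,
    order = toy$order,
    threshold = toy$threshold,
    links = toy$links,
    poses = purrr::map(toy$truth_poses, function(p) {
      list(rotation = as.vector(p$rotation), translation = p$translation,
           improper = p$improper)
    })
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
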