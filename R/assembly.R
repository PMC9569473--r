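#' Restraint loss of a placed assembly
#'
#' The assembly objective: sum of squared distance excesses over the
#' per-link upper bound, plus `lambda` per steric clash. Links with a
#' `target` column are scored two-sided (`(d - target)^2`), which is how
#' synthetic ground-truth restraints are fitted; experimental links are
#' upper-bound only. Links with at least one endpoint in a coil-level
#' segment get `coil_slack` added to their bound when a scheme is given
#' (coils are flexible; a rigid placement should not be charged for them
#' at full stringency).
#'
#' @param structures A single atom table or (named) list of placed atom
#'   tables; an `xl_assembly` is also accepted.
#' @param links Restraint tibble with `res_a`, `res_b` and optionally
#'   `d_max`, `target`.
#' @param linker,threshold Default bound when a link has no `d_max`
#'   (the linker's reported threshold unless `threshold` is given).
#' @param lambda Clash penalty, Angstrom^2 per clashing pair (default 100).
#' @param clash_cutoff Inter-body clash distance (default 4 A).
#' @param scheme Optional `xl_scheme` enabling coil slack.
#' @param coil_slack Extra Angstrom added to bounds of coil-touching links
#'   (default 10; only applied when `scheme` is given).
#' @return List with `restraint_sq`, `clashes`, `loss`, `per_link` tibble
#'   and `n_excluded` (links whose endpoints are not resolvable).
#' @export
restraint_loss <- function(structures, links, linker = linker_dsso(),
                           threshold = NULL, lambda = 100, clash_cutoff = 4,
                           scheme = NULL, coil_slack = 10) {
  if (inherits(structures, "xl_assembly")) structures <- structures$structures
  if (is.data.frame(structures)) structures <- list(structures)
  structures <- purrr::map(structures, as_structure)
  links <- prepare_restraints(links, linker, threshold, scheme, coil_slack)
  combined <- dplyr::bind_rows(structures)

  ca <- combined[combined$atom == "CA", , drop = FALSE]
  pos <- match(links$res_a, ca$resno)
  pos_b <- match(links$res_b, ca$resno)
  ok <- !is.na(pos) & !is.na(pos_b)
  xyz <- coords(ca)
  d <- rep(NA_real_, nrow(links))
  d[ok] <- sqrt(rowSums((xyz[pos[ok], , drop = FALSE] -
                           xyz[pos_b[ok], , drop = FALSE])^2))
  excess <- ifelse(is.na(links$target),
                   pmax(0, d - links$d_max),
                   abs(d - links$target))
  restraint_sq <- sum(excess[ok]^2)

  clashes <- 0L
  if (length(structures) > 1) {
    xs <- purrr::map(structures, function(s) coords(s[s$atom == "CA", ]))
    for (i in seq_along(xs)) {
      for (j in seq_along(xs)) {
        if (j > i) clashes <- clashes + clash_count(xs[[i]], xs[[j]], clash_cutoff)
      }
    }
  }
  list(restraint_sq = restraint_sq,
       clashes = as.integer(clashes),
       loss = restraint_sq + lambda * clashes,
       per_link = tibble(id = links$id, res_a = links$res_a,
                         res_b = links$res_b, distance = d,
                         bound = links$d_max, target = links$target,
                         excess = excess),
       n_excluded = sum(!ok))
}

# normalize a restraint table for fitting: canonical pairs, per-link bound,
# optional two-sided target, coil slack
prepare_restraints <- function(links, linker, threshold, scheme = NULL,
                               coil_slack = 10) {
  links <- canonicalize_links(links)
  if (is.null(threshold)) {
    threshold <- max_ca_distance(linker, "K", "K")$reported
  }
  if (!"d_max" %in% names(links)) links$d_max <- threshold
  links$d_max[is.na(links$d_max)] <- threshold
  if (!"target" %in% names(links)) links$target <- NA_real_
  if (!is.null(scheme) && coil_slack > 0) {
    in_coil <- !is.na(locate_residue(scheme, links$res_a)$coil) |
      !is.na(locate_residue(scheme, links$res_b)$coil)
    links$d_max[in_coil] <- links$d_max[in_coil] + coil_slack
  }
  links
}

#' Fit the pose of a mobile domain against a fixed assembly
#'
#' Multi-start rigid-body search: uniform random rotations with the mobile
#' restraint-anchor centroid initialized near the fixed anchors'
#' centroid, followed by coordinate descent over the 6 pose parameters
#' with step halving. The loss is the [restraint_loss()] objective over
#' the links bridging mobile and fixed. With `allow_mirror = TRUE` the
#' reflected mobile copy is optimized as well and the improper solution is
#' returned (flagged) only when its loss is strictly lower.
#'
#' @param mobile Atom table of the domain to place (any initial frame).
#' @param fixed Atom table (or list of placed tables) of the anchored part.
#' @param restraints Tibble with `res_a`, `res_b`, optional `d_max`,
#'   `target`; only links bridging mobile and fixed are used.
#' @param linker,threshold Default per-link bound (see [restraint_loss()]).
#' @param allow_mirror Also try the chirality-inverted mobile.
#' @param n_starts Random starts per branch (default 20).
#' @param seed RNG seed for reproducibility.
#' @param max_iter Maximum refinement sweeps per start (default 500).
#' @param refine_top How many best starts get full refinement (default 5).
#' @param lambda,clash_cutoff Clash penalty weight and distance.
#' @param scheme,coil_slack Coil-slack handling (see [restraint_loss()]).
#' @return An `xl_pose_fit`: the best `pose` (improper flagged), losses of
#'   both branches, the per-sweep loss trace, diagnostics. Use [tidy()] for
#'   per-restraint distances and [glance()] for the one-row summary.
#' @export
fit_pose <- function(mobile, fixed, restraints, linker = linker_dsso(),
                     threshold = NULL, allow_mirror = FALSE, n_starts = 20,
                     seed = 1, max_iter = 500, refine_top = 5,
                     lambda = 100, clash_cutoff = 4,
                     scheme = NULL, coil_slack = 10) {
  mobile <- as_structure(mobile)
  if (inherits(fixed, "xl_assembly")) fixed <- fixed$structures
  if (is.data.frame(fixed)) fixed <- list(fixed)
  fixed_comb <- as_structure(dplyr::bind_rows(purrr::map(fixed, as_structure)))
  links <- prepare_restraints(restraints, linker, threshold, scheme, coil_slack)

  mob_res <- unique(mobile$resno[mobile$atom == "CA"])
  fix_res <- unique(fixed_comb$resno[fixed_comb$atom == "CA"])
  a_in_mob <- links$res_a %in% mob_res
  b_in_mob <- links$res_b %in% mob_res
  a_in_fix <- links$res_a %in% fix_res
  b_in_fix <- links$res_b %in% fix_res
  bridges <- (a_in_mob & b_in_fix) | (b_in_mob & a_in_fix)
  n_excluded <- sum(!bridges)
  links <- links[bridges, , drop = FALSE]
  if (nrow(links) == 0L) {
    abort("No restraints bridge the mobile and fixed structures.",
          class = "xlinkr_restraint_error")
  }
  mob_end <- ifelse(links$res_a %in% mob_res, links$res_a, links$res_b)
  fix_end <- ifelse(links$res_a %in% mob_res, links$res_b, links$res_a)

  mob_ca <- mobile[mobile$atom == "CA", , drop = FALSE]
  fix_ca <- fixed_comb[fixed_comb$atom == "CA", , drop = FALSE]
  m_anchor <- coords(mob_ca)[match(mob_end, mob_ca$resno), , drop = FALSE]
  f_anchor <- coords(fix_ca)[match(fix_end, fix_ca$resno), , drop = FALSE]
  m_all <- coords(mob_ca)
  mc <- colMeans(m_anchor)
  fc <- colMeans(f_anchor)

  # degeneracy diagnostic: collinear anchors leave a rotation family free
  degenerate <- TRUE   # < 3 anchors can never pin a rigid pose
  if (nrow(m_anchor) >= 3) {
    sv <- svd(scale(m_anchor, center = TRUE, scale = FALSE))$d
    degenerate <- sum(sv > 1e-6 * max(sv, 1)) < 2
  }
  if (degenerate) {
    warn("Restraint anchors are (nearly) collinear; the pose family is not unique.")
  }

  fix_xyz <- coords(fix_ca)
  use_grid <- nrow(m_all) * nrow(fix_xyz) > 250000
  grid_fixed <- if (use_grid) grid_build(fix_xyz, clash_cutoff) else NULL
  cut2 <- clash_cutoff^2
  d_max <- links$d_max
  target <- links$target
  two_sided <- !is.na(target)

  # branch geometry: mobile anchors/atoms centered on the anchor centroid
  loss_fun <- function(R, cpos, m_cen, m_all_cen) {
    ma <- sweep(m_cen %*% t(R), 2, cpos, "+")
    d <- sqrt(rowSums((ma - f_anchor)^2))
    ex <- ifelse(two_sided, abs(d - target), pmax(0, d - d_max))
    all_xyz <- sweep(m_all_cen %*% t(R), 2, cpos, "+")
    n_clash <- if (use_grid) {
      grid_count(grid_fixed, all_xyz, clash_cutoff)
    } else {
      sum(cross_sqdist(all_xyz, fix_xyz) < cut2)
    }
    sum(ex^2) + lambda * n_clash
  }

  # least-squares proper rotation + translation mapping rows of P onto Q
  kabsch <- function(P, Q) {
    H <- crossprod(P, sweep(Q, 2, colMeans(Q)))
    sv <- svd(H)
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    list(R = R, cpos = colMeans(Q))
  }

  # flow a start toward restraint satisfaction: project each anchor onto
  # the sphere of its bound around its fixed partner, re-superpose, repeat
  project_start <- function(R, cpos, m_cen, n_iter = 300) {
    prev <- Inf
    for (it in seq_len(n_iter)) {
      a <- sweep(m_cen %*% t(R), 2, cpos, "+")
      dv <- a - f_anchor
      d <- sqrt(rowSums(dv^2))
      d[d < 1e-9] <- 1e-9
      want <- ifelse(two_sided, target, pmin(d, d_max))
      q <- f_anchor + dv * (want / d)
      resid <- sum((a - q)^2)
      if (resid < 1e-14 || prev - resid < 1e-12) break
      prev <- resid
      k <- kabsch(m_cen, q)
      R <- k$R
      cpos <- k$cpos
    }
    list(R = R, cpos = cpos)
  }

  refine <- function(R0, c0, m_cen, m_all_cen) {
    p <- numeric(6)
    steps <- c(rep(0.4, 3), rep(8, 3))
    cur <- loss_fun(R0, c0, m_cen, m_all_cen)
    trace <- cur
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      before <- cur
      for (k in 1:6) {
        for (sgn in c(1, -1)) {
          q <- p
          q[k] <- q[k] + sgn * steps[k]
          val <- loss_fun(rot_xyz(q[1], q[2], q[3]) %*% R0, c0 + q[4:6],
                          m_cen, m_all_cen)
          if (val < cur - 1e-12) {
            cur <- val
            p <- q
            improved <- TRUE
            break
          }
        }
      }
      trace <- c(trace, cur)
      if (!improved) {
        steps <- steps / 2
        if (steps[1] < 1e-4 && steps[4] < 1e-3) break
      } else if (before - cur < 1e-6 && steps[1] < 1e-3) {
        break
      }
      if (cur <= 1e-12) break
    }
    list(R = rot_xyz(p[1], p[2], p[3]) %*% R0, cpos = c0 + p[4:6],
         loss = cur, trace = trace,
         converged = steps[1] < 1e-4 || cur <= 1e-12)
  }

  run_branch <- function(M = NULL) {
    m_cen <- sweep(m_anchor, 2, mc)
    m_all_cen <- sweep(m_all, 2, mc)
    if (!is.null(M)) {
      m_cen <- m_cen %*% t(M)
      m_all_cen <- m_all_cen %*% t(M)
    }
    starts <- purrr::map(seq_len(n_starts), function(i) {
      R <- random_rotation()
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, 0, mean(ifelse(two_sided, target, d_max)) / 2)
      p <- project_start(R, fc + u * r, m_cen)
      list(R = p$R, cpos = p$cpos,
           loss = loss_fun(p$R, p$cpos, m_cen, m_all_cen))
    })
    ord <- order(vapply(starts, `[[`, numeric(1), "loss"))
    best_start_loss <- starts[[ord[1]]]$loss
    refined <- purrr::map(utils::head(ord, refine_top), function(i) {
      refine(starts[[i]]$R, starts[[i]]$cpos, m_cen, m_all_cen)
    })
    best <- refined[[which.min(vapply(refined, `[[`, numeric(1), "loss"))]]
    best$best_start_loss <- best_start_loss
    if (!is.null(M)) best$R <- best$R %*% M
    best
  }

  result <- with_seed_or_not(seed, {
    proper <- run_branch()
    improper <- if (allow_mirror) {
      run_branch(M = reflection_matrix(c(1, 0, 0)))
    }
    list(proper = proper, improper = improper)
  })

  use_improper <- !is.null(result$improper) &&
    result$improper$loss < result$proper$loss
  best <- if (use_improper) result$improper else result$proper
  R <- best$R
  t_vec <- best$cpos - as.vector(R %*% mc)
  final_pose <- pose(R, t_vec)

  placed <- transform_structure(mobile, final_pose)
  d_final <- sqrt(rowSums((coords(placed[placed$atom == "CA", ])[
    match(mob_end, placed$resno[placed$atom == "CA"]), , drop = FALSE] -
      f_anchor)^2))

  structure(list(
    pose = final_pose,
    loss = best$loss,
    proper_loss = result$proper$loss,
    improper_loss = if (is.null(result$improper)) NA_real_ else result$improper$loss,
    improper = final_pose$improper,
    trace = best$trace,
    best_start_loss = best$best_start_loss,
    converged = best$converged,
    degenerate = degenerate,
    n_restraints = nrow(links),
    n_excluded = n_excluded,
    per_link = tibble(id = links$id, res_a = links$res_a, res_b = links$res_b,
                      distance = d_final, bound = d_max, target = target)
  ), class = "xl_pose_fit")
}

#' @export
print.xl_pose_fit <- function(x, ...) {
  cat(sprintf("<xl_pose_fit> loss %.4g over %d restraints%s%s\n",
              x$loss, x$n_restraints,
              if (x$improper) " [IMPROPER]" else "",
              if (x$degenerate) " [degenerate anchors]" else ""))
  cat(sprintf("  proper loss %.4g, improper loss %s\n", x$proper_loss,
              if (is.na(x$improper_loss)) "not tried" else
                sprintf("%.4g", x$improper_loss)))
  invisible(x)
}

#' @export
tidy.xl_pose_fit <- function(x, ...) x$per_link

#' @export
glance.xl_pose_fit <- function(x, ...) {
  tibble(loss = x$loss, proper_loss = x$proper_loss,
         improper_loss = x$improper_loss, improper = x$improper,
         n_restraints = x$n_restraints, n_excluded = x$n_excluded,
         converged = x$converged, degenerate = x$degenerate)
}

#' @rdname fit_pose
#' @param object An `xl_pose_fit`.
#' @param ... Unused.
#' @export
autoplot.xl_pose_fit <- function(object, ...) {
  df <- tibble(sweep = seq_along(object$trace) - 1, loss = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "refinement sweep", y = "loss") +
    ggplot2::theme_minimal()
}

#' Greedy sequential assembly of rigid segments
#'
#' Places segments one at a time in the given order: the first is the
#' anchor (kept as passed), each later one is fitted with [fit_pose()]
#' against the union of already-placed segments using every restraint
#' bridging to them. Segments with no bridging restraint are skipped with
#' a warning. The final report evaluates all links on the assembled
#' coordinates.
#'
#' @param segments Named list of atom tables (each in its own frame).
#' @param links Restraint tibble (`res_a`, `res_b`, optional `d_max`,
#'   `target`).
#' @param order Character vector of segment names; first is the anchor.
#' @param linker,threshold,grace Restraint bands for the final report.
#' @param scheme Optional `xl_scheme` (topology breakdown + coil slack).
#' @param seed RNG seed, advanced deterministically per segment.
#' @param ... Passed to [fit_pose()] (`n_starts`, `allow_mirror`, ...).
#' @return An `xl_assembly`: placed structures, poses, fits, the final
#'   `xl_report`, and the names of skipped segments.
#' @export
sequential_assemble <- function(segments, links, order = names(segments),
                                linker = linker_dsso(), threshold = NULL,
                                grace = 30, scheme = NULL, seed = 1, ...) {
  stopifnot(is.list(segments), !is.null(names(segments)))
  missing_seg <- setdiff(order, names(segments))
  if (length(missing_seg)) {
    abort(paste("Unknown segment(s) in order:", paste(missing_seg, collapse = ", ")),
          class = "xlinkr_input_error")
  }
  if (is.null(threshold)) threshold <- max_ca_distance(linker, "K", "K")$reported
  placed <- list()
  poses <- list()
  fits <- list()
  skipped <- character()
  anchor <- order[1]
  placed[[anchor]] <- as_structure(segments[[anchor]])
  poses[[anchor]] <- pose_identity()
  for (k in seq_along(order)[-1]) {
    seg <- order[k]
    mob <- as_structure(segments[[seg]])
    fit <- tryCatch(
      fit_pose(mob, placed, links, linker = linker, threshold = threshold,
               scheme = scheme, seed = seed + k, ...),
      xlinkr_restraint_error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(sprintf("Segment '%s' has no restraint bridging the placed set; skipped.",
                   seg))
      skipped <- c(skipped, seg)
      next
    }
    placed[[seg]] <- transform_structure(mob, fit$pose)
    poses[[seg]] <- fit$pose
    fits[[seg]] <- fit
  }
  combined <- as_structure(dplyr::bind_rows(placed))
  ev <- evaluate_crosslinks(combined, links, linker = linker,
                            threshold = threshold, grace = grace)
  report <- summarize_restraints(ev, scheme = scheme)
  structure(list(structures = placed, poses = poses, fits = fits,
                 report = report, skipped = skipped,
                 threshold = threshold),
            class = "xl_assembly")
}

#' @export
print.xl_assembly <- function(x, ...) {
  cat(sprintf("<xl_assembly> %d segments placed%s\n", length(x$structures),
              if (length(x$skipped))
                paste0(" (skipped: ", paste(x$skipped, collapse = ", "), ")")
              else ""))
  print(x$report)
  invisible(x)
}

#' Combined atom table of a placed assembly
#'
#' @param assembly An `xl_assembly`.
#' @return One atom table with all placed segments (chain per segment as
#'   carried by the inputs).
#' @export
assembly_structure <- function(assembly) {
  as_structure(dplyr::bind_rows(assembly$structures))
}
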