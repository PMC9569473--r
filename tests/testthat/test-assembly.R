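test_that("restraint loss is squared excess plus clash penalty", {
  toy <- toy_apob(seed = 3, tight = FALSE)
  rl <- restraint_loss(toy$truth, toy$links)
  expect_equal(rl$loss, 0)
  expect_equal(rl$clashes, 0L)

  # one link at 30 with a 26 bound: excess 4, squared 16
  a <- ca_atom(1, 0, 0, 0)
  b <- ca_atom(50, 30, 0, 0, chain = "B")
  rl2 <- restraint_loss(list(a = a, b = b),
                        tibble::tibble(res_a = 1, res_b = 50), threshold = 26)
  expect_equal(rl2$restraint_sq, 16)
  expect_equal(rl2$loss, 16)

  # hand-computed sum over a planted mixture
  toy2 <- toy_apob(seed = 4, tight = FALSE)
  mixed <- plant_crosslinks(toy2$truth,
                            mix = c(satisfied = 3, marginal = 2, violated = 2),
                            seed = 21)
  rl3 <- restraint_loss(toy2$truth, mixed)
  expect_equal(rl3$restraint_sq,
               sum(pmax(0, mixed$truth_distance - 26)^2), tolerance = 1e-9)

  # clashes are charged at lambda each
  close_b <- ca_atom(50, 3, 0, 0, chain = "B")
  rl4 <- restraint_loss(list(a = a, b = close_b),
                        tibble::tibble(res_a = 1, res_b = 50), threshold = 26)
  expect_equal(rl4$clashes, 1L)
  expect_equal(rl4$loss, 100)
})

test_that("fit_pose recovers a scrambled domain against tight restraints", {
  fx <- recovery_fixture()
  sc <- scramble_segment(fx$mobile_truth, seed = 5)
  fit <- fit_pose(sc$structure, fx$fixed, fx$links, seed = 11)
  expect_lt(fit$loss, 1e-2)
  placed <- transform_structure(sc$structure, fit$pose)
  expect_lt(rmsd(placed, fx$mobile_truth), 2)
  expect_false(fit$improper)
  # refinement never increases the loss; the end beats the best start
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_lte(fit$loss, fit$best_start_loss)
})

test_that("a single upper-bound restraint is satisfiable (many poses exist)", {
  fx <- recovery_fixture()
  one <- fx$links[1, ]
  one$target <- NA_real_
  fit <- suppressWarnings(fit_pose(fx$mobile_truth, fx$fixed, one, seed = 2))
  expect_equal(fit$loss, 0)
  expect_true(fit$degenerate)   # one anchor cannot pin the pose family
})

test_that("fitting without bridging restraints is an explicit error", {
  fx <- recovery_fixture()
  none <- tibble::tibble(res_a = 1, res_b = 20)  # both ends in fixed
  expect_error(fit_pose(fx$mobile_truth, fx$fixed, none, seed = 1),
               class = "xlinkr_restraint_error")
})

test_that("distance-only solutions come in chirality pairs", {
  # reflecting a zero-restraint-loss configuration through any plane gives
  # another zero-restraint-loss configuration (the formal mirror ambiguity)
  fx <- recovery_fixture()
  both <- list(f = fx$fixed, m = fx$mobile_truth)
  rl <- restraint_loss(both, fx$links)
  expect_equal(rl$restraint_sq, 0)
  for (normal in list(c(1, 0, 0), c(0, 1, 1), c(1, -2, 3))) {
    refl <- purrr::map(both, mirror_structure, point = c(2, -1, 5),
                       normal = normal)
    rl_m <- restraint_loss(refl, fx$links)
    expect_equal(rl_m$restraint_sq, 0, tolerance = 1e-9)
  }
})

test_that("mirror-demanding restraints are solved and flagged improper", {
  mf <- mirror_fixture(seed = 7)
  no_mirror <- fit_pose(mf$mobile, mf$fixed, mf$links, seed = 3,
                        allow_mirror = FALSE)
  with_mirror <- fit_pose(mf$mobile, mf$fixed, mf$links, seed = 3,
                          allow_mirror = TRUE)
  expect_gt(no_mirror$loss, 1)
  expect_lt(with_mirror$loss, 1e-3)
  expect_true(with_mirror$improper)
  expect_true(with_mirror$pose$improper)
  expect_lt(with_mirror$improper_loss, with_mirror$proper_loss)

  # before reflection some links stay beyond the limit; after, all fit
  before <- evaluate_crosslinks(
    dplyr::bind_rows(mf$fixed, transform_structure(mf$mobile, no_mirror$pose)),
    mf$links)
  after <- evaluate_crosslinks(
    dplyr::bind_rows(mf$fixed, transform_structure(mf$mobile, with_mirror$pose)),
    mf$links)
  expect_lt(sum(before$category == "satisfied"), nrow(before))
  expect_equal(sum(after$category == "satisfied"), nrow(after))
})

test_that("greedy sequential assembly satisfies the toy restraint set", {
  toy <- toy_apob(seed = 42)
  asm <- suppressWarnings(
    sequential_assemble(toy$segments, toy$links, order = toy$order,
                        scheme = toy$scheme, seed = 1))
  g <- glance(asm$report)
  expect_equal(g$n_measured, 13)
  expect_equal(g$n_satisfied, 13)
  expect_equal(g$percent_within_threshold, 100)
  expect_length(asm$skipped, 0)
})

test_that("assembly order does not change a fully constrained outcome", {
  fx <- recovery_fixture()
  segs <- list(f = fx$fixed, m = scramble_segment(fx$mobile_truth, seed = 2)$structure)
  a1 <- suppressWarnings(sequential_assemble(segs, fx$links,
                                             order = c("f", "m"), seed = 4))
  a2 <- suppressWarnings(sequential_assemble(segs, fx$links,
                                             order = c("m", "f"), seed = 4))
  expect_equal(glance(a1$report)$n_satisfied, glance(a2$report)$n_satisfied)
  expect_equal(glance(a1$report)$n_satisfied, nrow(fx$links))
})

test_that("segments without bridging restraints are skipped with a warning", {
  fx <- recovery_fixture()
  lone <- make_segment("helix", 10, start_resno = 500, chain = "Z")
  segs <- list(f = fx$fixed, m = fx$mobile_truth, z = lone)
  expect_warning(
    asm <- sequential_assemble(segs, fx$links, order = c("f", "m", "z"),
                               seed = 1),
    "skipped")
  expect_equal(asm$skipped, "z")
})

test_that("fit diagnostics surface through tidy and glance", {
  fx <- recovery_fixture()
  sc <- scramble_segment(fx$mobile_truth, seed = 9)
  fit <- fit_pose(sc$structure, fx$fixed, fx$links, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(fx$links))
  expect_true(all(c("distance", "bound", "target") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_restraints, nrow(fx$links))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
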