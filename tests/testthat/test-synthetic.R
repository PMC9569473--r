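test_that("ideal helix geometry matches its closed-form chord length", {
  h <- make_segment("helix", 25)
  chord <- sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2)
  consec <- vapply(1:24, function(i) measure_distance(h, i, i + 1), numeric(1))
  expect_equal(consec, rep(chord, 24), tolerance = 1e-10)
})

test_that("strand end-to-end length follows the zigzag geometry", {
  n <- 30
  s <- make_segment("strand", n)
  # the odd step count leaves one residual zigzag half-step in y
  expect_equal(measure_distance(s, 1, n), 3.8 * (n - 1) * cos(5 * pi / 180),
               tolerance = 1e-4)
  exact <- sqrt((3.8 * (n - 1) * cos(5 * pi / 180))^2 +
                  (3.8 * sin(5 * pi / 180))^2)
  expect_equal(measure_distance(s, 1, n), exact, tolerance = 1e-9)
})

test_that("coils are self-avoiding with 3.8 A steps", {
  cl <- make_segment("coil", 40, seed = 6)
  xyz <- as.matrix(cl[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_equal(steps, rep(3.8, 39), tolerance = 1e-9)
  d <- as.matrix(dist(xyz))
  nonadj <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[nonadj]), 3.5)
})

test_that("generation is reproducible under a seed", {
  expect_identical(make_segment("coil", 30, seed = 3),
                   make_segment("coil", 30, seed = 3))
  expect_identical(toy_apob(seed = 5)$links, toy_apob(seed = 5)$links)
  expect_false(identical(make_segment("coil", 30, seed = 3),
                         make_segment("coil", 30, seed = 4)))
})

test_that("planted mixtures evaluate to their designed composition", {
  toy <- toy_apob(seed = 2)
  links <- plant_crosslinks(toy$truth,
                            mix = c(satisfied = 56, marginal = 3, violated = 5),
                            seed = 13)
  ev <- evaluate_crosslinks(dplyr::bind_rows(toy$truth), links)
  g <- glance(summarize_restraints(ev))
  expect_equal(g$n_measured, 64)
  expect_equal(g$n_satisfied, 56)
  expect_equal(g$percent_within_threshold, 87.5)

  all_sat <- plant_crosslinks(toy$truth, mix = c(satisfied = 10), seed = 1)
  ev2 <- evaluate_crosslinks(dplyr::bind_rows(toy$truth), all_sat)
  expect_true(all(ev2$category == "satisfied"))
})

test_that("infeasible bands error by name", {
  h <- make_segment("helix", 12)
  expect_error(
    plant_crosslinks(h, mix = c(violated = 50)),
    "violated", class = "xlinkr_synthetic_error")
})

test_that("scrambling records an exact inverse pose", {
  h <- make_segment("helix", 20)
  sc <- scramble_segment(h, seed = 8)
  back <- transform_structure(sc$structure, sc$truth_pose)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(h[, c("x", "y", "z")]), tolerance = 1e-9)
  expect_false(sc$truth_pose$improper)

  scm <- scramble_segment(h, seed = 8, mirror = TRUE)
  expect_true(scm$applied_pose$improper)
  backm <- transform_structure(scm$structure, scm$truth_pose)
  expect_equal(as.matrix(backm[, c("x", "y", "z")]),
               as.matrix(h[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("a mirrored scramble is recovered as an improper pose", {
  fx <- recovery_fixture()
  scm <- scramble_segment(fx$mobile_truth, seed = 4, mirror = TRUE)
  fit <- fit_pose(scm$structure, fx$fixed, fx$links, seed = 6,
                  allow_mirror = TRUE)
  expect_true(fit$improper)
  expect_lt(rmsd(transform_structure(scm$structure, fit$pose),
                 fx$mobile_truth), 2)
})

test_that("simulate_fixture writes a loadable bundle", {
  dir <- tempfile("fixture")
  simulate_fixture(dir, seed = 11)
  expect_true(all(file.exists(file.path(
    dir, c("truth.pdb", "S1.pdb", "links.tsv", "scheme.yaml", "truth.json")))))
  links <- read_links(file.path(dir, "links.tsv"))
  expect_equal(nrow(links), 13)
  sch <- read_scheme(file.path(dir, "scheme.yaml"))
  expect_equal(sch$span, c(1L, 455L))
  truth <- read_pdb(file.path(dir, "truth.pdb"))
  ev <- evaluate_crosslinks(truth, links)
  expect_true(all(ev$category == "satisfied"))
})
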