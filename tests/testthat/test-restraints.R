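test_that("distance classification uses closed threshold and grace bands", {
  expect_equal(as.character(classify_distance(26.9)), "marginal")
  expect_equal(as.character(classify_distance(42.5)), "violated")
  expect_equal(as.character(classify_distance(26.0)), "satisfied")
  expect_equal(as.character(classify_distance(30.0)), "marginal")
  expect_equal(as.character(classify_distance(NA)), "unmeasurable")
  expect_error(classify_distance(-1), class = "xlinkr_input_error")
})

test_that("classification partitions distances and is monotone", {
  set.seed(20)
  d <- sort(c(runif(200, 0, 60), 26, 30))
  cat <- classify_distance(d)
  expect_false(anyNA(cat))
  # monotone non-decreasing category index along increasing distance
  expect_true(all(diff(as.integer(cat)) >= 0))
})

test_that("cross-link evaluation measures planted ground truth", {
  toy <- toy_apob(seed = 5)
  ev <- evaluate_crosslinks(dplyr::bind_rows(toy$truth), toy$links)
  expect_equal(nrow(ev), nrow(toy$links))
  m <- match(ev$id, toy$links$id)
  expect_equal(ev$distance, toy$links$truth_distance[m], tolerance = 1e-9)
  expect_true(all(ev$category == "satisfied"))
})

test_that("endpoints in unmodeled regions are unmeasurable, not fatal", {
  s <- make_segment("helix", 50, start_resno = 2551)
  # model covering 2591+ only, like a segment whose first stretch was cut
  coverage <- 2591:2700
  links <- tibble::tibble(res_a = c(2560, 2595), res_b = c(2596, 2598))
  ev <- evaluate_crosslinks(s, links, coverage = coverage)
  expect_equal(as.character(ev$category[ev$res_a == 2560]), "unmeasurable")
  expect_true(is.na(ev$distance[ev$res_a == 2560]))
  expect_false(is.na(ev$distance[ev$res_a == 2595]))
})

test_that("links outside the sequence span are an error", {
  s <- make_segment("helix", 10)
  expect_error(
    evaluate_crosslinks(s, tibble::tibble(res_a = 2, res_b = 5000),
                        sequence_span = c(1, 100)),
    class = "xlinkr_range_error")
})

test_that("empty link lists give empty evaluations", {
  s <- make_segment("helix", 10)
  ev <- evaluate_crosslinks(s, tibble::tibble(res_a = integer(),
                                              res_b = integer()))
  expect_equal(nrow(ev), 0)
})

test_that("disulfide evaluation enforces cysteine and the S-S bound", {
  sg <- function(resno, x) {
    tibble::tibble(chain = "A", resno = as.integer(resno), resname = "CYS",
                   atom = c("CA", "SG"), x = c(x, x), y = c(0, 0.5),
                   z = 0, element = c("C", "S"))
  }
  s <- dplyr::bind_rows(sg(10, 0), sg(20, 16))
  ev <- evaluate_disulfides(s, tibble::tibble(cys_a = 10, cys_b = 20))
  expect_equal(as.character(ev$category), "violated")
  expect_equal(ev$distance, 16)

  close_pair <- dplyr::bind_rows(sg(10, 0), sg(20, 2.05))
  ev2 <- evaluate_disulfides(close_pair, tibble::tibble(cys_a = 10, cys_b = 20))
  expect_equal(as.character(ev2$category), "satisfied")

  boundary <- dplyr::bind_rows(sg(10, 0), sg(20, 5.6))
  ev3 <- evaluate_disulfides(boundary, tibble::tibble(cys_a = 10, cys_b = 20))
  expect_equal(as.character(ev3$category), "satisfied")

  notcys <- dplyr::bind_rows(sg(10, 0),
                             ca_atom(20, 3, 0, 0, resname = "LYS"))
  expect_error(evaluate_disulfides(notcys, tibble::tibble(cys_a = 10, cys_b = 20)),
               "not CYS", class = "xlinkr_residue_error")
})

test_that("Calpha-only models fall back to a flagged CA bound", {
  s <- dplyr::bind_rows(ca_atom(10, 0, 0, 0, resname = "CYS"),
                        ca_atom(20, 6, 0, 0, resname = "CYS"))
  ev <- evaluate_disulfides(s, tibble::tibble(cys_a = 10, cys_b = 20))
  expect_true(ev$fallback)
  expect_equal(ev$atom_a, "CA")
  expect_equal(as.character(ev$category), "satisfied")  # 6 <= 7.5 fallback bound
})

test_that("canonicalization dedupes orientation-independent pairs", {
  links <- tibble::tibble(res_a = c(5, 9, 2, 2), res_b = c(9, 5, 2, 7))
  out <- canonicalize_links(links)
  expect_equal(nrow(out), 2)           # (5,9) twice collapsed, (2,2) dropped
  expect_true(all(out$res_a < out$res_b))
})
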