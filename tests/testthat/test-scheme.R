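test_that("residue counting over inclusive ranges", {
  expect_equal(residue_count(c(28, 1017)), 990L)
  expect_equal(residue_count(tibble::tibble(start = c(2901, 3341, 3718),
                                            end = c(2928, 3379, 4057))), 407L)
  expect_equal(residue_count(c(42, 42)), 1L)
  expect_error(residue_count(c(10, 5)), class = "xlinkr_range_error")
})

test_that("packaged apoB scheme reproduces the printed bookkeeping", {
  sch <- apob_scheme()
  subunits <- paste("subunit", c("I", "II", "III", "IV", "V"))
  counts <- vapply(subunits, function(s) {
    residue_count(dplyr::filter(tibble::as_tibble(sch), segment == s))
  }, integer(1))
  expect_equal(unname(counts), c(990L, 1055L, 478L, 1507L, 506L))
  expect_equal(sum(counts), 4536L)
  # fractions sum to 100 within rounding
  fr <- vapply(subunits, function(s) coverage_fraction(sch, s), numeric(1))
  expect_equal(unname(fr), c(21.8, 23.2, 10.5, 33.2, 11.2), tolerance = 0.05)
  expect_lt(abs(sum(fr) - 100), 0.3)
  # named domain/coil counts
  count_of <- function(s) {
    residue_count(dplyr::filter(tibble::as_tibble(sch), segment == s))
  }
  expect_equal(count_of("subunit II coil"), 483L)
  expect_equal(count_of("subunit II domain 1"), 572L)
  expect_equal(count_of("subunit IV domain 3"), 407L)
  # coverage mask excludes the unmodeled stretches of subunit IV
  expect_false(2560 %in% sch$coverage)
  expect_true(2591 %in% sch$coverage)
})

test_that("locate places residues per level and flags outside", {
  sch <- apob_scheme()
  loc <- locate_residue(sch, c(763, 27, 2285, 3400))
  expect_equal(loc$subunit[1], "subunit I")
  expect_true(loc$outside[2])            # signal peptide
  expect_equal(loc$subunit[3], "subunit III")
  expect_true(is.na(loc$domain[3]))      # inter-domain gap 2274-2292
  expect_equal(loc$domain[4], "subunit IV domain 2")
})

test_that("topology classification matches the subunit architecture", {
  sch <- apob_scheme()
  links <- tibble::tibble(res_a = c(763, 1087, 3682, 3400),
                          res_b = c(1324, 1121, 4103, 3500))
  topo <- classify_topology(sch, links)$topology
  expect_equal(as.character(topo),
               c("inter-subunit",   # I to II
                 "intra-subunit",   # both in the subunit II coil
                 "inter-subunit",   # IV to V
                 "intra-domain"))   # both in subunit IV domain 2
  expect_error(classify_topology(sch, tibble::tibble(res_a = 5, res_b = 100)),
               class = "xlinkr_range_error")
})

test_that("locate and topology agree on inter-subunit calls", {
  sch <- apob_scheme()
  set.seed(31)
  links <- tibble::tibble(res_a = sample(28:4563, 60),
                          res_b = sample(28:4563, 60))
  links <- links[links$res_a != links$res_b, ]
  topo <- classify_topology(sch, links)$topology
  la <- locate_residue(sch, links$res_a)$subunit
  lb <- locate_residue(sch, links$res_b)$subunit
  expect_equal(topo == "inter-subunit", la != lb)
})

test_that("scheme validation catches bad input", {
  expect_error(new_scheme(tibble::tibble(segment = "x", level = "subunit",
                                         start = 10, end = 5), c(1, 100)),
               class = "xlinkr_range_error")
  expect_error(new_scheme(tibble::tibble(segment = c("a", "b"),
                                         level = "subunit",
                                         start = c(1, 40), end = c(50, 90)),
                          c(1, 100)),
               class = "xlinkr_range_error")  # overlap within a level
  expect_error(new_scheme(tibble::tibble(segment = "a", level = "blob",
                                         start = 1, end = 5), c(1, 100)),
               class = "xlinkr_input_error")
})

test_that("scheme files round trip through YAML and JSON", {
  sch <- apob_scheme()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_scheme(sch, path)
    back <- read_scheme(path)
    expect_equal(back$segments, sch$segments)
    expect_equal(back$span, sch$span)
    expect_equal(sort(back$coverage), sort(sch$coverage))
  }
})
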