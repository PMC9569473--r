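obs_row <- function(peptide, start, end, replicate, condition) {
  tibble::tibble(peptide = peptide, start = start, end = end,
                 replicate = replicate, condition = condition)
}

# a peptide detected in the given replicates per condition
detections <- function(peptide, start, end, unpainted = 1:3, painted = 1:3) {
  dplyr::bind_rows(
    purrr::map_dfr(unpainted, ~obs_row(peptide, start, end, .x, "unpainted")),
    purrr::map_dfr(painted, ~obs_row(peptide, start, end, .x, "painted"))
  )
}

test_that("paint-positive needs full unpainted presence and painted absence", {
  obs <- dplyr::bind_rows(
    detections("AAAK", 10, 13, unpainted = 1:3, painted = integer()),
    detections("GGGR", 30, 33, unpainted = 1:2, painted = integer()),
    detections("CCCK", 50, 53, unpainted = 1:3, painted = 2)
  )
  out <- paint_regions(obs, n_replicates = 3)
  expect_equal(out, tibble::tibble(start = 10L, end = 13L))
})

test_that("overlapping paint-positive peptides merge", {
  obs <- dplyr::bind_rows(
    detections("A", 10, 25, painted = integer()),
    detections("B", 20, 40, painted = integer())
  )
  expect_equal(paint_regions(obs),
               tibble::tibble(start = 10L, end = 40L))
})

test_that("adding a painted detection can only shrink the output", {
  set.seed(14)
  seqn <- paste(sample(c("A", "G", "K", "R", "S", "L"), 120, replace = TRUE),
                collapse = "")
  obs <- make_painting_dataset(seqn, tibble::tibble(start = 20, end = 60),
                               dropout = 0)
  base_regions <- paint_regions(obs, seqn)
  base_cov <- sum(base_regions$end - base_regions$start + 1)
  positives <- unique(obs[obs$condition == "unpainted", c("peptide", "start", "end")])
  for (i in seq_len(min(5, nrow(positives)))) {
    extra <- obs_row(positives$peptide[i], positives$start[i],
                     positives$end[i], 1, "painted")
    shrunk <- paint_regions(dplyr::bind_rows(obs, extra), seqn)
    expect_lte(sum(shrunk$end - shrunk$start + 1), base_cov)
  }
})

test_that("replicate counts beyond n_replicates are rejected", {
  obs <- detections("AAAK", 10, 13, unpainted = 1:4, painted = integer())
  expect_error(paint_regions(obs, n_replicates = 3),
               class = "xlinkr_input_error")
})

test_that("peptides must match the sequence when it is given", {
  obs <- detections("ZZZZ", 1, 4, painted = integer())
  expect_error(paint_regions(obs, sequence = "AAAAGGGG"),
               class = "xlinkr_input_error")
})

test_that("zero dropout recovers the peptide-resolution exposed coverage", {
  seqn <- paste(rep("AAAKGGGRCCCKDDDKEEER", 5), collapse = "")
  exposed <- tibble::tibble(start = c(10, 55), end = c(30, 70))
  obs <- make_painting_dataset(seqn, exposed, dropout = 0)
  got <- paint_regions(obs, seqn)
  # oracle: interval union of the digest peptides overlapping the ranges
  peps <- digest(seqn, missed_cleavages = 0, min_len = 1)
  overlapping <- peps[purrr::map_lgl(seq_len(nrow(peps)), function(i) {
    any(peps$start[i] <= exposed$end & peps$end[i] >= exposed$start)
  }), ]
  expected <- overlapping |>
    dplyr::arrange(start) |>
    (\(df) {
      out <- df[1, c("start", "end")]
      for (i in seq_len(nrow(df))[-1]) {
        if (df$start[i] <= out$end[nrow(out)] + 1) {
          out$end[nrow(out)] <- max(out$end[nrow(out)], df$end[i])
        } else {
          out <- rbind(out, df[i, c("start", "end")])
        }
      }
      out
    })()
  expect_equal(got, tibble::as_tibble(expected))
})

test_that("total unpainted dropout empties the output", {
  seqn <- paste(rep("AAAKGGGR", 6), collapse = "")
  obs <- make_painting_dataset(seqn, tibble::tibble(start = 5, end = 20),
                               dropout = 1)
  expect_equal(nrow(paint_regions(obs)), 0)
})

test_that("mono-link concordance counts sites inside painted ranges", {
  ranges <- tibble::tibble(start = c(10, 50), end = c(20, 60))
  expect_equal(monolink_concordance(c(12, 15, 55), ranges), 1.0)
  expect_true(is.na(monolink_concordance(integer(), ranges)))
  expect_equal(monolink_concordance(c(12, 15, 55, 58, 59, 60, 11, 19, 100, 200),
                                    ranges), 0.8)
})

test_that("observation tables round trip through TSV", {
  obs <- detections("AAAK", 10, 13, painted = integer())
  path <- tempfile(fileext = ".tsv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$peptide, obs$peptide)
  expect_equal(back$start, obs$start)

  rf <- tempfile(fileext = ".txt")
  write_ranges(tibble::tibble(start = 10, end = 40), rf)
  expect_match(readLines(rf), "painted\t10\t40")
})
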