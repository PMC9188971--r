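test_that("compute_mpsc averages the 5-8 s window and z-scores across voxels", {
  vals <- array(0, dim = c(2L, 2L, 12L))
  # trial 1: voxel 1 reads 1 and voxel 2 reads 3 throughout images 5-8
  vals[1L, 1L, 6:9] <- 1
  vals[1L, 2L, 6:9] <- 3
  # trial 2 (block 2): same pattern swapped, plus junk outside the window
  vals[2L, 1L, 6:9] <- 3
  vals[2L, 2L, 6:9] <- 1
  vals[, , c(1:5, 10:12)] <- stats::rnorm(2 * 2 * 8) * 100
  ts <- trial_timeseries(vals, onsets = c(0L, 0L),
                         trial_labels = c("a", "a"),
                         presentation_block = c(1L, 2L))
  m <- compute_mpsc(ts, window_offset = 5, window_length = 4)
  # (1, 3) z-scored with sample SD: +/- 1/sqrt(2)
  expect_equal(m[1L, "a", ], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(m[2L, "a", ], c(1, -1) / sqrt(2), tolerance = 1e-12)
})

test_that("compute_mpsc rejects bad windows, duplicate concepts, flat trials", {
  vals <- array(1, dim = c(2L, 3L, 10L))
  vals[, 2L, ] <- 2; vals[, 3L, ] <- 3
  ts <- trial_timeseries(vals, onsets = c(0L, 3L),
                         trial_labels = c("a", "b"),
                         presentation_block = c(1L, 1L))
  expect_error(compute_mpsc(ts, window_offset = 5, window_length = 4),
               "window exceeds trial span.*2")
  expect_error(
    trial_timeseries(vals, onsets = c(0L, 0L), trial_labels = c("a", "a"),
                     presentation_block = c(1L, 1L)),
    "duplicate concept within block 1")
  flat <- array(7, dim = c(1L, 3L, 10L))
  ts2 <- trial_timeseries(flat, onsets = 0L, trial_labels = "a",
                          presentation_block = 1L)
  expect_error(compute_mpsc(ts2), "zero trial variance")
})

test_that("per-trial z-scoring is idempotent and normalization is validated", {
  set.seed(1)
  x <- matrix(stats::rnorm(60), 6L)
  z1 <- ztrial(x)
  expect_equal(ztrial(z1), z1, tolerance = 1e-10)
  expect_equal(unname(rowMeans(z1)), rep(0, 6L), tolerance = 1e-12)
  expect_equal(unname(apply(z1, 1L, stats::sd)), rep(1, 6L),
               tolerance = 1e-12)

  ds <- handmade_dataset()
  ok <- activation_dataset(ds$data, ds$participant_ids, ds$language,
                           ds$grid, ds$concepts, check = TRUE)
  expect_s3_class(ok, "activation_dataset")
  bad <- ds$data
  bad[1L, 1L, 1L, ] <- bad[1L, 1L, 1L, ] + 5   # breaks mean-0
  expect_error(
    activation_dataset(bad, ds$participant_ids, ds$language, ds$grid,
                       ds$concepts, check = TRUE),
    "normalization violated")
})

test_that("average_presentations is linear and validates its subset", {
  ds <- handmade_dataset(n_participants = 1L, n_blocks = 6L, noise_sd = 0.3)
  all6 <- average_presentations(ds)[[1L]]
  h1 <- average_presentations(ds, 1:3)[[1L]]
  h2 <- average_presentations(ds, 4:6)[[1L]]
  expect_equal(all6, (h1 + h2) / 2, tolerance = 1e-12)
  expect_error(average_presentations(ds, integer(0)), "nonempty")

  # two blocks holding v and -v average to zero
  v <- ztrial(matrix(stats::rnorm(12L), 3L))
  dat <- array(NA_real_, c(1L, 2L, 3L, 4L),
               dimnames = list(NULL, NULL, paste0("c", 1:3), NULL))
  dat[1L, 1L, , ] <- v; dat[1L, 2L, , ] <- -v
  cs <- concept_set(paste0("c", 1:3),
                    stats::setNames(rep("x", 3L), paste0("c", 1:3)))
  ds2 <- activation_dataset(dat, "p1", "test", voxel_grid(c(4L, 1L, 1L)),
                            cs, check = FALSE)
  expect_equal(unname(average_presentations(ds2)[[1L]]),
               matrix(0, 3L, 4L), tolerance = 1e-12)
})

test_that("cohort write/read round trip is lossless and realigns by label", {
  sim <- simulate_cohorts(tiny_spec(seed = 7L))
  ds <- sim$cohorts[[1L]]
  dir <- withr::local_tempdir()
  manifest <- write_cohort(ds, dir)
  back <- read_cohort(manifest)
  expect_identical(back$data, ds$data)
  expect_identical(back$participant_ids, ds$participant_ids)
  expect_identical(back$language, ds$language)
  expect_identical(back$concepts$labels, ds$concepts$labels)

  # permute concept rows in one file: reader realigns by label
  f <- file.path(dir, sprintf("%s_block01.csv", ds$participant_ids[1L]))
  tab <- utils::read.csv(f, check.names = FALSE)
  perm <- sample(nrow(tab))
  utils::write.csv(tab[perm, ], f, row.names = FALSE, quote = FALSE)
  back2 <- read_cohort(manifest)
  expect_equal(back2$data, ds$data, tolerance = 1e-12)

  # manifest must carry the required keys
  man <- jsonlite::read_json(manifest)
  man$language <- NULL
  broken <- file.path(dir, "broken.json")
  jsonlite::write_json(man, broken, auto_unbox = FALSE)
  expect_error(read_cohort(broken), "language")
})

test_that("default concept set has 7 categories x 4 concepts", {
  cs <- default_concepts()
  expect_length(cs$labels, 28L)
  expect_equal(unname(table(cs$categories)), rep(4L, 7L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(cs$labels) > 0L)
})

test_that("word_length_measure handles single, combined and degenerate cases", {
  labs <- paste0("w", 1:6)
  cats <- stats::setNames(rep("x", 6L), labs)
  a <- concept_set(labs, cats, stats::setNames(c(4, 4, 4, 4, 4, 4), labs))
  expect_equal(unname(word_length_measure(list(a, a), "combined")),
               rep(0, 6L))
  b <- concept_set(labs, cats, stats::setNames(c(2, 9, 4, 12, 7, 3), labs))
  comb <- word_length_measure(list(a, b), "combined")
  # with one degenerate (constant) table the combined measure is half the
  # other table's z-scores
  expect_equal(comb, scale(b$word_length)[, 1L] / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(word_length_measure(concept_set(labs, cats), "single"),
               "no word lengths")
  expect_error(word_length_measure(a, "combined"), "two concept sets")
})
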