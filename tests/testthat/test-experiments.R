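test_that("an unrandomized trajectory point is exactly degenerate", {
  tr <- randomization_trajectory(20, seed = 1, reps = 2, m_solutions = 4,
                                 swap_levels = 0)
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$normalized_median_sum == 0))
  expect_true(all(tr$mean_solution_distance == 0))
  # identical inputs: spread 0, pinned as middle
  expect_true(all(tr$middle_count == 4L))
  expect_true(all(tr$valid))
})

test_that("trajectories are reproducible and respect the invariants", {
  args <- list(n = 24, seed = 314, reps = 2, m_solutions = 4,
               swap_levels = c(0, 50, 200))
  a <- do.call(randomization_trajectory, args)
  b <- do.call(randomization_trajectory, args)
  expect_identical(a, b)
  expect_true(all(a$normalized_median_sum <= a$k))
  expect_true(all(a$corner_1 + a$corner_2 + a$corner_3 + a$middle_count ==
                    a$m_solutions))
  # saturation: the scrambled end sits far above the start
  s <- saturation_summary(a, from = 200)
  expect_gt(s$normalized_median_sum, 1.5)
  expect_lte(s$normalized_median_sum, 2)
  expect_gt(s$mean_solution_distance, 0.3)
  expect_lte(s$mean_solution_distance, 2 / 3)
})

test_that("higher k trajectories respect the k - 1 and (k-1)/k ceilings", {
  tr <- higher_k_trajectory(21, k_values = c(3, 4), seed = 27, reps = 1,
                            m_solutions = 4, swap_levels = c(0, 200))
  k4 <- tr[tr$k == 4, ]
  expect_true(all(k4[k4$swaps_per_100 == 0, "normalized_median_sum"] == 0))
  sat4 <- k4[k4$swaps_per_100 == 200, ]
  expect_lt(sat4$mean_solution_distance, 3 / 4)
  expect_lte(sat4$normalized_median_sum, 3)
  expect_gt(sat4$normalized_median_sum, 2)
  # corner counts cover all four inputs' columns
  expect_true(all(c("corner_1", "corner_4") %in% names(tr)))
})

test_that("corner census records classify every sampled solution", {
  cc <- corner_middle_experiment(c(15, 30), reps = 2, m_solutions = 5, seed = 8)
  expect_equal(nrow(cc), 4L)
  expect_true(all(cc$valid))
  expect_true(all(cc$middle_count + cc$corner_1 + cc$corner_2 + cc$corner_3 ==
                    cc$solutions_per_instance))
  expect_true(all(cc$middle_fraction >= 0 & cc$middle_fraction <= 1))
  expect_true(all(cc$mean_nearest_input_distance >= 0 &
                    cc$mean_nearest_input_distance <= 1))
})

test_that("corner accumulation is exchangeable across the three inputs", {
  # no presentation-order artifact: totals per corner are uniform
  tr <- randomization_trajectory(40, seed = 97, reps = 10, m_solutions = 10,
                                 swap_levels = 250)
  counts <- c(sum(tr$corner_1), sum(tr$corner_2), sum(tr$corner_3))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("record export round-trips exactly and carries the schema", {
  tr <- randomization_trajectory(15, seed = 6, reps = 1, m_solutions = 3,
                                 swap_levels = c(0, 100))
  path <- file.path(withr::local_tempdir(), "records")
  files <- summarize_and_export(tr, path)
  expect_true(all(file.exists(files)))
  back <- read_experiment_records(path)
  expect_identical(back$normalized_median_sum, tr$normalized_median_sum)
  expect_identical(back$mean_solution_distance, tr$mean_solution_distance)
  expect_identical(back$middle_count, tr$middle_count)
  expect_setequal(names(back), names(tr))
  cfg <- attr(back, "config")
  expect_equal(cfg$seed, 6)
  expect_equal(cfg$mode, "exact")
  expect_error(summarize_and_export(tr[0, ], path), "non-empty")
})
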