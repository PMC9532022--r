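# Small helper: an individual-trajectory list entry offset from the
# template's reference points.
offset_traj <- function(tpl, offset, name = "ellipse") {
  list(subject_id = "x", template_name = name,
       segment_index = 1L, aligned_points = tpl$ref_points + offset,
       bin_counts = rep(1L, nrow(tpl$ref_points)))
}

test_that("aggregating one trajectory is the identity", {
  tpl <- segment_template("ellipse", n_ref = 10)
  tr <- offset_traj(tpl, cbind(rnorm(10), rnorm(10)))
  agg <- aggregate_trajectories(list(tr))
  expect_equal(agg$aligned_points, tr$aligned_points)
  expect_identical(agg$n_contributing, rep(1L, 10L))
})

test_that("symmetric offsets cancel under mean aggregation", {
  tpl <- segment_template("ellipse", n_ref = 10)
  d <- cbind(rep(3, 10), rep(-2, 10))
  agg <- aggregate_trajectories(list(offset_traj(tpl, d),
                                     offset_traj(tpl, -d)),
                                method = "mean")
  expect_equal(agg$aligned_points, tpl$ref_points)
  expect_equal(error_profile(agg, tpl)$mean_error, 0)
})

test_that("the median resists a single displaced trajectory, the mean does not", {
  tpl <- segment_template("ellipse", n_ref = 10)
  trajs <- c(replicate(9, offset_traj(tpl, 0), simplify = FALSE),
             list(offset_traj(tpl, cbind(rep(50, 10), 0))))
  med <- aggregate_trajectories(trajs, method = "median")
  expect_equal(med$aligned_points, tpl$ref_points)
  avg <- aggregate_trajectories(trajs, method = "mean")
  expect_equal(error_profile(avg, tpl)$per_bin_error, rep(5, 10))

  # robustness to an arbitrary outlier at one bin (>= 3 inputs)
  trio <- replicate(3, offset_traj(tpl, cbind(rnorm(10, 0, 0.1), 0)),
                    simplify = FALSE)
  base <- aggregate_trajectories(trio)$aligned_points
  trio[[2L]]$aligned_points[4L, ] <- c(1e6, -1e6)
  bent <- aggregate_trajectories(trio)$aligned_points
  expect_equal(bent[-4L, ], base[-4L, ])
})

test_that("aggregation is permutation-invariant and type-checked", {
  tpl <- segment_template("ellipse", n_ref = 10)
  set.seed(2)
  trajs <- replicate(5, offset_traj(tpl, cbind(rnorm(10), rnorm(10))),
                     simplify = FALSE)
  a <- aggregate_trajectories(trajs)
  b <- aggregate_trajectories(rev(trajs))
  expect_equal(a$aligned_points, b$aligned_points)
  trajs[[2L]]$template_name <- "lemniscate"
  expect_error(aggregate_trajectories(trajs), "different templates")
  expect_error(aggregate_trajectories(list()), "no trajectories")
})

test_that("missing bins aggregate over the available inputs only", {
  tpl <- segment_template("ellipse", n_ref = 6)
  t1 <- offset_traj(tpl, 0); t2 <- offset_traj(tpl, cbind(rep(2, 6), 0))
  t1$aligned_points[2L, ] <- NA
  t2$aligned_points[c(2L, 5L), ] <- NA
  agg <- aggregate_trajectories(list(t1, t2), method = "mean")
  expect_identical(agg$n_contributing, c(2L, 0L, 2L, 2L, 1L, 2L))
  expect_true(all(is.na(agg$aligned_points[2L, ])))
  expect_equal(agg$aligned_points[5L, ], tpl$ref_points[5L, ])  # t1 only
  ep <- error_profile(agg, tpl)
  expect_equal(ep$coverage, 5 / 6)
  expect_true(is.na(ep$per_bin_error[2L]))
})

test_that("error profiles are exact Euclidean distances", {
  tpl <- segment_template("three_petal", n_ref = 20)
  expect_equal(error_profile(tpl$ref_points, tpl)$mean_error, 0)
  shifted <- tpl$ref_points + matrix(rep(c(3, 4), each = 20), ncol = 2)
  ep <- error_profile(shifted, tpl)
  expect_equal(ep$per_bin_error, rep(5, 20))
  expect_equal(ep$mean_error, 5)
  set.seed(4)
  rand <- tpl$ref_points + matrix(rnorm(40), ncol = 2)
  oracle <- bf_errors(rand, tpl$ref_points)
  got <- error_profile(rand, tpl)
  expect_equal(got$per_bin_error, oracle$per_bin, tolerance = 1e-12)
  expect_equal(got$mean_error, oracle$mean, tolerance = 1e-12)
  expect_error(error_profile(matrix(NA_real_, 20, 2), tpl), "non-missing")
  expect_error(error_profile(matrix(0, 7, 2), tpl), "does not match")
})

test_that("regional error maps decompose into their definitions", {
  tpl <- segment_template("ellipse", n_ref = 15)
  set.seed(7)
  trajs <- replicate(6, offset_traj(tpl, cbind(rnorm(15), rnorm(15))),
                     simplify = FALSE)
  ind <- regional_error_map(trajs, tpl, "individual-average")
  agg <- regional_error_map(trajs, tpl, "aggregate")
  imp <- regional_error_map(trajs, tpl, "improvement")
  expect_equal(imp, ind - agg)
  # recomputation from stored per-trajectory profiles
  E <- sapply(trajs, function(tr) error_profile(tr, tpl)$per_bin_error)
  expect_equal(ind, rowMeans(E))
  # identical inputs: aggregation changes nothing anywhere
  same <- replicate(4, trajs[[1L]], simplify = FALSE)
  expect_equal(regional_error_map(same, tpl, "improvement"), rep(0, 15))
  # symmetric pair, mean aggregation: improvement d at every bin
  d <- 2.5
  pair <- list(offset_traj(tpl, cbind(rep(d, 15), 0)),
               offset_traj(tpl, cbind(rep(-d, 15), 0)))
  expect_equal(regional_error_map(pair, tpl, "improvement",
                                  method = "mean"), rep(d, 15))
})

test_that("mean aggregation satisfies the convexity bound bin-wise", {
  tpl <- segment_template("four_petal", n_ref = 30)
  for (seed in 1:5) {
    set.seed(seed)
    trajs <- replicate(8, offset_traj(
      tpl, cbind(rnorm(30, 0, 3), rnorm(30, 0, 3))), simplify = FALSE)
    agg_err <- regional_error_map(trajs, tpl, "aggregate", method = "mean")
    ind_err <- regional_error_map(trajs, tpl, "individual-average")
    expect_true(all(agg_err <= ind_err + 1e-12))
  }
})

test_that("median and mean aggregates nearly coincide under symmetric noise", {
  # per-bin |median - mean| of the aggregate stays far below the
  # individual error scale
  tpl <- segment_template("ellipse", n_ref = 25)
  set.seed(12)
  sigma <- 2
  trajs <- replicate(100, offset_traj(
    tpl, matrix(rnorm(50, 0, sigma), ncol = 2)), simplify = FALSE)
  med <- aggregate_trajectories(trajs, "median")$aligned_points
  avg <- aggregate_trajectories(trajs, "mean")$aligned_points
  gap <- sqrt(rowSums((med - avg)^2))
  ind_err <- mean(regional_error_map(trajs, tpl, "individual-average"))
  expect_lt(mean(gap), 0.1 * ind_err)
  # both aggregates sit an order of magnitude below the individual error
  for (m in list(med, avg))
    expect_lt(error_profile(m, tpl)$mean_error, 0.2 * ind_err)
})
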