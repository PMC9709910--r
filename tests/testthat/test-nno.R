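# Molecules whose oleic-mid atoms sit at the given points; the other atoms
# ride along rigidly.
mols_at <- function(centers, box = c(20, 20, 20), time = 0) {
  tpl <- crystal_template()
  coords <- lapply(seq_len(nrow(centers)), function(i) {
    sweep(tpl, 2L, centers[i, ] - tpl["oleic_mid", ], "+")
  })
  frame_snapshot(do.call(rbind, coords), box, time)
}

mols_selection <- function(n) {
  uniform_selection(n, stats::setNames(1:7, tagcryst:::role_names()), 7L)
}

test_that("the neighbor relation is symmetric, inclusive and cutoff-driven", {
  f <- mols_at(rbind(c(5, 5, 5), c(5, 5, 5.9)))
  kp <- extract_key_positions(f, mols_selection(2))
  s <- neighbor_sets(kp, cutoff = 1.0)
  expect_equal(s[["1"]], 2L)
  expect_equal(s[["2"]], 1L)
  # just beyond the cutoff
  f2 <- mols_at(rbind(c(5, 5, 5), c(5, 5, 6.01)))
  s2 <- neighbor_sets(extract_key_positions(f2, mols_selection(2)), 1.0)
  expect_length(s2[["1"]], 0L)
  # single molecule: empty set
  s1 <- neighbor_sets(extract_key_positions(mols_at(rbind(c(5, 5, 5))),
                                            mols_selection(1)), 1.0)
  expect_length(s1[["1"]], 0L)
})

test_that("cell-list neighbor sets equal the all-pairs computation", {
  set.seed(12)
  box <- c(12, 9, 14)
  centers <- cbind(runif(300, 0, box[1]), runif(300, 0, box[2]),
                   runif(300, 0, box[3]))
  kp <- extract_key_positions(mols_at(centers, box), mols_selection(300))
  expect_identical(neighbor_sets(kp, 1.0, method = "cell"),
                   neighbor_sets(kp, 1.0, method = "all"))
})

test_that("NNO counts common neighbors across frame transitions", {
  sel <- mols_selection(2)
  near <- rbind(c(5, 5, 5), c(5, 5, 5.9))
  far <- rbind(c(5, 5, 5), c(5, 5, 9.0))
  # static pair over 3 frames: 2 x 2 matrix of ones
  traj <- trajectory(list(mols_at(near, time = 0), mols_at(near, time = 1),
                          mols_at(near, time = 2)), sel)
  nn <- nno_matrix(traj)
  expect_equal(unname(nn$values), matrix(1L, 2, 2))
  expect_equal(nn$transition_times, c(1, 2))
  # neighbor lost in the second frame: intersection is empty
  traj2 <- trajectory(list(mols_at(near, time = 0), mols_at(far, time = 1)),
                      sel)
  expect_equal(unname(nno_matrix(traj2)$values), matrix(0L, 2, 1))
  # fewer than stride + 1 frames is an error
  expect_error(nno_matrix(traj2, stride = 2), "at least 3 frames")
})

test_that("a frozen trajectory has NNO equal to the neighbor-set size", {
  sys <- build_box(box_spec(lattice_spec("beta2", c(3, 2, 2)), n_melt = 6,
                            seed = 6))
  traj <- make_pseudo_trajectory(sys, n_frames = 4, jitter_sd = 0,
                                 melt_step_nm = 0, seed = 6)
  nn <- nno_matrix(traj)
  sizes <- lengths(neighbor_sets(system_keypos(sys), 1.0))
  for (t in seq_len(ncol(nn$values))) {
    expect_equal(unname(nn$values[, t]), unname(sizes))
  }
})

test_that("NNO is invariant under rigid translation plus box wrapping", {
  sys <- build_box(box_spec(lattice_spec("beta2", c(2, 1, 2)), n_melt = 5,
                            seed = 8))
  traj <- make_pseudo_trajectory(sys, n_frames = 3, jitter_sd = 0.01, seed = 8)
  shifted <- lapply(traj$frames, function(f) {
    frame_snapshot(wrap_positions(f$positions + 3.123, f$box), f$box, f$time)
  })
  nn0 <- nno_matrix(traj)
  nn1 <- nno_matrix(trajectory(shifted, traj$selection))
  expect_equal(nn0$values, nn1$values)
})

test_that("isolated melt molecules have all-zero NNO rows", {
  sel <- mols_selection(4)
  centers <- rbind(c(3, 3, 3), c(3, 3, 3.9),   # a bound pair
                   c(10, 10, 10), c(16, 4, 12))  # two isolated molecules
  traj <- trajectory(list(mols_at(centers, time = 0),
                          mols_at(centers, time = 1)), sel)
  nn <- nno_matrix(traj)
  expect_true(all(nn$values[3:4, ] == 0L))
  expect_true(all(nn$values[1:2, ] == 1L))
})

test_that("interior molecules out-coordinate corner molecules in a 3-D crystal", {
  sys <- build_box(box_spec(lattice_spec("beta2", c(3, 3, 3)), n_melt = 0,
                            seed = 9))
  traj <- make_pseudo_trajectory(sys, n_frames = 3, jitter_sd = 0, seed = 9)
  nn <- nno_matrix(traj)
  # corner: molecule 1 of the first cell; interior: molecule 1 of the
  # central cell (cell 14 of 27 in build order)
  corner <- nn$values[1, ]
  interior <- nn$values[4 * 13 + 1, ]
  expect_true(all(interior > corner))
})

test_that("the heat map writes an image and the raw matrix as CSV", {
  sel <- mols_selection(2)
  near <- rbind(c(5, 5, 5), c(5, 5, 5.9))
  traj <- trajectory(list(mols_at(near, time = 0), mols_at(near, time = 1),
                          mols_at(near, time = 2)), sel)
  nn <- nno_matrix(traj)
  path <- withr::local_tempfile(fileext = ".png")
  nno_heatmap(nn, path)
  expect_true(file.exists(paste0(path, ".csv")))
  csv <- utils::read.csv(paste0(path, ".csv"))
  expect_equal(csv$molecule_id, 1:2)
  expect_equal(unname(as.matrix(csv[, -1])), matrix(1L, 2, 2))
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
})
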