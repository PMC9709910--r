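test_that("lattice molecule counts follow the 4-per-cell construction", {
  b <- build_lattice(lattice_spec("beta2", c(7, 1, 6)))
  expect_equal(b$n_molecules, 168L)
  expect_equal(nrow(b$cells), 42L)
  expect_equal(nrow(b$positions), 7L * 168L)
  expect_equal(build_lattice(lattice_spec("beta1", c(10, 1, 10)))$n_molecules,
               400L)
  b1 <- build_lattice(lattice_spec("beta1", c(1, 1, 1)))
  expect_equal(b1$n_molecules, 4L)
  expect_equal(nrow(b1$cells), 1L)
})

test_that("the reference boxes reproduce the published compositions", {
  sys1 <- build_box1(seed = 1)
  expect_length(sys1$labels, 200L)
  expect_equal(sum(sys1$labels == "crystal_beta2"), 168L)
  expect_equal(sum(sys1$labels == "melt"), 32L)
  sys2 <- build_box2(seed = 1)
  expect_length(sys2$labels, 1200L)
  expect_equal(unname(table(sys2$labels)[c("crystal_beta1", "crystal_beta2",
                                           "melt")]),
               c(400L, 200L, 600L), ignore_attr = TRUE)
})

test_that("each template cell satisfies its own polymorph signature", {
  tbl <- default_signature_table()
  for (poly in c("beta2", "beta1")) {
    sys <- build_box(box_spec(lattice_spec(poly, c(1, 1, 1)), n_melt = 0,
                              seed = 1))
    normals <- orientation_normals(system_keypos(sys))
    expect_equal(classify_candidate(1:4, normals, tbl), poly)
  }
})

test_that("zero-jitter self-calibration classifies every crystal molecule", {
  for (poly in c("beta2", "beta1")) {
    sys <- build_box(box_spec(lattice_spec(poly, c(2, 1, 2)), n_melt = 0,
                              seed = 1))
    traj <- trajectory(list(sys$frame), sys$selection)
    ref <- suppressWarnings(calibrate(traj, cells = sys$cells))
    kp <- system_keypos(sys)
    expect_true(all(classify_parallel(kp, ref)))
    expect_true(all(classify_stretched(kp, ref)))
    fr <- polymorph_frame(kp, ref)
    expect_true(all(fr$assignment == poly))
  }
})

test_that("ground-truth cells are a subset of the enumerated candidates", {
  ref <- shared_reference()
  sys <- build_box(box_spec(list(lattice_spec("beta1", c(2, 1, 2)),
                                 lattice_spec("beta2", c(2, 1, 1))),
                            n_melt = 0, seed = 1))
  cand <- enumerate_unit_cells(system_keypos(sys), ref)
  gt <- apply(as.matrix(sys$cells[, 1:4]), 1L, paste, collapse = "-")
  expect_true(all(gt %in% cand$canonical))
})

test_that("generation is bit-for-bit reproducible from the seed", {
  a <- build_box1(seed = 7)
  b <- build_box1(seed = 7)
  expect_identical(a$frame$positions, b$frame$positions)
  expect_identical(a$kinks, b$kinks)
  c <- build_box1(seed = 8)
  expect_false(identical(a$frame$positions, c$frame$positions))
  ta <- make_pseudo_trajectory(a, n_frames = 4, jitter_sd = 0.01,
                               melt_onset_frame = 2, melt_ramp_frames = 2,
                               seed = 3)
  tb <- make_pseudo_trajectory(b, n_frames = 4, jitter_sd = 0.01,
                               melt_onset_frame = 2, melt_ramp_frames = 2,
                               seed = 3)
  expect_identical(lapply(ta$frames, `[[`, "positions"),
                   lapply(tb$frames, `[[`, "positions"))
})

test_that("melt conformations fail the C bands and respect the separation rule", {
  sys <- build_box1(seed = 5)
  ref <- shared_reference()
  kp <- system_keypos(sys)
  melts <- sys$labels == "melt"
  expect_false(any(classify_parallel(kp, ref)[melts]))
  expect_false(any(classify_stretched(kp, ref)[melts]))
  # oleic-mid separation of melts from everything else
  om <- kp$oleic_mid
  for (m in which(melts)) {
    d <- min_image_distance(om[rep(m, nrow(om) - 1), ],
                            om[-m, , drop = FALSE], kp$box)
    expect_gte(min(d), 0.8)
  }
})

test_that("an over-crowded melt request fails with a generation error", {
  expect_error(build_box(box_spec(list(), n_melt = 400, box = c(4, 4, 4),
                                  seed = 1, melt_min_sep = 0.8)),
               "generation error")
})

test_that("a static pseudo-trajectory is identical frame to frame", {
  sys <- build_box(box_spec(lattice_spec("beta2", c(2, 1, 1)), n_melt = 4,
                            seed = 2))
  traj <- make_pseudo_trajectory(sys, n_frames = 3, jitter_sd = 0,
                                 melt_step_nm = 0, melt_onset_frame = 10,
                                 seed = 2)
  expect_identical(traj$frames[[1]]$positions, traj$frames[[2]]$positions)
  expect_identical(traj$frames[[2]]$positions, traj$frames[[3]]$positions)
  nn <- nno_matrix(traj)
  expect_equal(nn$values[, 1], nn$values[, 2])
})

test_that("progressive melting drives crystallinity down monotonically", {
  ref <- shared_reference()
  sys <- build_box(box_spec(lattice_spec("beta2", c(3, 1, 3)), n_melt = 8,
                            seed = 3))
  traj <- make_pseudo_trajectory(sys, n_frames = 24, jitter_sd = 0,
                                 melt_onset_frame = 8, melt_ramp_frames = 10,
                                 melt_step_nm = 0.08, seed = 3)
  cr <- crystallinity_timeseries(traj, ref)
  after <- cr$summary$pct_parallel[8:24]
  expect_true(all(diff(after) <= 0))
  expect_lt(cr$summary$pct_parallel[24], 5)
  expect_true(all(diff(cr$summary$pct_stretched[8:24]) <= 0))
  # before onset the crystal is intact
  expect_equal(cr$summary$pct_parallel[1], 100 * 36 / 44)
})
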