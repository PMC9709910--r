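normals_from <- function(...) {
  n <- rbind(...)
  list(molecule_id = seq_len(nrow(n)), normal = n,
       degenerate = rowSums(n * n) < 1e-18)
}

test_that("the oleic-plane normal follows the kink handedness", {
  up <- orientation_normal(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_false(up$degenerate)
  expect_equal(up$normal / sqrt(sum(up$normal^2)), matrix(c(0, 0, 1), 1))
  down <- orientation_normal(c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(down$normal / sqrt(sum(down$normal^2)), matrix(c(0, 0, -1), 1))
  col <- orientation_normal(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(col$degenerate)
})

test_that("rotation signs compare kink orientations, flagging orthogonality", {
  expect_equal(rotation_sign(c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(rotation_sign(c(0, 0, 1), c(0, 0, -1)), -1)
  expect_true(is.na(rotation_sign(c(0, 0, 1), c(1, 0, 0))))
  # magnitude-normalized: scale must not matter
  expect_equal(rotation_sign(c(0, 0, 5), c(0, 0, -0.01)), -1)
})

test_that("signature classification separates the polymorphs", {
  tbl <- default_signature_table()
  z <- c(0, 0, 1)
  # sides pointing the same way -> beta2
  expect_equal(classify_candidate(1:4, normals_from(z, -z, z, -z), tbl),
               "beta2")
  # sides opposed -> beta1
  expect_equal(classify_candidate(1:4, normals_from(z, -z, -z, z), tbl),
               "beta1")
  # orthogonal normal -> indeterminate -> none
  expect_equal(classify_candidate(1:4, normals_from(z, c(1, 0, 0), z, -z), tbl),
               "none")
  # degenerate normal -> none
  expect_equal(classify_candidate(1:4, normals_from(z, 0 * z, z, -z), tbl),
               "none")
  # s14 inconsistent with s12 * s13 -> none
  expect_equal(classify_candidate(1:4, normals_from(z, -z, z, z), tbl),
               "none")
})

test_that("within-side role swaps preserve the polymorph label", {
  tbl <- default_signature_table()
  z <- c(0, 0, 1)
  for (pat in list(list(normals_from(z, -z, z, -z), "beta2"),
                   list(normals_from(z, -z, -z, z), "beta1"))) {
    expect_equal(classify_candidate(c(2, 1, 4, 3), pat[[1]], tbl), pat[[2]])
    expect_equal(classify_candidate(1:4, pat[[1]], tbl), pat[[2]])
  }
})

test_that("signature tables round-trip through YAML and can be overridden", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("require_consistency: false", "patterns:",
               "  - label: alpha", "    s12: 1", "    s13: 1", "    s14: 1"),
             path)
  tbl <- read_signature_table(path)
  expect_false(tbl$require_consistency)
  z <- c(0, 0, 1)
  expect_equal(classify_candidate(1:4, normals_from(z, z, z, z), tbl), "alpha")
  expect_equal(classify_candidate(1:4, normals_from(z, -z, z, -z), tbl), "none")
})

test_that("the unpruned search space grows as n(n-1)(n-2)(n-3)", {
  expect_equal(search_space_size(4), 24)
  expect_equal(search_space_size(1000), 994010994000)
})

test_that("a single idealized cell is recovered with its constructed roles", {
  ref <- shared_reference()
  for (poly in c("beta2", "beta1")) {
    sys <- build_box(box_spec(lattice_spec(poly, c(1, 1, 1)), n_melt = 0,
                              seed = 1))
    kp <- system_keypos(sys)
    cand <- enumerate_unit_cells(kp, ref)
    expect_true(tagcryst:::canonical_key(1:4) %in% cand$canonical)
    fr <- polymorph_frame(kp, ref)
    expect_true(all(fr$labeled$label == poly))
    expect_true(all(fr$assignment == poly))
  }
})

test_that("an all-melt box yields no candidate pairs and no cells", {
  ref <- shared_reference()
  sys <- build_box(box_spec(list(), n_melt = 10, box = c(16, 16, 16),
                            seed = 5))
  kp <- system_keypos(sys)
  expect_equal(nrow(candidate_pairs(kp, ref)), 0L)
  expect_equal(nrow(enumerate_unit_cells(kp, ref)), 0L)
  fr <- polymorph_frame(kp, ref)
  expect_true(all(fr$assignment == "melt"))
  expect_equal(fr$pct_beta1 + fr$pct_beta2, 0)
})

test_that("candidate side pairs from the cell list match the all-pairs scan", {
  ref <- shared_reference()
  sys <- build_box(box_spec(lattice_spec("beta1", c(2, 1, 2),
                                         jitter_sd = 0.01, seed = 11),
                            n_melt = 10, seed = 11))
  kp <- system_keypos(sys)
  a <- candidate_pairs(kp, ref, method = "cell")
  b <- candidate_pairs(kp, ref, method = "all")
  key <- function(p) sort(paste(p$a, p$b))
  expect_equal(key(a), key(b))
})

test_that("pruned enumeration equals the brute-force oracle on mixed fixtures", {
  ref <- shared_reference()
  for (seed in c(21, 22, 23)) {
    sys <- random_small_system(seed)
    kp <- system_keypos(sys)
    expect_setequal(enumerate_unit_cells(kp, ref)$canonical,
                    brute_force_unit_cells(kp, ref)$canonical)
  }
})

test_that("the brute-force oracle refuses oversized systems", {
  ref <- shared_reference()
  sys <- build_box(box_spec(lattice_spec("beta2", c(4, 1, 4)), n_melt = 0,
                            seed = 1))
  expect_error(brute_force_unit_cells(system_keypos(sys), ref), "n > 60")
})

test_that("the ledger accumulates detections and resolves by majority", {
  led <- accumulate_ledger(
    data.frame(m1 = 1L, m2 = 2L, m3 = 3L, m4 = 4L, label = "beta2"),
    molecule_ids = 1:6)
  expect_equal(unname(led[, "beta2"]), c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(sum(led[, "beta1"]), 0L)
  # molecule 1 in three beta1 cells and one beta2 cell
  led2 <- accumulate_ledger(
    data.frame(m1 = c(1L, 1L, 1L, 1L), m2 = c(2L, 2L, 5L, 2L),
               m3 = c(3L, 6L, 3L, 3L), m4 = c(4L, 4L, 4L, 6L),
               label = c("beta1", "beta1", "beta1", "beta2")),
    molecule_ids = 1:6)
  expect_equal(unname(led2[1, ]), c(3L, 1L))
  res <- assign_polymorphs(led2)
  expect_equal(as.character(res$assignment[1]), "beta1")
  # empty candidate list: all melt
  led0 <- accumulate_ledger(
    data.frame(m1 = integer(), m2 = integer(), m3 = integer(),
               m4 = integer(), label = character()), 1:4)
  res0 <- assign_polymorphs(led0)
  expect_true(all(res0$assignment == "melt"))
  expect_equal(res0$pct_beta1, 0)
})

test_that("assignment follows the rule table including ties", {
  led <- matrix(c(3L, 0L, 2L, 0L,
                  1L, 2L, 2L, 0L), ncol = 2,
                dimnames = list(1:4, c("beta1", "beta2")))
  res <- assign_polymorphs(led)
  expect_equal(as.character(res$assignment), c("beta1", "beta2", "tie", "melt"))
  expect_equal(unname(res$scores[3, ]), c(0.5, 0.5))
  expect_equal(res$pct_beta1, 100 * 1.5 / 4)
  expect_equal(res$pct_beta2, 100 * 1.5 / 4)
})

test_that("classification is invariant under rigid rotation and translation", {
  ref <- shared_reference()
  sys <- build_box(box_spec(list(lattice_spec("beta1", c(2, 1, 1)),
                                 lattice_spec("beta2", c(1, 1, 2))),
                            n_melt = 6, seed = 13))
  kp <- system_keypos(sys)
  fr0 <- polymorph_frame(kp, ref)
  # rotate about the box center inside a generously padded cube so the
  # minimum image never engages
  big <- c(60, 60, 60)
  pos <- sys$frame$positions
  set.seed(13)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  center <- matrix(colMeans(pos), nrow(pos), 3, byrow = TRUE)
  pos_rot <- (pos - center) %*% t(R) + 30
  kp_rot <- extract_key_positions(frame_snapshot(pos_rot, big, 0),
                                  sys$selection)
  kp_big <- extract_key_positions(frame_snapshot(pos - center + 30, big, 0),
                                  sys$selection)
  fr_big <- polymorph_frame(kp_big, ref)
  fr_rot <- polymorph_frame(kp_rot, ref)
  expect_setequal(fr_rot$labeled$canonical, fr_big$labeled$canonical)
  expect_equal(fr_rot$ledger, fr_big$ledger)
  expect_equal(as.character(fr_rot$assignment), as.character(fr0$assignment))
})

test_that("melts far outside the P1 band are always assigned melt", {
  ref <- shared_reference()
  sys <- build_box(box_spec(lattice_spec("beta2", c(2, 1, 2),
                                         jitter_sd = 0.008, seed = 17),
                            n_melt = 12, seed = 17))
  fr <- polymorph_frame(system_keypos(sys), ref)
  expect_true(all(fr$assignment[sys$labels == "melt"] == "melt"))
  p <- fr$pct_beta1 + fr$pct_beta2
  expect_true(p >= 0 && p <= 100)
})

test_that("the cumulative ledger mode accumulates detections over frames", {
  ref <- shared_reference()
  sys <- build_box(box_spec(lattice_spec("beta2", c(2, 1, 1)), n_melt = 0,
                            seed = 19))
  traj <- make_pseudo_trajectory(sys, n_frames = 3, jitter_sd = 0.005,
                                 seed = 19)
  per <- polymorph_timeseries(traj, ref)
  cum <- polymorph_timeseries(traj, ref, cumulative = TRUE)
  expect_equal(cum$ledgers[[3]], Reduce(`+`, per$ledgers))
  expect_equal(per$summary$pct_beta2, rep(100, 3))
})
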