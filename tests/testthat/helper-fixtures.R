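# Shared fixtures, built in code. The calibrated reference is computed once
# per test run (thermally jittered pure beta-2 lattice) and reused.

.fixture_cache <- new.env()

shared_reference <- function() {
  if (is.null(.fixture_cache$ref)) {
    .fixture_cache$ref <- calibrate_reference(seed = 101)
  }
  .fixture_cache$ref
}

# A hand-assembled reference with chosen means/sds, for band-logic tests.
manual_reference <- function(keys, means, sds, multiplier = 2) {
  ref <- data.frame(key = keys, mean = means, sd = sds,
                    n_samples = 100L, multiplier = multiplier)
  class(ref) <- c("tag_reference", "data.frame")
  ref
}

# Key positions for hand-placed molecules: `coords` is a list with one
# 7 x 3 matrix per molecule (rows in role order).
manual_keypos <- function(coords, box = c(50, 50, 50)) {
  pos <- do.call(rbind, coords)
  frame <- frame_snapshot(pos, box, 0)
  sel <- uniform_selection(length(coords),
                           stats::setNames(1:7, tagcryst:::role_names()), 7L)
  extract_key_positions(frame, sel)
}

crystal_template <- function(kink = 1) tagcryst:::tag_template(kink)

# A randomized small mixed system (<= 60 molecules) for oracle comparisons.
random_small_system <- function(seed) {
  set.seed(seed)
  polymorph <- sample(c("beta1", "beta2"), 1)
  cells <- c(sample(1:3, 1), 1L, sample(1:2, 1))
  jitter <- sample(c(0, 0.004, 0.008), 1)
  n_melt <- sample(0:8, 1)
  build_box(box_spec(lattice_spec(polymorph, cells, jitter_sd = jitter,
                                  seed = seed),
                     n_melt = n_melt, seed = seed))
}

system_keypos <- function(sys) {
  extract_key_positions(sys$frame, sys$selection)
}
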