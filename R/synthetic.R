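# Idealized sn-POSt geometry. One molecule contributes its 7 metric atoms;
# offsets are nm relative to the molecule origin (glycerol region), long
# axis along z. Lateral sub-spacings (~0.45-0.55 nm) and the ~4.5 nm
# extended length are consistent with a united-atom C16/C18:1/C18 TAG; the
# cell is a geometric idealization satisfying the package's own criteria,
# not a reproduction of published unit-cell coordinates.
#' @keywords internal
#' @noRd
tag_template <- function(kink = 1) {
  m <- rbind(
    palmitic_mid  = c(0, 0.00, -1.00),
    palmitic_tail = c(0, 0.00, -1.90),
    stearic_mid   = c(0, 0.45, -1.00),
    stearic_tail  = c(0, 0.45, -2.10),
    oleic_first   = c(0, 0.20,  0.25),
    oleic_mid     = c(0, 0.20 + 0.12 * kink, 1.30),
    oleic_last    = c(0, 0.20,  2.35))
  m
}

# Within-cell molecule origins (role order 1..4) and kink sign patterns.
# Sides: (1,2) and (3,4), 0.55 nm apart along x; the second side is offset
# 1.15 nm along z. Kinks alternate within a side; beta-2 repeats the same
# pattern on both sides, beta-1 mirrors it.
#' @keywords internal
#' @noRd
cell_geometry <- function(polymorph = c("beta2", "beta1")) {
  polymorph <- match.arg(polymorph)
  list(origins = rbind(c(0, 0, 0), c(0.55, 0, 0),
                       c(0, 0, 1.15), c(0.55, 0, 1.15)),
       kinks = if (polymorph == "beta2") c(1, -1, 1, -1) else c(1, -1, -1, 1),
       lengths = c(a = 1.35, b = 0.90, c = 2.60))
}

#' Reference distances of the idealized crystal template
#'
#' The exact values every criterion distance takes in an unjittered lattice;
#' used by the melt-conformation sampler to guarantee metric separability.
#'
#' @return Named numeric vector over [criterion_keys()] (nm).
#' @export
template_distances <- function() {
  tpl <- tag_template(1)
  geo <- cell_geometry("beta2")
  d <- function(a, b) sqrt(sum((a - b)^2))
  om <- function(i) geo$origins[i, ] + tag_template(geo$kinks[i])["oleic_mid", ]
  pt <- function(i) geo$origins[i, ] + tpl["palmitic_tail", ]
  c(C1_1 = d(tpl["palmitic_tail", ], tpl["stearic_tail", ]),
    C1_2 = d(tpl["palmitic_mid", ], tpl["stearic_mid", ]),
    C2_1 = d(tpl["oleic_last", ], tpl["stearic_tail", ]),
    C2_2 = d(tpl["oleic_last", ], tpl["palmitic_tail", ]),
    P1   = d(om(1), om(2)),
    P2_1 = d(pt(1), pt(2)), P2_2 = d(pt(1), pt(3)), P2_3 = d(pt(1), pt(4)),
    P2_4 = d(pt(2), pt(4)), P2_5 = d(pt(3), pt(4)))
}

#' Specify an idealized crystal lattice
#'
#' @param polymorph `"beta2"` or `"beta1"`.
#' @param cells Integer vector `c(n_a, n_b, n_c)` of unit cells along x, y,
#'   z; the lattice holds `4 * n_a * n_b * n_c` molecules.
#' @param origin Cartesian origin (nm) of the first cell.
#' @param jitter_sd Gaussian positional jitter per coordinate (nm) applied
#'   at build time (default 0 = perfect lattice).
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @return List of class `tag_lattice_spec`.
#' @export
lattice_spec <- function(polymorph = c("beta2", "beta1"), cells = c(1, 1, 1),
                         origin = c(0, 0, 0), jitter_sd = 0, seed = 1L) {
  polymorph <- match.arg(polymorph)
  cells <- as.integer(cells)
  if (length(cells) != 3L || any(cells < 1L)) stop("`cells` must be 3 integers >= 1")
  structure(list(polymorph = polymorph, cells = cells,
                 origin = as.numeric(origin), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "tag_lattice_spec")
}

#' Build an idealized crystal lattice
#'
#' Places `4 * n_a * n_b * n_c` molecules at exact template positions (plus
#' Gaussian jitter if requested) and records the constructed unit cells as
#' ground truth for detection tests. At zero jitter every intramolecular
#' C1/C2 distance and every intra-cell P1/P2 distance equals its template
#' value exactly.
#'
#' @param spec `tag_lattice_spec` from [lattice_spec()].
#' @return List with `positions` (7 atoms per molecule, role order),
#'   `n_molecules`, `kinks`, `cells` (`data.frame(m1..m4, polymorph)`), and
#'   `polymorph`.
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "tag_lattice_spec"))
  geo <- cell_geometry(spec$polymorph)
  n_cells <- prod(spec$cells)
  n_mol <- 4L * n_cells
  pos <- matrix(0, 7L * n_mol, 3L)
  kinks <- integer(n_mol)
  cells <- matrix(0L, n_cells, 4L)
  mol <- 0L; cl <- 0L
  for (ic in seq_len(spec$cells[3])) {
    for (ib in seq_len(spec$cells[2])) {
      for (ia in seq_len(spec$cells[1])) {
        cl <- cl + 1L
        cell_origin <- spec$origin +
          c((ia - 1L) * geo$lengths["a"], (ib - 1L) * geo$lengths["b"],
            (ic - 1L) * geo$lengths["c"])
        for (r in 1:4) {
          mol <- mol + 1L
          kinks[mol] <- geo$kinks[r]
          at <- tag_template(geo$kinks[r])
          rows <- (7L * (mol - 1L) + 1L):(7L * mol)
          pos[rows, ] <- sweep(at, 2L, cell_origin + geo$origins[r, ], "+")
          cells[cl, r] <- mol
        }
      }
    }
  }
  if (spec$jitter_sd > 0) {
    pos <- pos + with_seed(spec$seed, matrix(
      stats::rnorm(length(pos), 0, spec$jitter_sd), nrow(pos), 3L))
  }
  list(positions = pos, n_molecules = n_mol, kinks = kinks,
       cells = data.frame(m1 = cells[, 1], m2 = cells[, 2], m3 = cells[, 3],
                          m4 = cells[, 4], polymorph = spec$polymorph),
       polymorph = spec$polymorph)
}

#' Specify a simulation box of lattices plus melt molecules
#'
#' @param lattices List of `tag_lattice_spec`s. When more than one is given
#'   and their origins are all zero, they are laid out along x with a 3 nm
#'   gap.
#' @param n_melt Number of randomly placed melt molecules.
#' @param box Box lengths (nm); `NULL` auto-sizes to the lattice extent plus
#'   `pad` on every side.
#' @param pad Padding (nm) used when auto-sizing (default 2.5).
#' @param melt_min_sep Minimum minimum-imaged oleic-mid distance (nm)
#'   between a melt molecule and every other molecule (default 0.8, i.e.
#'   at least 1.2 x the P1 band's upper bound), so melts can never form a
#'   unit-cell side.
#' @param seed RNG seed for melt placement and conformations.
#' @return List of class `tag_box_spec`.
#' @export
box_spec <- function(lattices = list(), n_melt = 0L, box = NULL, pad = 2.5,
                     melt_min_sep = 0.8, seed = 1L) {
  if (inherits(lattices, "tag_lattice_spec")) lattices <- list(lattices)
  stopifnot(all(vapply(lattices, inherits, logical(1), "tag_lattice_spec")))
  if (!length(lattices) && is.null(box)) {
    stop("a melt-only box needs explicit `box` lengths")
  }
  structure(list(lattices = lattices, n_melt = as.integer(n_melt), box = box,
                 pad = pad, melt_min_sep = melt_min_sep,
                 seed = as.integer(seed)),
            class = "tag_box_spec")
}

#' Build a simulation box: crystal lattice(s) plus melt molecules
#'
#' Lattice molecules are numbered first (1..n_crystal), melts after,
#' mirroring how such boxes are indexed when generated for MD. Melt
#' conformations are rejection-sampled to fail at least one C1 and one C2
#' band by a wide margin, and melt positions keep every melt's oleic-mid
#' atom at least `melt_min_sep` from all other molecules, guaranteeing
#' metric separability between the phases.
#'
#' @param spec `tag_box_spec`.
#' @return Object of class `tag_system`: list with `frame` ([frame_snapshot()]),
#'   `selection`, `labels` (`crystal_beta1`/`crystal_beta2`/`melt`),
#'   `cells` (ground-truth `data.frame(m1..m4, polymorph)`), `kinks`.
#' @export
build_box <- function(spec) {
  stopifnot(inherits(spec, "tag_box_spec"))
  lat_specs <- spec$lattices
  # Auto-layout multiple all-default-origin lattices along x.
  if (length(lat_specs) > 1L &&
      all(vapply(lat_specs, function(l) all(l$origin == 0), logical(1)))) {
    xoff <- 0
    for (i in seq_along(lat_specs)) {
      lat_specs[[i]]$origin <- c(xoff, 0, 0)
      geo <- cell_geometry(lat_specs[[i]]$polymorph)
      xoff <- xoff + lat_specs[[i]]$cells[1] * geo$lengths["a"] + 3.0
    }
  }
  built <- lapply(lat_specs, build_lattice)
  pos <- if (length(built)) {
    do.call(rbind, lapply(built, `[[`, "positions"))
  } else matrix(0, 0L, 3L)
  kinks <- unlist(lapply(built, `[[`, "kinks"))
  labels <- unlist(lapply(built, function(b) {
    rep(paste0("crystal_", b$polymorph), b$n_molecules)
  }))
  # Renumber ground-truth cells into the global molecule numbering.
  off <- 0L
  cells <- do.call(rbind, lapply(built, function(b) {
    cl <- b$cells
    cl[, 1:4] <- cl[, 1:4] + off
    off <<- off + b$n_molecules
    cl
  }))
  if (is.null(cells)) {
    cells <- data.frame(m1 = integer(), m2 = integer(), m3 = integer(),
                        m4 = integer(), polymorph = character())
  }
  # Shift everything positive and fix the box.
  if (nrow(pos)) {
    lo <- apply(pos, 2L, min)
    pos <- sweep(pos, 2L, lo - spec$pad, "-")
    extent <- apply(pos, 2L, max) + spec$pad
  } else {
    extent <- c(0, 0, 0)
  }
  box <- if (is.null(spec$box)) as.numeric(extent) else check_box(spec$box)
  if (any(extent > box + 1e-9)) {
    stop("generation error: lattices (extent ", paste(round(extent, 2), collapse = " x "),
         " nm) do not fit the requested box")
  }
  n_crystal <- length(kinks)
  if (spec$n_melt > 0L) {
    melt <- with_seed(spec$seed + 1L,
                      place_melts(spec$n_melt, pos, box, spec$melt_min_sep))
    pos <- rbind(pos, melt$positions)
    kinks <- c(kinks, melt$kinks)
    labels <- c(labels, rep("melt", spec$n_melt))
  }
  n_mol <- n_crystal + spec$n_melt
  sel <- uniform_selection(n_mol, stats::setNames(1:7, role_names()), 7L)
  list_out <- list(frame = frame_snapshot(pos, box, 0),
                   selection = sel, labels = labels, cells = cells,
                   kinks = kinks, n_crystal = n_crystal)
  structure(list_out, class = "tag_system")
}

#' @export
print.tag_system <- function(x, ...) {
  cat("TAG system:", length(x$labels), "molecules (",
      sum(x$labels != "melt"), "crystal /", sum(x$labels == "melt"),
      "melt ),", nrow(x$cells), "ground-truth cells\n")
  cat("  box", paste(round(x$frame$box, 2), collapse = " x "), "nm\n")
  invisible(x)
}

# Melt placement: rejection sampling in the free volume. Molecule positions
# are anchored at the oleic-mid atom; candidates are rejected when any atom
# leaves the box or the oleic-mid comes closer than `min_sep` to any placed
# molecule's oleic-mid.
#' @keywords internal
#' @noRd
place_melts <- function(n_melt, crystal_pos, box, min_sep, max_tries = 2000L) {
  om_row <- match("oleic_mid", role_names())
  n_cry <- nrow(crystal_pos) / 7L
  oms <- crystal_pos[om_row + 7L * (seq_len(n_cry) - 1L), , drop = FALSE]
  positions <- matrix(0, 7L * n_melt, 3L)
  kinks <- integer(n_melt)
  for (m in seq_len(n_melt)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      kink <- sample(c(-1, 1), 1L)
      conf <- melt_conformation(kink)
      center <- stats::runif(3L, 0.2, box - 0.2)
      at <- sweep(conf, 2L, center, "+")
      if (any(at < 0.1) || any(sweep(at, 2L, box - 0.1, ">"))) next
      if (nrow(oms) &&
          min(min_image_distance(matrix(center, nrow(oms), 3, byrow = TRUE),
                                 oms, box)) < min_sep) next
      positions[(7L * (m - 1L) + 1L):(7L * m), ] <- at
      kinks[m] <- kink
      oms <- rbind(oms, center)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("generation error: could not place melt molecule ", m, " after ",
           max_tries, " tries (box too crowded; min_sep = ", min_sep, " nm)")
    }
  }
  list(positions = positions, kinks = kinks)
}

# A melted conformation: the crystalline template with the oleic chain
# folded back and the stearic chain displaced, randomly rotated, and
# re-sampled until it misses both C1 bands and both C2 bands by at least
# max(0.08 nm, 15%) — far outside any plausible calibrated band, so melts
# are never classified crystalline. Coordinates are centered on oleic_mid.
#' @keywords internal
#' @noRd
melt_conformation <- function(kink = 1, max_tries = 200L) {
  ref <- template_distances()
  margin <- stats::setNames(pmax(0.08, 0.15 * ref), names(ref))
  for (try in seq_len(max_tries)) {
    at <- tag_template(kink)
    u <- stats::runif(1, 0.35, 0.60)
    at["oleic_last", ] <- at["oleic_mid", ] +
      u * (at["oleic_last", ] - at["oleic_mid", ])
    for (r in c("stearic_mid", "stearic_tail")) {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      at[r, ] <- at[r, ] + stats::runif(1, 0.25, 0.45) * v
    }
    d <- c(C1_1 = sqrt(sum((at["palmitic_tail", ] - at["stearic_tail", ])^2)),
           C1_2 = sqrt(sum((at["palmitic_mid", ] - at["stearic_mid", ])^2)),
           C2_1 = sqrt(sum((at["oleic_last", ] - at["stearic_tail", ])^2)),
           C2_2 = sqrt(sum((at["oleic_last", ] - at["palmitic_tail", ])^2)))
    fails <- abs(d - ref[names(d)]) > margin[names(d)]
    if (!all(fails)) next
    rot <- random_rotation()
    at <- at %*% t(rot)
    return(sweep(at, 2L, at["oleic_mid", ], "-"))
  }
  stop("generation error: could not sample a melt conformation")
}

# Uniform random rotation via a normalized quaternion.
#' @keywords internal
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Generate a pseudo-trajectory from a synthetic system
#'
#' A stand-in for an MD melt: before `melt_onset_frame` crystal molecules
#' jitter about their lattice sites while melt molecules random-walk; from
#' the onset, crystal molecules detach in random order over
#' `melt_ramp_frames` frames, get a melt conformation (outside the C bands)
#' and random-walk from their site. Molecules are kept whole; diffusing
#' molecules wrap by their center. Output is bit-for-bit reproducible from
#' the seed.
#'
#' @param system `tag_system` from [build_box()].
#' @param n_frames Number of frames (>= 2).
#' @param jitter_sd Thermal jitter sd per coordinate (nm) for attached
#'   crystal molecules.
#' @param melt_onset_frame First frame (1-based) of progressive melting;
#'   `Inf` disables melting.
#' @param melt_ramp_frames Frames over which all crystal molecules detach.
#' @param melt_step_nm Random-walk step sd per frame for diffusing
#'   molecules.
#' @param frame_dt Time between frames (ps).
#' @param seed RNG seed.
#' @return `tag_trajectory`.
#' @export
make_pseudo_trajectory <- function(system, n_frames, jitter_sd = 0.01,
                                   melt_onset_frame = Inf,
                                   melt_ramp_frames = 1L,
                                   melt_step_nm = 0.05, frame_dt = 1,
                                   seed = 1L) {
  stopifnot(inherits(system, "tag_system"))
  if (n_frames < 2L) stop("n_frames must be >= 2")
  with_seed(seed, {
    base <- system$frame$positions
    box <- system$frame$box
    n_mol <- length(system$labels)
    is_melt <- system$labels == "melt"
    crystal_ids <- which(!is_melt)
    release_order <- sample(crystal_ids)
    offsets <- matrix(0, n_mol, 3L)  # random-walk displacement per molecule
    detached <- is_melt
    conf <- base  # current conformation (lattice or melt conformer)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f >= melt_onset_frame) {
        frac <- min(1, (f - melt_onset_frame + 1) / max(1L, melt_ramp_frames))
        n_rel <- ceiling(frac * length(crystal_ids))
        newly <- release_order[seq_len(n_rel)]
        newly <- newly[!detached[newly]]
        for (m in newly) {
          rows <- mol_rows(m)
          site_om <- base[rows[6L], ]
          conf[rows, ] <- sweep(melt_conformation(sample(c(-1, 1), 1L)),
                                2L, site_om, "+")
          detached[m] <- TRUE
        }
      }
      pos <- conf
      for (m in seq_len(n_mol)) {
        rows <- mol_rows(m)
        if (detached[m]) {
          offsets[m, ] <- offsets[m, ] + stats::rnorm(3L, 0, melt_step_nm)
          shift <- offsets[m, ]
          # wrap by the molecule center so molecules stay whole
          center <- conf[rows[6L], ] + shift
          wrapped <- as.numeric(wrap_positions(matrix(center, 1L), box))
          shift <- shift + (wrapped - center)
          pos[rows, ] <- sweep(conf[rows, ], 2L, shift, "+")
        } else if (jitter_sd > 0) {
          pos[rows, ] <- conf[rows, ] +
            matrix(stats::rnorm(21L, 0, jitter_sd), 7L, 3L)
        }
      }
      frames[[f]] <- frame_snapshot(pos, box, (f - 1) * frame_dt)
    }
    trajectory(frames, system$selection)
  })
}

#' @keywords internal
#' @noRd
mol_rows <- function(m) (7L * (m - 1L) + 1L):(7L * m)

#' Reference crystal compositions used throughout the package
#'
#' `build_box1()` is a 7 x 1 x 6 beta-2 lattice (168 molecules, 84%) plus 32
#' melt molecules; `build_box2()` holds 1200 molecules: a 10 x 1 x 10 beta-1
#' crystal (400, 33.33%), a 10 x 1 x 5 beta-2 crystal (200, 16.67%) and 600
#' melts.
#'
#' @param seed RNG seed for melt placement/conformations.
#' @param jitter_sd Build-time lattice jitter (default 0: perfect crystals).
#' @return `tag_system`.
#' @export
build_box1 <- function(seed = 42L, jitter_sd = 0) {
  build_box(box_spec(lattice_spec("beta2", c(7L, 1L, 6L),
                                  jitter_sd = jitter_sd, seed = seed),
                     n_melt = 32L, seed = seed))
}

#' @rdname build_box1
#' @export
build_box2 <- function(seed = 42L, jitter_sd = 0) {
  build_box(box_spec(list(lattice_spec("beta1", c(10L, 1L, 10L),
                                       jitter_sd = jitter_sd, seed = seed),
                          lattice_spec("beta2", c(10L, 1L, 5L),
                                       jitter_sd = jitter_sd, seed = seed + 1L)),
                     n_melt = 600L, seed = seed))
}

#' Calibrate a reference on a jittered pure lattice
#'
#' Builds a defect-free lattice of the requested polymorph, generates a
#' short thermally jittered pseudo-trajectory of it (the analogue of
#' calibrating on "a perfect crystal of an equilibrated system"), and
#' calibrates every criterion band, using the builder's ground-truth cells
#' for the P keys.
#'
#' @param polymorph Lattice polymorph (bands are shared between polymorphs;
#'   the cells are geometrically identical up to kink pattern).
#' @param cells Lattice size for the calibration crystal.
#' @param n_frames Calibration frames.
#' @param jitter_sd Thermal jitter sd (nm).
#' @param multiplier Band half-width in sds.
#' @param seed RNG seed.
#' @return `tag_reference`.
#' @export
calibrate_reference <- function(polymorph = "beta2", cells = c(3L, 1L, 3L),
                                n_frames = 10L, jitter_sd = 0.01,
                                multiplier = 2, seed = 1L) {
  sys <- build_box(box_spec(lattice_spec(polymorph, cells), n_melt = 0L,
                            seed = seed))
  traj <- make_pseudo_trajectory(sys, n_frames = n_frames,
                                 jitter_sd = jitter_sd, seed = seed)
  calibrate(traj, cells = sys$cells, multiplier = multiplier)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}
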