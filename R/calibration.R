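#' Distance criteria implemented by the package
#'
#' * `C1_1`, `C1_2` — "parallel": palmitic-tail/stearic-tail and
#'   palmitic-mid/stearic-mid distances (raw, intramolecular).
#' * `C2_1`, `C2_2` — "stretched": oleic-last to stearic-tail and to
#'   palmitic-tail (raw, intramolecular).
#' * `P1` — unit-cell "side": oleic-mid to oleic-mid distance of the two
#'   molecule pairs forming the sides (minimum-imaged).
#' * `P2_1`..`P2_5` — palmitic-tail distances between the four molecules of
#'   a candidate cell: pairs (1,2), (1,3), (1,4), (2,4), (3,4). The three
#'   crystallographically distinct classes — sides `{P2_1, P2_5}`, crossings
#'   `{P2_2, P2_4}` and the diagonal `{P2_3}` — are calibrated by pooling
#'   equivalent pairs.
#'
#' @return Character vector of all criterion keys.
#' @export
criterion_keys <- function() {
  c("C1_1", "C1_2", "C2_1", "C2_2", "P1", paste0("P2_", 1:5))
}

#' @keywords internal
#' @noRd
c_keys <- function() c("C1_1", "C1_2", "C2_1", "C2_2")

# Per-sample distances for the requested keys in one frame.
# `cells` (data.frame m1..m4 of molecule ids) is required for P keys and
# declares the crystallographically equivalent pairs to pool.
#' @keywords internal
#' @noRd
criterion_samples <- function(kp, keys, cells = NULL) {
  stopifnot(inherits(kp, "tag_keypos"))
  out <- list()
  for (key in keys) {
    out[[key]] <- switch(key,
      C1_1 = raw_distance(kp$palmitic_tail, kp$stearic_tail),
      C1_2 = raw_distance(kp$palmitic_mid, kp$stearic_mid),
      C2_1 = raw_distance(kp$oleic_last, kp$stearic_tail),
      C2_2 = raw_distance(kp$oleic_last, kp$palmitic_tail),
      {
        if (is.null(cells)) {
          stop("calibration error: key ", key, " needs declared unit cells")
        }
        pr <- equivalent_pairs(key, cells)
        min_image_distance(role_rows(kp, pr$role_a, pr$a),
                           role_rows(kp, pr$role_b, pr$b), kp$box)
      })
  }
  out
}

#' @keywords internal
#' @noRd
role_rows <- function(kp, role, ids) {
  kp[[role]][match(ids, kp$molecule_id), , drop = FALSE]
}

# Which molecule pairs of each declared cell are pooled for a P key.
#' @keywords internal
#' @noRd
equivalent_pairs <- function(key, cells) {
  pair_cols <- switch(key,
    P1   = list(c("m1", "m2"), c("m3", "m4")),
    P2_1 = ,
    P2_5 = list(c("m1", "m2"), c("m3", "m4")),
    P2_2 = ,
    P2_4 = list(c("m1", "m3"), c("m2", "m4")),
    P2_3 = list(c("m1", "m4")),
    stop("configuration error: unknown criterion key: ", key))
  role <- if (key == "P1") "oleic_mid" else "palmitic_tail"
  a <- unlist(lapply(pair_cols, function(pc) cells[[pc[1]]]))
  b <- unlist(lapply(pair_cols, function(pc) cells[[pc[2]]]))
  list(a = a, b = b, role_a = role, role_b = role)
}

#' Calibrate reference distance bands on a perfect-crystal trajectory
#'
#' Computes, for every requested criterion, the mean and standard deviation
#' of the corresponding distance pooled over all molecules (for the
#' intramolecular `C` keys) or over all declared crystallographically
#' equivalent pairs (for `P1`/`P2_x`) and over all frames. The acceptance
#' band for a distance `d` is `mean +/- multiplier * sd`.
#'
#' The standard deviation uses the n-1 (sample) denominator; with the
#' hundreds-to-thousands of pooled samples a calibration run produces, the
#' choice is immaterial but fixed.
#'
#' @param traj `tag_trajectory` of a defect-free reference crystal.
#' @param keys Criterion keys to calibrate (default: all `C` keys, plus the
#'   `P` keys when `cells` is given).
#' @param cells Optional `data.frame` with columns `m1..m4`: the unit cells
#'   constructed by the lattice builder, declaring equivalent pairs for the
#'   `P` keys.
#' @param multiplier Band half-width in standard deviations (default 2).
#' @param selection Overrides `traj$selection` if given.
#' @return `data.frame` of class `tag_reference` with columns `key`, `mean`,
#'   `sd`, `n_samples`, `multiplier`.
#' @export
calibrate <- function(traj, keys = NULL, cells = NULL, multiplier = 2,
                      selection = NULL) {
  stopifnot(inherits(traj, "tag_trajectory"))
  selection <- if (is.null(selection)) traj$selection else selection
  if (is.null(selection)) stop("calibration error: no selection available")
  if (is.null(keys)) {
    keys <- if (is.null(cells)) c_keys() else criterion_keys()
  }
  pooled <- stats::setNames(vector("list", length(keys)), keys)
  for (f in traj$frames) {
    kp <- extract_key_positions(f, selection)
    smp <- criterion_samples(kp, keys, cells)
    for (key in keys) pooled[[key]] <- c(pooled[[key]], smp[[key]])
  }
  rows <- lapply(keys, function(key) {
    x <- pooled[[key]]
    if (!length(x)) stop("calibration error: zero samples for key ", key)
    s <- if (length(x) > 1L) stats::sd(x) else 0
    data.frame(key = key, mean = mean(x), sd = s,
               n_samples = length(x), multiplier = multiplier)
  })
  ref <- do.call(rbind, rows)
  class(ref) <- c("tag_reference", "data.frame")
  zero <- ref$sd == 0 & ref$multiplier > 0
  if (any(zero)) {
    warning("sd = 0 for key(s) ", paste(ref$key[zero], collapse = ", "),
            ": acceptance band collapses to a point", call. = FALSE)
  }
  bad <- ref$mean - ref$multiplier * ref$sd <= 0
  if (any(bad)) {
    warning("lower band bound is not positive for key(s) ",
            paste(ref$key[bad], collapse = ", "), call. = FALSE)
  }
  ref
}

#' @keywords internal
#' @noRd
reference_row <- function(reference, key) {
  i <- match(key, reference$key)
  if (is.na(i)) {
    stop("configuration error: key ", key, " not present in the reference ",
         "(have: ", paste(reference$key, collapse = ", "), ")")
  }
  reference[i, , drop = FALSE]
}

# Small absolute slack keeps sd = 0 point-bands usable in floating point
# (a lattice calibrated on itself must classify itself).
BAND_EPS_NM <- 1e-9

#' Band bounds for one criterion
#'
#' @param reference `tag_reference`.
#' @param key Criterion key.
#' @param multiplier Optional override of the stored multiplier.
#' @return Numeric `c(lower, upper)` in nm.
#' @export
band_bounds <- function(reference, key, multiplier = NULL) {
  r <- reference_row(reference, key)
  k <- if (is.null(multiplier)) r$multiplier else multiplier
  c(r$mean - k * r$sd - BAND_EPS_NM, r$mean + k * r$sd + BAND_EPS_NM)
}

#' Is a distance within a criterion's calibrated band?
#'
#' The check is inclusive at the boundary: `|d - mean| <= multiplier * sd`.
#'
#' @param distance Numeric vector of distances in nm.
#' @param key Criterion key present in `reference`.
#' @param reference `tag_reference` from [calibrate()].
#' @param multiplier Optional override of the stored multiplier.
#' @return Logical vector.
#' @export
within_band <- function(distance, key, reference, multiplier = NULL) {
  b <- band_bounds(reference, key, multiplier)
  distance >= b[1] & distance <= b[2]
}

#' Write a calibrated reference to a flat key/value text file
#'
#' Calibration only needs to run once per system; the serialized reference
#' is reused by later analysis runs.
#'
#' @param reference `tag_reference`.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tagcryst distance reference: key mean_nm sd_nm n_samples multiplier", con)
  writeLines(sprintf("%s %.12g %.12g %d %.6g", reference$key, reference$mean,
                     reference$sd, reference$n_samples, reference$multiplier), con)
  invisible(path)
}

#' Read a calibrated reference written by [write_reference()]
#'
#' @param path Path to the reference file.
#' @return `tag_reference`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("I/O error: reference file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ref <- do.call(rbind, lapply(parts, function(p) {
    data.frame(key = p[1], mean = as.numeric(p[2]), sd = as.numeric(p[3]),
               n_samples = as.integer(p[4]), multiplier = as.numeric(p[5]))
  }))
  if (anyNA(ref$mean) || anyNA(ref$sd)) stop("format error: bad reference file: ", path)
  class(ref) <- c("tag_reference", "data.frame")
  ref
}
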