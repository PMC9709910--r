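# Degenerate / indeterminate thresholds (nm^2 for cross products, and for
# normalized dot products).
DEGEN_EPS <- 1e-9
INDET_EPS <- 1e-9

#' Normal to the plane of the oleic chain
#'
#' The oleic chain of a crystalline TAG is kinked at its cis double bond.
#' The cross product of the two half-chain vectors (first -> mid and
#' mid -> last) gives the normal to the chain plane; its direction encodes
#' the "rotation" of the kink and is the quantity that distinguishes the
#' beta-1 and beta-2 polymorphs.
#'
#' @param ole_first,ole_mid,ole_last Coordinates (length-3 vectors or n x 3
#'   matrices) of the first, kink and last oleic chain atoms.
#' @return List with `normal` (n x 3 matrix, unnormalized) and `degenerate`
#'   (logical: `TRUE` where the three atoms are collinear, norm < 1e-9 nm^2).
#' @export
orientation_normal <- function(ole_first, ole_mid, ole_last) {
  a <- to_xyz(ole_mid) - to_xyz(ole_first)
  b <- to_xyz(ole_last) - to_xyz(ole_mid)
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  list(normal = n, degenerate = sqrt(rowSums(n * n)) < DEGEN_EPS)
}

#' Oleic-plane normals for all molecules in a frame
#'
#' @param kp `tag_keypos`.
#' @return List with `molecule_id`, `normal` (n x 3) and `degenerate`.
#' @export
orientation_normals <- function(kp) {
  stopifnot(inherits(kp, "tag_keypos"))
  on <- orientation_normal(kp$oleic_first, kp$oleic_mid, kp$oleic_last)
  list(molecule_id = kp$molecule_id, normal = on$normal,
       degenerate = on$degenerate)
}

#' Relative rotation of two oleic kinks
#'
#' The dot product of two oleic-plane normals, divided by its own magnitude,
#' gives +1 when the kinks rotate the same way and -1 when they rotate
#' opposite ways.
#'
#' @param normal_a,normal_b Length-3 normals (not degenerate).
#' @return `+1`, `-1`, or `NA` when the normals are (numerically)
#'   orthogonal, which makes the rotation indeterminate.
#' @export
rotation_sign <- function(normal_a, normal_b) {
  d <- sum(as.numeric(normal_a) * as.numeric(normal_b))
  na <- sqrt(sum(normal_a^2)); nb <- sqrt(sum(normal_b^2))
  if (na < DEGEN_EPS || nb < DEGEN_EPS) return(NA_real_)
  if (abs(d) / (na * nb) < INDET_EPS) return(NA_real_)
  sign(d)
}

#' Default polymorph signature table
#'
#' The four molecules of a candidate cell give three rotation signs relative
#' to molecule 1: `s12`, `s13`, `s14` (the self comparison 1.1 is +1 by
#' construction). The kinks of the two sides point the same way in beta-2
#' (`s13 = +1`) and opposite ways in beta-1 (`s13 = -1`); within a side the
#' two molecules oppose each other, which the consistency requirement
#' `s14 = s12 * s13` enforces without pinning `s12` itself. The table is
#' configuration, not code: users calibrating against real crystal
#' structures can supply their own (see [read_signature_table()]).
#'
#' @return List with `patterns` (`data.frame(label, s12, s13, s14)`, `NA` =
#'   unconstrained) and `require_consistency`.
#' @export
default_signature_table <- function() {
  list(patterns = data.frame(label = c("beta2", "beta1"),
                             s12 = NA_real_, s13 = c(1, -1), s14 = NA_real_),
       require_consistency = TRUE)
}

#' Read a polymorph signature table from YAML
#'
#' Layout: `require_consistency: true/false` and a `patterns:` list of
#' entries with `label` and any of `s12`, `s13`, `s14` (+1/-1; omitted =
#' unconstrained).
#'
#' @param path Path to the YAML file.
#' @return Signature table list as in [default_signature_table()].
#' @export
read_signature_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: signature table not found: ", path)
  y <- yaml::read_yaml(path)
  pats <- do.call(rbind, lapply(y$patterns, function(p) {
    data.frame(label = p$label,
               s12 = if (is.null(p$s12)) NA_real_ else p$s12,
               s13 = if (is.null(p$s13)) NA_real_ else p$s13,
               s14 = if (is.null(p$s14)) NA_real_ else p$s14)
  }))
  list(patterns = pats,
       require_consistency = !isFALSE(y$require_consistency))
}

#' Classify a candidate unit cell as beta-1, beta-2 or neither
#'
#' Computes the rotation signs of molecules 2, 3 and 4 relative to molecule
#' 1 and matches them against the signature table. Candidates containing a
#' degenerate or indeterminate rotation are rejected.
#'
#' @param candidate Integer vector `c(m1, m2, m3, m4)` of molecule ids.
#' @param normals Output of [orientation_normals()].
#' @param signature_table Signature table (default
#'   [default_signature_table()]).
#' @return `"beta1"`, `"beta2"` (or another table label), or `"none"`.
#' @export
classify_candidate <- function(candidate, normals,
                               signature_table = default_signature_table()) {
  idx <- match(candidate, normals$molecule_id)
  if (anyNA(idx)) stop("candidate references unknown molecule ids")
  if (any(normals$degenerate[idx])) return("none")
  n <- normals$normal[idx, , drop = FALSE]
  s <- c(rotation_sign(n[1, ], n[2, ]),
         rotation_sign(n[1, ], n[3, ]),
         rotation_sign(n[1, ], n[4, ]))
  if (anyNA(s)) return("none")
  if (isTRUE(signature_table$require_consistency) && s[3] != s[1] * s[2]) {
    return("none")
  }
  pats <- signature_table$patterns
  for (r in seq_len(nrow(pats))) {
    want <- as.numeric(pats[r, c("s12", "s13", "s14")])
    if (all(is.na(want) | want == s)) return(as.character(pats$label[r]))
  }
  "none"
}

#' Ordered molecule pairs forming potential unit-cell sides
#'
#' A side of the four-molecule unit cell is a pair whose minimum-imaged
#' oleic-mid distance lies within the calibrated `P1` band. Pairs are found
#' with a periodic cell list (bin size >= the band's upper bound) and
#' returned in both orientations, since either molecule can take role 1.
#'
#' @param kp `tag_keypos`.
#' @param reference `tag_reference` containing `P1`.
#' @param method Neighbor search method (`"cell"` or `"all"`).
#' @return `data.frame(a, b, dist)` of ordered pairs.
#' @export
candidate_pairs <- function(kp, reference, method = c("cell", "all")) {
  b <- band_bounds(reference, "P1")
  pr <- neighbor_pairs(kp$oleic_mid, kp$box, b[2], method = match.arg(method))
  pr <- pr[pr$dist >= b[1], , drop = FALSE]
  ids <- kp$molecule_id
  data.frame(a = c(ids[pr$i], ids[pr$j]),
             b = c(ids[pr$j], ids[pr$i]),
             dist = c(pr$dist, pr$dist))
}

#' @keywords internal
#' @noRd
canonical_key <- function(m) {
  if (m[1] > m[2]) m <- m[c(2, 1, 4, 3)]
  paste(m, collapse = "-")
}

#' Enumerate four-molecule unit-cell candidates
#'
#' Finds ordered 4-tuples `(m1, m2, m3, m4)` such that
#' * `(m1, m2)` and `(m3, m4)` are sides (oleic-mid distance in the `P1`
#'   band),
#' * the five palmitic-tail distances P2-1 (1,2), P2-2 (1,3), P2-3 (1,4),
#'   P2-4 (2,4) and P2-5 (3,4) lie in their calibrated bands, and
#' * strictly `P2-1 < P2-2` and `P2-4 > P2-5`, which fixes the role
#'   geometry without measuring the (2,3) distance.
#'
#' The search is pruned: sides come from [candidate_pairs()], and side pairs
#' are joined only when the two role-1 palmitic tails are within the P2-2
#' band's upper bound (cell-list search on the tail positions). The
#' role-symmetric duplicate of a tuple (`(m2, m1, m4, m3)`) is removed via a
#' canonical key, so each detection event appears once.
#'
#' @param kp `tag_keypos`.
#' @param reference `tag_reference` with `P1` and `P2_1..P2_5`.
#' @param method Neighbor search method for the pruning passes.
#' @return `data.frame(m1, m2, m3, m4, canonical)` of distance-passing
#'   candidates (unlabeled).
#' @export
enumerate_unit_cells <- function(kp, reference, method = c("cell", "all")) {
  method <- match.arg(method)
  empty <- data.frame(m1 = integer(), m2 = integer(), m3 = integer(),
                      m4 = integer(), canonical = character())
  sides <- candidate_pairs(kp, reference, method)
  if (!nrow(sides)) return(empty)
  p2b <- lapply(paste0("P2_", 1:5), band_bounds, reference = reference)
  pt <- kp$palmitic_tail
  ids <- kp$molecule_id
  # Pruning join: role-1 tails of the two sides must satisfy P2-2, so only
  # tail pairs within its upper bound are considered.
  join <- neighbor_pairs(pt, kp$box, p2b[[2]][2], method = method)
  if (!nrow(join)) return(empty)
  adj <- c(split(ids[join$j], factor(ids[join$i], levels = ids)),
           split(ids[join$i], factor(ids[join$j], levels = ids)))
  adj <- lapply(stats::setNames(as.character(ids), ids),
                function(id) sort(unique(c(adj[names(adj) == id], recursive = TRUE))))
  sides_by_first <- split(seq_len(nrow(sides)), factor(sides$a, levels = ids))
  ptr <- function(id) pt[match(id, ids), , drop = FALSE]
  res <- vector("list", 0L)
  for (s in seq_len(nrow(sides))) {
    m1 <- sides$a[s]; m2 <- sides$b[s]
    p2_1 <- min_image_distance(ptr(m1), ptr(m2), kp$box)
    if (p2_1 < p2b[[1]][1] || p2_1 > p2b[[1]][2]) next
    for (m3 in adj[[as.character(m1)]]) {
      if (m3 == m1 || m3 == m2) next
      for (sb in sides_by_first[[as.character(m3)]]) {
        m4 <- sides$b[sb]
        if (m4 == m1 || m4 == m2) next
        p2_2 <- min_image_distance(ptr(m1), ptr(m3), kp$box)
        if (p2_2 < p2b[[2]][1] || p2_2 > p2b[[2]][2]) next
        p2_3 <- min_image_distance(ptr(m1), ptr(m4), kp$box)
        if (p2_3 < p2b[[3]][1] || p2_3 > p2b[[3]][2]) next
        p2_4 <- min_image_distance(ptr(m2), ptr(m4), kp$box)
        if (p2_4 < p2b[[4]][1] || p2_4 > p2b[[4]][2]) next
        p2_5 <- min_image_distance(ptr(m3), ptr(m4), kp$box)
        if (p2_5 < p2b[[5]][1] || p2_5 > p2b[[5]][2]) next
        if (!(p2_1 < p2_2 && p2_4 > p2_5)) next
        res[[length(res) + 1L]] <- c(m1, m2, m3, m4)
      }
    }
  }
  if (!length(res)) return(empty)
  m <- do.call(rbind, res)
  out <- data.frame(m1 = m[, 1], m2 = m[, 2], m3 = m[, 3], m4 = m[, 4])
  out$canonical <- apply(m, 1L, canonical_key)
  out <- out[!duplicated(out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive unit-cell search (testing oracle)
#'
#' Scans all ordered 4-tuples of molecules with a compiled quadruple loop,
#' applying exactly the conditions of [enumerate_unit_cells()] but without
#' any spatial pruning. Complexity is O(n^4), so it refuses to run above 60
#' molecules; it exists to validate the pruned search on small systems.
#'
#' @inheritParams enumerate_unit_cells
#' @return `data.frame(m1, m2, m3, m4, canonical)`.
#' @export
brute_force_unit_cells <- function(kp, reference) {
  n <- length(kp$molecule_id)
  if (n > 60L) stop("brute_force_unit_cells is a testing oracle; refusing n > 60")
  empty <- data.frame(m1 = integer(), m2 = integer(), m3 = integer(),
                      m4 = integer(), canonical = character())
  if (n < 4L) return(empty)
  p1b <- band_bounds(reference, "P1")
  p2b <- vapply(paste0("P2_", 1:5), band_bounds, numeric(2), reference = reference)
  m <- bf_unit_cells(kp$oleic_mid, kp$palmitic_tail, kp$box,
                     p1b[1], p1b[2], p2b[1, ], p2b[2, ])
  if (!nrow(m)) return(empty)
  ids <- kp$molecule_id
  out <- data.frame(m1 = ids[m[, 1]], m2 = ids[m[, 2]],
                    m3 = ids[m[, 3]], m4 = ids[m[, 4]])
  out$canonical <- apply(as.matrix(out), 1L, canonical_key)
  out <- out[!duplicated(out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Size of the unpruned ordered-4-tuple search space
#'
#' The number of ordered 4-tuples of distinct molecules,
#' `n (n-1) (n-2) (n-3)`; for 1000 molecules about 10^12, which is why the
#' pruned (or GPU-parallel) search is needed.
#'
#' @param n_molecules Number of molecules.
#' @return Numeric count.
#' @export
search_space_size <- function(n_molecules) {
  n <- as.numeric(n_molecules)
  n * (n - 1) * (n - 2) * (n - 3)
}

#' Accumulate the per-molecule polymorph ledger
#'
#' Every labeled candidate adds 1 to the matching polymorph count of each of
#' its four molecules. Overlapping candidates deliberately over-count — the
#' tolerance bands and side-by-side cells make double detection unavoidable
#' — and the ledger's majority rule absorbs this.
#'
#' @param labeled `data.frame` with `m1..m4` and `label`
#'   (`"beta1"`/`"beta2"`).
#' @param molecule_ids All molecule ids in the system.
#' @return Integer matrix (molecules x 2) with columns `beta1`, `beta2`.
#' @export
accumulate_ledger <- function(labeled, molecule_ids) {
  led <- matrix(0L, length(molecule_ids), 2L,
                dimnames = list(molecule_ids, c("beta1", "beta2")))
  for (r in seq_len(nrow(labeled))) {
    lab <- labeled$label[r]
    if (!lab %in% colnames(led)) next
    mi <- match(as.integer(labeled[r, c("m1", "m2", "m3", "m4")]), molecule_ids)
    led[mi, lab] <- led[mi, lab] + 1L
  }
  led
}

#' Resolve the ledger into per-molecule assignments and percentages
#'
#' Per molecule: if the beta-1 count exceeds the beta-2 count the molecule
#' scores (1, 0); if smaller, (0, 1); if both are zero it is a melt and
#' scores (0, 0); and in the unlikely tie with nonzero counts it scores
#' (0.5, 0.5). Percentages are 100 x (summed scores) / (total molecules).
#'
#' @param ledger Matrix from [accumulate_ledger()].
#' @return List with `assignment` (factor: beta1/beta2/melt/tie), `scores`
#'   (molecules x 2), `pct_beta1`, `pct_beta2`.
#' @export
assign_polymorphs <- function(ledger) {
  b1 <- ledger[, "beta1"]; b2 <- ledger[, "beta2"]
  scores <- matrix(0, nrow(ledger), 2L,
                   dimnames = list(rownames(ledger), c("beta1", "beta2")))
  assignment <- rep("melt", nrow(ledger))
  assignment[b1 > b2] <- "beta1"
  assignment[b1 < b2] <- "beta2"
  tie <- b1 == b2 & b1 > 0
  assignment[tie] <- "tie"
  scores[b1 > b2, 1] <- 1
  scores[b1 < b2, 2] <- 1
  scores[tie, ] <- 0.5
  list(assignment = factor(assignment, levels = c("beta1", "beta2", "melt", "tie")),
       scores = scores,
       pct_beta1 = 100 * sum(scores[, 1]) / nrow(ledger),
       pct_beta2 = 100 * sum(scores[, 2]) / nrow(ledger))
}

#' Full polymorph pipeline for one frame
#'
#' @param kp `tag_keypos`.
#' @param reference Calibrated `tag_reference`.
#' @param signature_table Signature table.
#' @param method Neighbor search method.
#' @return List with `labeled` (labeled candidates), `ledger`, and the
#'   [assign_polymorphs()] result.
#' @export
polymorph_frame <- function(kp, reference,
                            signature_table = default_signature_table(),
                            method = c("cell", "all")) {
  cand <- enumerate_unit_cells(kp, reference, method = method)
  normals <- orientation_normals(kp)
  if (nrow(cand)) {
    cand$label <- vapply(seq_len(nrow(cand)), function(r) {
      classify_candidate(as.integer(cand[r, c("m1", "m2", "m3", "m4")]),
                         normals, signature_table)
    }, character(1))
    labeled <- cand[cand$label != "none", , drop = FALSE]
  } else {
    labeled <- cbind(cand, data.frame(label = character()))
  }
  ledger <- accumulate_ledger(labeled, kp$molecule_id)
  c(list(labeled = labeled, ledger = ledger), assign_polymorphs(ledger))
}

#' Percentage of molecules in each polymorph versus time
#'
#' Runs the unit-cell detection, classification and ledger pipeline on every
#' frame. By default each frame gets its own ledger; with
#' `cumulative = TRUE` detections accumulate over frames and the reported
#' percentages at frame t reflect all detections up to t.
#'
#' @param traj `tag_trajectory`.
#' @param reference Calibrated `tag_reference`.
#' @param signature_table Signature table.
#' @param cumulative Accumulate the ledger across frames (default `FALSE`).
#' @param method Neighbor search method.
#' @return Object of class `tag_polymorph`: list with `summary`
#'   (`data.frame(time_ps, pct_beta1, pct_beta2)`), `assignments` (molecule
#'   x frame factor matrix) and `ledgers` (per frame, as accumulated).
#' @export
polymorph_timeseries <- function(traj, reference,
                                 signature_table = default_signature_table(),
                                 cumulative = FALSE,
                                 method = c("cell", "all")) {
  stopifnot(inherits(traj, "tag_trajectory"))
  if (!length(traj$frames)) stop("domain error: empty trajectory")
  n_mol <- nrow(traj$selection)
  n_fr <- length(traj$frames)
  times <- numeric(n_fr)
  p1 <- numeric(n_fr); p2 <- numeric(n_fr)
  assignments <- matrix(NA_character_, n_mol, n_fr)
  ledgers <- vector("list", n_fr)
  acc <- NULL
  for (t in seq_len(n_fr)) {
    kp <- extract_key_positions(traj$frames[[t]], traj$selection)
    fr <- polymorph_frame(kp, reference, signature_table)
    led <- fr$ledger
    if (cumulative) {
      acc <- if (is.null(acc)) led else acc + led
      led <- acc
      res <- assign_polymorphs(led)
    } else {
      res <- fr
    }
    times[t] <- traj$frames[[t]]$time
    p1[t] <- res$pct_beta1; p2[t] <- res$pct_beta2
    assignments[, t] <- as.character(res$assignment)
    ledgers[[t]] <- led
  }
  rownames(assignments) <- sort(traj$selection$molecule_id)
  structure(list(summary = data.frame(time_ps = times, pct_beta1 = p1,
                                      pct_beta2 = p2),
                 assignments = assignments, ledgers = ledgers,
                 cumulative = cumulative),
            class = "tag_polymorph")
}

#' @export
print.tag_polymorph <- function(x, ...) {
  s <- x$summary
  cat("Polymorph time series:", nrow(s), "frames,", nrow(x$assignments),
      "molecules", if (x$cumulative) "(cumulative ledger)" else "", "\n")
  cat(sprintf("  beta1 %.2f%% -> %.2f%%; beta2 %.2f%% -> %.2f%%\n",
              s$pct_beta1[1], s$pct_beta1[nrow(s)],
              s$pct_beta2[1], s$pct_beta2[nrow(s)]))
  invisible(x)
}

#' Line plot of the polymorph percentages versus time
#'
#' @param x `tag_polymorph`.
#' @param path Optional PNG output path.
#' @export
plot_polymorph <- function(x, path = NULL) {
  draw <- function() {
    s <- x$summary
    graphics::plot(s$time_ps, s$pct_beta2, type = "l", col = "darkorange",
                   ylim = c(0, 100), xlab = "time (ps)",
                   ylab = "% of molecules", lwd = 2)
    graphics::lines(s$time_ps, s$pct_beta1, col = "purple", lwd = 2)
    graphics::legend("topright", c("beta2", "beta1"),
                     col = c("darkorange", "purple"), lwd = 2, bty = "n")
  }
  render_png(draw, path)
}
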