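#' Classify molecules as "parallel" (C1 criteria)
#'
#' A molecule has its sn-1 and sn-3 chains packed side by side when both the
#' palmitic-tail/stearic-tail distance (C1_1) and the palmitic-mid/
#' stearic-mid distance (C1_2) lie within their calibrated bands. Two
#' distances are required so that chains which are merely randomly close do
#' not count as parallel.
#'
#' Intramolecular distances are computed without minimum imaging; molecules
#' are expected to be whole (see [make_molecules_whole()]).
#'
#' @param kp `tag_keypos` for one frame.
#' @param reference `tag_reference` containing `C1_1` and `C1_2`.
#' @param multiplier Optional band-width override.
#' @return Logical vector, one entry per molecule in `molecule_id` order.
#' @export
classify_parallel <- function(kp, reference, multiplier = NULL) {
  d1 <- raw_distance(kp$palmitic_tail, kp$stearic_tail)
  d2 <- raw_distance(kp$palmitic_mid, kp$stearic_mid)
  within_band(d1, "C1_1", reference, multiplier) &
    within_band(d2, "C1_2", reference, multiplier)
}

#' Classify molecules as "stretched" (C2 criteria)
#'
#' A molecule spans its full crystalline extension when the distances from
#' the last oleic atom to the stearic tail (C2_1) and to the palmitic tail
#' (C2_2) both lie within their calibrated bands.
#'
#' @inheritParams classify_parallel
#' @param reference `tag_reference` containing `C2_1` and `C2_2`.
#' @return Logical vector, one entry per molecule.
#' @export
classify_stretched <- function(kp, reference, multiplier = NULL) {
  d1 <- raw_distance(kp$oleic_last, kp$stearic_tail)
  d2 <- raw_distance(kp$oleic_last, kp$palmitic_tail)
  within_band(d1, "C2_1", reference, multiplier) &
    within_band(d2, "C2_2", reference, multiplier)
}

#' Per-frame percentage of parallel and stretched molecules
#'
#' Runs both intramolecular classifiers on every frame. The two criteria are
#' evaluated independently; the denominator is all molecules in the box.
#'
#' @param traj `tag_trajectory` with a selection.
#' @param reference Calibrated `tag_reference`.
#' @param multiplier Optional band-width override.
#' @return Object of class `tag_crystallinity`: list with
#'   * `summary` — `data.frame(time_ps, pct_parallel, pct_stretched)`;
#'   * `parallel`, `stretched` — logical molecule x frame matrices.
#' @export
crystallinity_timeseries <- function(traj, reference, multiplier = NULL) {
  stopifnot(inherits(traj, "tag_trajectory"))
  if (!length(traj$frames)) stop("domain error: empty trajectory")
  if (is.null(traj$selection)) stop("configuration error: trajectory has no selection")
  n_mol <- nrow(traj$selection)
  n_fr <- length(traj$frames)
  par_m <- matrix(FALSE, n_mol, n_fr)
  str_m <- matrix(FALSE, n_mol, n_fr)
  times <- numeric(n_fr)
  for (t in seq_len(n_fr)) {
    kp <- extract_key_positions(traj$frames[[t]], traj$selection)
    par_m[, t] <- classify_parallel(kp, reference, multiplier)
    str_m[, t] <- classify_stretched(kp, reference, multiplier)
    times[t] <- traj$frames[[t]]$time
  }
  rownames(par_m) <- rownames(str_m) <- sort(traj$selection$molecule_id)
  structure(list(
    summary = data.frame(time_ps = times,
                         pct_parallel = 100 * colMeans(par_m),
                         pct_stretched = 100 * colMeans(str_m)),
    parallel = par_m, stretched = str_m), class = "tag_crystallinity")
}

#' @export
print.tag_crystallinity <- function(x, ...) {
  s <- x$summary
  cat("Crystallinity time series:", nrow(s), "frames,", nrow(x$parallel),
      "molecules\n")
  cat(sprintf("  parallel  %.1f%% -> %.1f%%\n", s$pct_parallel[1],
              s$pct_parallel[nrow(s)]))
  cat(sprintf("  stretched %.1f%% -> %.1f%%\n", s$pct_stretched[1],
              s$pct_stretched[nrow(s)]))
  invisible(x)
}

#' Line plot of the crystallinity percentages versus time
#'
#' @param x `tag_crystallinity`.
#' @param path Optional PNG output path; when `NULL`, draws on the current
#'   device.
#' @return The output path (or `NULL`), invisibly.
#' @export
plot_crystallinity <- function(x, path = NULL) {
  draw <- function() {
    s <- x$summary
    graphics::plot(s$time_ps, s$pct_stretched, type = "l", col = "blue",
                   ylim = c(0, 100), xlab = "time (ps)",
                   ylab = "% of molecules", lwd = 2)
    graphics::lines(s$time_ps, s$pct_parallel, col = "red", lwd = 2)
    graphics::legend("topright", c("stretched", "parallel"),
                     col = c("blue", "red"), lwd = 2, bty = "n")
  }
  render_png(draw, path)
}

# Plots are best effort: a headless device failure must never abort an
# analysis run.
#' @keywords internal
#' @noRd
render_png <- function(draw, path, width = 900, height = 600) {
  if (is.null(path)) { draw(); return(invisible(NULL)) }
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    TRUE
  }, error = function(e) {
    warning("plot skipped: ", conditionMessage(e), call. = FALSE)
    FALSE
  })
  invisible(if (ok) path else NULL)
}
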