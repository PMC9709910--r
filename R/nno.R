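#' Near-neighbor sets of every molecule in one frame
#'
#' Two molecules are neighbors when the minimum-imaged distance between
#' their middle oleic chain atoms is at most `cutoff` (inclusive). The
#' search uses a periodic cell list with bin size >= cutoff.
#'
#' @param kp `tag_keypos` for one frame.
#' @param cutoff Neighbor cutoff in nm (default 1.0).
#' @param method Passed to [neighbor_pairs()] (`"cell"` or `"all"`).
#' @return Named list: for each molecule id, an integer vector of neighbor
#'   molecule ids.
#' @export
neighbor_sets <- function(kp, cutoff = 1.0, method = c("cell", "all")) {
  stopifnot(inherits(kp, "tag_keypos"))
  pr <- neighbor_pairs(kp$oleic_mid, kp$box, cutoff, method = match.arg(method))
  ids <- kp$molecule_id
  sets <- stats::setNames(rep(list(integer(0)), length(ids)), ids)
  if (nrow(pr)) {
    fi <- factor(ids[pr$i], levels = ids)
    fj <- factor(ids[pr$j], levels = ids)
    half <- split(ids[pr$j], fi)
    other <- split(ids[pr$i], fj)
    for (m in seq_along(ids)) {
      sets[[m]] <- sort(c(half[[m]], other[[m]]))
    }
  }
  sets
}

#' Near-neighbor occupancy matrix
#'
#' For each molecule `i` and each frame transition `t -> t + stride`, counts
#' the molecules that are within `cutoff` of `i` in both frames. Crystalline
#' molecules keep the same neighbors between frames (high NNO); melted
#' molecules do not (low NNO).
#'
#' @param traj `tag_trajectory` with a selection.
#' @param cutoff Neighbor cutoff in nm (default 1.0).
#' @param stride Frame stride between the compared frames (default 1).
#' @return Object of class `tag_nno`: list with the integer `values` matrix
#'   (molecules x transitions), `cutoff`, `stride`, `molecule_ids`, and
#'   `transition_times` (time of the later frame, ps).
#' @export
nno_matrix <- function(traj, cutoff = 1.0, stride = 1L) {
  stopifnot(inherits(traj, "tag_trajectory"))
  if (is.null(traj$selection)) stop("configuration error: trajectory has no selection")
  stride <- as.integer(stride)
  if (stride < 1L) stop("domain error: stride must be >= 1")
  n_fr <- length(traj$frames)
  if (n_fr - stride < 1L) {
    stop("domain error: need at least ", stride + 1L, " frames at stride ", stride)
  }
  sets <- lapply(traj$frames, function(f) {
    neighbor_sets(extract_key_positions(f, traj$selection), cutoff)
  })
  ids <- sort(traj$selection$molecule_id)
  n_tr <- n_fr - stride
  vals <- matrix(0L, length(ids), n_tr, dimnames = list(ids, NULL))
  times <- numeric(n_tr)
  for (t in seq_len(n_tr)) {
    a <- sets[[t]]; b <- sets[[t + stride]]
    vals[, t] <- vapply(seq_along(ids),
                        function(m) length(intersect(a[[m]], b[[m]])), integer(1))
    times[t] <- traj$frames[[t + stride]]$time
  }
  structure(list(values = vals, cutoff = cutoff, stride = stride,
                 molecule_ids = ids, transition_times = times),
            class = "tag_nno")
}

#' @export
print.tag_nno <- function(x, ...) {
  cat("NNO matrix:", nrow(x$values), "molecules x", ncol(x$values),
      "transitions (cutoff", x$cutoff, "nm, stride", x$stride, ")\n")
  cat("  value range", min(x$values), "..", max(x$values), "\n")
  invisible(x)
}

#' Write an NNO matrix as CSV
#'
#' One row per molecule; the first column is `molecule_id`, the remaining
#' columns are the transitions labeled by the time of the later frame.
#'
#' @param nno `tag_nno`.
#' @param path Output path.
#' @export
write_nno_csv <- function(nno, path) {
  df <- data.frame(molecule_id = nno$molecule_ids, nno$values,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("t_%g", nno$transition_times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' NNO heat map
#'
#' Renders the occupancy matrix with molecules on the ordinate (id order),
#' frame transitions on the abscissa, and brightness increasing with NNO.
#' The color scale is normalized to the observed maximum. A CSV of the raw
#' matrix is written next to the image.
#'
#' @param nno `tag_nno`.
#' @param path PNG output path (`NULL` draws on the current device).
#' @param write_csv Also write `<path>.csv` with the raw matrix
#'   (default `TRUE` when `path` is given).
#' @return The image path, invisibly.
#' @export
nno_heatmap <- function(nno, path = NULL, write_csv = !is.null(path)) {
  stopifnot(inherits(nno, "tag_nno"))
  if (!length(nno$values)) stop("domain error: empty NNO matrix")
  if (write_csv) write_nno_csv(nno, paste0(path, ".csv"))
  draw <- function() {
    v <- nno$values
    zmax <- max(v, 1L)
    graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = t(v),
                    zlim = c(0, zmax),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "frame transition", ylab = "molecule",
                    useRaster = TRUE)
  }
  render_png(draw, path)
}
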