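#' Minimum-image distance in an orthorhombic periodic box
#'
#' Computes the Euclidean distance between points under the minimum-image
#' convention: each Cartesian component of the separation vector is wrapped
#' into `(-box/2, box/2]` before the norm is taken. Only orthorhombic
#' (rectangular) boxes are supported.
#'
#' @param a,b Numeric vectors of length 3, or matrices with 3 columns
#'   (one row per point; rows are paired).
#' @param box Numeric vector of 3 strictly positive box lengths in nm.
#' @return Numeric vector of distances in nm, one per row pair.
#' @examples
#' min_image_distance(c(0.2, 0, 0), c(9.9, 0, 0), c(10, 10, 10)) # 0.3
#' @export
min_image_distance <- function(a, b, box) {
  d <- min_image_displacement(a, b, box)
  sqrt(rowSums(d * d))
}

#' @keywords internal
#' @noRd
check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || anyNA(box) || any(box <= 0)) {
    stop("`box` must be 3 strictly positive orthorhombic box lengths (nm); ",
         "triclinic boxes are not supported", call. = FALSE)
  }
  as.numeric(box)
}

# Minimum-image displacement b - a, wrapped component-wise. Returns an
# n x 3 matrix.
#' @keywords internal
#' @noRd
min_image_displacement <- function(a, b, box) {
  box <- check_box(box)
  a <- to_xyz(a)
  b <- to_xyz(b)
  d <- b - a
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

#' @keywords internal
#' @noRd
to_xyz <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("coordinate matrices must have 3 columns", call. = FALSE)
    x
  } else {
    matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
}

#' Euclidean distance without periodic wrapping
#'
#' Raw (non-imaged) distance, used for intramolecular criteria where
#' molecules are kept whole.
#'
#' @inheritParams min_image_distance
#' @return Numeric vector of distances in nm.
#' @export
raw_distance <- function(a, b) {
  a <- to_xyz(a)
  b <- to_xyz(b)
  d <- b - a
  sqrt(rowSums(d * d))
}

#' All point pairs within a cutoff under periodic boundaries
#'
#' Finds every unordered pair `(i, j)`, `i < j`, whose minimum-image distance
#' is at most `cutoff`. The default method bins points into a cell list with
#' bin size >= cutoff and only examines neighboring bins; `method = "all"`
#' is the quadratic all-pairs scan used as an independent cross-check in the
#' test-suite.
#'
#' @param pos Numeric matrix, n x 3, positions in nm.
#' @param box Box lengths (nm), length 3.
#' @param cutoff Distance cutoff in nm; must be positive and no larger than
#'   half the smallest box length (minimum-image uniqueness).
#' @param method `"cell"` (cell list, default) or `"all"` (dense scan).
#' @return `data.frame` with integer columns `i`, `j` (`i < j`) and numeric
#'   `dist`.
#' @export
neighbor_pairs <- function(pos, box, cutoff, method = c("cell", "all")) {
  method <- match.arg(method)
  box <- check_box(box)
  pos <- to_xyz(pos)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a single positive length in nm", call. = FALSE)
  }
  if (cutoff > min(box) / 2) {
    stop("cutoff (", cutoff, " nm) exceeds half the smallest box length (",
         min(box) / 2, " nm): minimum image is ambiguous", call. = FALSE)
  }
  n <- nrow(pos)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n < 2L) return(empty)
  if (method == "all") {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- min_image_distance(pos[idx[, 1], , drop = FALSE],
                            pos[idx[, 2], , drop = FALSE], box)
    keep <- d <= cutoff
    out <- data.frame(i = idx[keep, 1], j = idx[keep, 2], dist = d[keep])
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  cell_list_pairs(pos, box, cutoff)
}

# Cell-list pair search. Points are wrapped into the box, binned on a grid
# with spacing >= cutoff, and pairs are gathered from each bin with itself
# and its half-shell of neighboring bins (13 offsets in 3-D), with wrapping
# of bin indices when a dimension has >= 3 bins. Dimensions with fewer than
# 3 bins degenerate to scanning all bin combinations along that axis, which
# stays correct because the final minimum-image distance filter is applied.
#' @keywords internal
#' @noRd
cell_list_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  w <- wrap_positions(pos, box)
  nb <- pmax(1L, as.integer(floor(box / cutoff)))
  # Bin triple per point (0-based).
  bt <- matrix(0L, n, 3)
  for (k in 1:3) {
    b <- as.integer(floor(w[, k] / box[k] * nb[k]))
    b[b >= nb[k]] <- nb[k] - 1L  # guard w == box after rounding
    bt[, k] <- b
  }
  lin <- bt[, 1] + nb[1] * (bt[, 2] + nb[2] * bt[, 3])
  members <- split(seq_len(n), lin)
  occ_lin <- as.integer(names(members))
  occ_t <- cbind(occ_lin %% nb[1],
                 (occ_lin %/% nb[1]) %% nb[2],
                 occ_lin %/% (nb[1] * nb[2]))
  # Neighbor bin offsets: self + half shell so each bin pair is visited once.
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] >= 0)))
  offs <- offs[keep, , drop = FALSE]
  ii <- integer(0); jj <- integer(0)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (q in seq_along(members)) {
    assign(as.character(occ_lin[q]), q, envir = lookup)
  }
  for (q in seq_along(members)) {
    a <- members[[q]]
    for (r in seq_len(nrow(offs))) {
      tgt <- occ_t[q, ] + offs[r, ]
      skip <- FALSE
      for (k in 1:3) {
        if (nb[k] >= 3L) {
          tgt[k] <- tgt[k] %% nb[k]
        } else if (tgt[k] < 0L || tgt[k] >= nb[k]) {
          # <3 bins along k: every bin already adjacent to every other, so
          # out-of-range offsets are duplicates of in-range ones.
          skip <- TRUE
          break
        }
      }
      if (skip) next
      tlin <- tgt[1] + nb[1] * (tgt[2] + nb[2] * tgt[3])
      if (all(offs[r, ] == 0L)) {
        if (length(a) < 2L) next
        cmb <- utils::combn(a, 2L)
        ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
      } else {
        p <- get0(as.character(tlin), envir = lookup)
        if (is.null(p) || p == q) next
        bset <- members[[p]]
        g <- expand.grid(i = a, j = bset)
        ii <- c(ii, g$i); jj <- c(jj, g$j)
      }
    }
  }
  if (!length(ii)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  d <- min_image_distance(pos[ii, , drop = FALSE], pos[jj, , drop = FALSE], box)
  keep <- d <= cutoff
  out <- data.frame(i = ii[keep], j = jj[keep], dist = d[keep])
  out <- unique(out)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wrap positions into the primary box image
#'
#' @param pos n x 3 matrix of positions (nm).
#' @param box Box lengths (nm).
#' @return Matrix of the same shape with all coordinates in `[0, box)`.
#' @export
wrap_positions <- function(pos, box) {
  box <- check_box(box)
  pos <- to_xyz(pos)
  for (k in 1:3) {
    pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
  }
  pos
}
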