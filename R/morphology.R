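## Low-level 3-D grid utilities shared by the segmentation and phantom code.
## Masks are plain logical arrays; all operations are vectorised or C-level.

#' Label connected components of a 3-D logical mask
#'
#' Breadth-first labeling of the foreground voxels of a 3-D logical array.
#' Labels are positive integers in first-encounter order; background voxels
#' get 0.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 (face neighbours) or 26 (face, edge and corner
#'   neighbours).
#' @return Integer array of the same dimension as `mask`, with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  lab <- label_components_cpp(as.vector(mask), as.integer(dim(mask)),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- dim(mask)
  attr(lab, "n_components") <- n
  lab
}

# Shift a 3-D array along one axis, filling vacated slices with `fill`.
shift_array <- function(a, axis, by, fill = FALSE) {
  if (by == 0) return(a)
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    if (by >= d[axis]) return(out)
    dst[[axis]] <- (by + 1):d[axis]
    src[[axis]] <- 1:(d[axis] - by)
  } else {
    if (-by >= d[axis]) return(out)
    dst[[axis]] <- 1:(d[axis] + by)
    src[[axis]] <- (1 - by):d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation/erosion with a 6-connected (cross) structuring element,
# applied `iter` times. Outside the grid counts as background.
dilate_mask <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    r <- m
    for (ax in 1:3) r <- r | shift_array(m, ax, 1L) | shift_array(m, ax, -1L)
    m <- r
  }
  m
}

erode_mask <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    r <- m
    for (ax in 1:3) {
      r <- r & shift_array(m, ax, 1L, fill = FALSE) &
        shift_array(m, ax, -1L, fill = FALSE)
    }
    m <- r
  }
  m
}

close_mask <- function(m, iter = 1L) erode_mask(dilate_mask(m, iter), iter)

#' Dice similarity coefficient between two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return 2|a∩b| / (|a|+|b|); 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Separable 3-D Gaussian blur. `sigma_mm` is one scalar; `spacing` converts
# it to voxels per axis. Edges are handled by replicate padding so flat
# fields stay flat.
gaussian_blur3 <- function(a, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(a)
  d <- dim(a)
  for (axis in 1:3) {
    sig <- sigma_mm / spacing[axis]
    if (sig < 1e-6) next
    r <- max(1L, as.integer(ceiling(3 * sig)))
    k <- dnorm(seq(-r, r), sd = sig)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    f <- f[(r + 1):(r + d[axis]), , drop = FALSE]
    a <- aperm(array(as.numeric(f), dim = d[perm]), order(perm))
  }
  a
}

# Squared in-plane distance (mm^2) of every voxel centre from the grid
# centre, as an nx-by-ny matrix. Used by the phantom's cylindrical geometry.
plane_r2 <- function(dims, spacing, axes = c(1L, 2L)) {
  cx <- (dims[axes[1]] + 1) / 2
  cy <- (dims[axes[2]] + 1) / 2
  x <- (seq_len(dims[axes[1]]) - cx) * spacing[axes[1]]
  y <- (seq_len(dims[axes[2]]) - cy) * spacing[axes[2]]
  outer(x^2, y^2, `+`)
}
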