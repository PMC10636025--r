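#' Construct an image volume
#'
#' The basic substrate of all quantification: a 3-D scalar grid (Hounsfield
#' units for CT, non-negative activity counts for SPECT) with voxel spacing
#' in mm and a designated limb axis running proximal (index 1) to distal.
#'
#' @param voxels 3-D numeric array.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm;
#'   anisotropic spacing is allowed.
#' @param modality `"CT"` or `"SPECT"`. SPECT voxels must be non-negative.
#' @param limb_axis which grid axis runs proximal to distal (default 3).
#' @return An object of class `image_volume`: a list with elements `voxels`,
#'   `spacing`, `modality`, `limb_axis`.
#' @export
image_volume <- function(voxels, spacing, modality = c("CT", "SPECT"),
                         limb_axis = 3L) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  if (any(dim(voxels) < 2))
    stop("grid must have at least 2 voxels along each axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  limb_axis <- as.integer(limb_axis)
  if (!limb_axis %in% 1:3) stop("`limb_axis` must be 1, 2 or 3", call. = FALSE)
  if (modality == "SPECT" && any(voxels < 0, na.rm = TRUE))
    stop("SPECT voxels must be non-negative", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, modality = modality,
                 limb_axis = limb_axis),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s %s, spacing %s mm, limb axis %d\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$limb_axis))
  invisible(x)
}

# Voxel volume in mm^3.
voxel_volume_mm3 <- function(spacing) prod(spacing)

#' Construct a set of compartment masks
#'
#' Holds limb, bone, muscle and subcutaneous (SC) masks for one CT volume.
#' The SC compartment is defined by subtraction: SC = limb minus bone minus
#' muscle. The constructor enforces that identity, that bone and muscle are
#' disjoint, and that every mask is contained in the limb; a mask set
#' violating any of these is rejected.
#'
#' @param limb,bone,muscle logical arrays of identical dimension.
#' @param subcutaneous optional logical array; if supplied it must equal
#'   `limb & !(bone | muscle)` exactly, otherwise it is computed.
#' @return Object of class `compartment_masks`.
#' @export
compartment_masks <- function(limb, bone, muscle, subcutaneous = NULL) {
  for (m in list(limb, bone, muscle))
    if (!is.logical(m) || length(dim(m)) != 3)
      stop("masks must be 3-D logical arrays", call. = FALSE)
  if (!identical(dim(limb), dim(bone)) || !identical(dim(limb), dim(muscle)))
    stop("masks must share one grid", call. = FALSE)
  if (any(bone & muscle))
    stop("bone and muscle masks overlap", call. = FALSE)
  if (any(bone & !limb) || any(muscle & !limb))
    stop("bone and muscle must be contained in the limb mask", call. = FALSE)
  sc <- limb & !(bone | muscle)
  if (!is.null(subcutaneous) && !identical(as.vector(subcutaneous),
                                           as.vector(sc)))
    stop("subcutaneous mask violates the subtraction identity ",
         "SC = limb & !(bone | muscle)", call. = FALSE)
  structure(list(limb = limb, bone = bone, muscle = muscle,
                 subcutaneous = sc),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf(
    "<compartment_masks> limb %d, bone %d, muscle %d, subcutaneous %d voxels\n",
    sum(x$limb), sum(x$bone), sum(x$muscle), sum(x$subcutaneous)))
  invisible(x)
}

#' Split the limb into proximal and distal region masks
#'
#' The limb is divided at a fixed fractional plane along the limb axis
#' (default half-way, a stand-in for the elbow/knee). Proximal is the
#' low-index end.
#'
#' @param mask logical array to partition (typically the limb or SC mask).
#' @param split_fraction position of the split plane as a fraction of the
#'   axis length, in (0, 1).
#' @param limb_axis axis running proximal to distal.
#' @return Named list of two disjoint logical arrays, `proximal` and
#'   `distal`, whose union is `mask`.
#' @export
region_masks <- function(mask, split_fraction = 0.5, limb_axis = 3L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            split_fraction > 0, split_fraction < 1)
  d <- dim(mask)
  n <- d[limb_axis]
  cut <- max(1L, min(n - 1L, as.integer(floor(n * split_fraction))))
  idx <- slice.index(mask, limb_axis)
  prox <- mask & (idx <= cut)
  dist <- mask & (idx > cut)
  list(proximal = prox, distal = dist)
}
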