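#' Construct ROI masks on a voxel grid
#'
#' Builds named 3D boolean masks on a shared isotropic grid with an
#' MNI-like coordinate frame (the \code{origin_mm} is the mm coordinate of
#' voxel [1,1,1]). Supported shapes: \code{sphere} (center, radius),
#' \code{ellipsoid} (center, semiaxes), \code{box} (center, halfsize) and
#' \code{box_pair} (two boxes mirrored in x, e.g. bilateral striatum).
#' Membership is by Euclidean distance of voxel centres in mm.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param origin_mm mm coordinate of the first voxel.
#' @param rois Named list of ROI specs, each a list with \code{type} and the
#'   shape parameters above.
#' @return Named list of class \code{roi_mask_set}; each element is a 3D
#'   logical array with attributes \code{voxel_mm} and \code{origin_mm}.
#' @examples
#' m <- make_roi_masks(c(20, 20, 20), 2, c(-19, -19, -19),
#'                     list(ball = list(type = "sphere", center = c(0, 0, 0),
#'                                      radius = 6)))
#' sum(m$ball)
#' @export
make_roi_masks <- function(grid_shape, voxel_mm, origin_mm, rois) {
  stopifnot(length(grid_shape) == 3L, voxel_mm > 0, length(origin_mm) == 3L)
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("every ROI must be named")
  if (anyDuplicated(names(rois))) stop("duplicate ROI names")
  ax <- lapply(1:3, function(d) origin_mm[d] + (seq_len(grid_shape[d]) - 1) * voxel_mm)
  X <- array(rep(ax[[1L]], times = prod(grid_shape[2:3])), grid_shape)
  Y <- array(rep(rep(ax[[2L]], each = grid_shape[1L]), grid_shape[3L]), grid_shape)
  Z <- array(rep(ax[[3L]], each = prod(grid_shape[1:2])), grid_shape)

  build <- function(spec) {
    ctr <- spec$center
    m <- switch(spec$type,
      sphere = {
        if (spec$radius <= 0) stop("radius must be positive")
        (X - ctr[1L])^2 + (Y - ctr[2L])^2 + (Z - ctr[3L])^2 <= spec$radius^2
      },
      ellipsoid = {
        if (any(spec$semiaxes <= 0)) stop("semiaxes must be positive")
        ((X - ctr[1L]) / spec$semiaxes[1L])^2 +
          ((Y - ctr[2L]) / spec$semiaxes[2L])^2 +
          ((Z - ctr[3L]) / spec$semiaxes[3L])^2 <= 1
      },
      box = {
        h <- spec$halfsize
        abs(X - ctr[1L]) <= h[1L] & abs(Y - ctr[2L]) <= h[2L] &
          abs(Z - ctr[3L]) <= h[3L]
      },
      box_pair = {
        h <- spec$halfsize
        (abs(X - ctr[1L]) <= h[1L] | abs(X + ctr[1L]) <= h[1L]) &
          abs(Y - ctr[2L]) <= h[2L] & abs(Z - ctr[3L]) <= h[3L]
      },
      stop("unknown ROI type: ", spec$type)
    )
    if (!any(m)) stop("ROI produced an empty mask")
    attr(m, "voxel_mm") <- voxel_mm
    attr(m, "origin_mm") <- origin_mm
    m
  }
  masks <- lapply(rois, build)
  # pairwise disjointness
  if (length(masks) > 1L) {
    tot <- Reduce(`+`, masks)
    if (any(tot > 1L)) stop("ROI masks overlap")
  }
  structure(masks, class = "roi_mask_set")
}

#' Default study grid and ROI masks
#'
#' A 48 x 56 x 44 grid at 2 mm isotropic resolution in an MNI-like frame,
#' with three regions: a dopaminergic-midbrain ellipsoid (centre
#' (0, -14, -10) mm, semi-axes (8, 8, 6) mm; a geometric stand-in for the
#' substantia nigra / VTA), a bilateral associative-limbic striatum box pair
#' (centres (+-24, 6, 2) mm), and the right-DLPFC sphere of radius 10 mm
#' centred at (50, 30, 28) mm.
#'
#' @param voxel_mm Voxel size (default 2 mm).
#' @return An \code{roi_mask_set} with elements midbrain, striatum, dlpfc.
#' @export
default_roi_masks <- function(voxel_mm = 2) {
  make_roi_masks(
    grid_shape = c(48L, 56L, 44L), voxel_mm = voxel_mm,
    origin_mm = c(-34, -60, -40),
    rois = list(
      midbrain = list(type = "ellipsoid", center = c(0, -14, -10),
                      semiaxes = c(8, 8, 6)),
      striatum = list(type = "box_pair", center = c(24, 6, 2),
                      halfsize = c(8, 8, 6)),
      dlpfc = list(type = "sphere", center = c(50, 30, 28), radius = 10)
    )
  )
}

# mm coordinates of TRUE voxels (origin-relative if no origin attribute)
voxel_coords <- function(mask, voxel_mm = NULL) {
  if (is.null(voxel_mm)) voxel_mm <- attr(mask, "voxel_mm")
  if (is.null(voxel_mm)) voxel_mm <- 1
  origin <- attr(mask, "origin_mm")
  if (is.null(origin)) origin <- c(0, 0, 0)
  idx <- which(mask, arr.ind = TRUE)
  sweep((idx - 1) * voxel_mm, 2L, -origin)
}

#' Write / read a mask or image as NIfTI-1
#'
#' Thin wrappers around RNifti; the voxel size is recorded in the header.
#'
#' @param img 3D logical/numeric array (optionally with a \code{voxel_mm}
#'   attribute) or 4D numeric array.
#' @param path File path (.nii or .nii.gz).
#' @param voxel_mm Voxel size in mm if not carried as an attribute.
#' @export
write_nifti_image <- function(img, path, voxel_mm = NULL) {
  if (is.null(voxel_mm)) voxel_mm <- attr(img, "voxel_mm")
  if (is.null(voxel_mm)) voxel_mm <- 1
  arr <- array(as.numeric(img), dim(img))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(voxel_mm, min(3L, length(dim(img))))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim(im))
  attr(arr, "voxel_mm") <- RNifti::pixdim(im)[1L]
  arr
}

#' @rdname write_nifti_image
#' @export
read_nifti_mask <- function(path) {
  arr <- read_nifti_image(path)
  m <- arr > 0.5
  attr(m, "voxel_mm") <- attr(arr, "voxel_mm")
  m
}
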