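#' Voxel grid geometry
#'
#' A `vox_grid` carries the shared geometry of all volumes belonging to one
#' subject: array dimensions, voxel size in mm, the world-space position of
#' the centre of the first voxel, and the left-right convention. World
#' coordinates follow the usual neuroimaging convention that the coordinate
#' increasing along `lr_axis` points to the anatomical right, so voxels with
#' negative coordinate on that axis are in the left hemisphere.
#'
#' @param shape integer vector of length 3, array dimensions.
#' @param voxel_mm numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param origin_mm numeric vector of length 3, world coordinate (mm) of the
#'   centre of voxel (1,1,1). Default centres the grid on world origin so
#'   the field of view is symmetric about the mid-sagittal plane.
#' @param lr_axis which axis (1, 2 or 3) is the left-right axis.
#' @return an object of class `vox_grid`.
#' @export
vox_grid <- function(shape, voxel_mm = c(1, 1, 1),
                     origin_mm = -(shape - 1) * voxel_mm / 2,
                     lr_axis = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(voxel_mm) == 3, all(voxel_mm > 0),
            length(origin_mm) == 3, lr_axis %in% 1:3)
  structure(list(shape = shape, voxel_mm = as.numeric(voxel_mm),
                 origin_mm = as.numeric(origin_mm),
                 lr_axis = as.integer(lr_axis)),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("vox_grid %s, voxels %s mm, origin (%s) mm, L-R axis %d\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", "),
              x$lr_axis))
  invisible(x)
}

#' World coordinates along each axis
#'
#' @param grid a [vox_grid()].
#' @return list of three numeric vectors, the world coordinate (mm) of voxel
#'   centres along each axis.
#' @export
grid_coords <- function(grid) {
  lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_mm[a])
}

#' World coordinate arrays on the full grid
#'
#' @param grid a [vox_grid()].
#' @return list of three arrays of dim `grid$shape` with voxel-centre world
#'   coordinates.
#' @export
grid_coord_arrays <- function(grid) {
  cc <- grid_coords(grid)
  sh <- grid$shape
  list(
    array(rep(cc[[1]], times = sh[2] * sh[3]), dim = sh),
    array(rep(rep(cc[[2]], each = sh[1]), times = sh[3]), dim = sh),
    array(rep(cc[[3]], each = sh[1] * sh[2]), dim = sh)
  )
}

new_volume <- function(grid, value = 0) array(value, dim = grid$shape)

check_volume <- function(vol, grid, name = "volume") {
  if (!identical(dim(vol), as.integer(grid$shape)))
    stop(sprintf("%s has dim (%s) but grid is (%s)", name,
                 paste(dim(vol), collapse = ","),
                 paste(grid$shape, collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

#' Hemisphere masks
#'
#' Splits the grid into left and right half-spaces at world coordinate 0 on
#' the left-right axis. Voxels whose centre lies within half a voxel of the
#' mid-sagittal plane are assigned to neither hemisphere, so laterality
#' statistics never mix signal across the midline.
#'
#' @param grid a [vox_grid()].
#' @return list with logical arrays `left` and `right`.
#' @export
hemisphere_masks <- function(grid) {
  x <- grid_coord_arrays(grid)[[grid$lr_axis]]
  hv <- grid$voxel_mm[grid$lr_axis] / 2
  list(left = x <= -hv, right = x >= hv)
}

#' Reflect a volume across the mid-sagittal plane
#'
#' Used to build mirror-symmetric anatomy and to map left-hemisphere ROIs to
#' their right homologues. Exact only when the grid is symmetric about world
#' coordinate 0 on the left-right axis (the synthetic template always is).
#'
#' @param vol array matching `grid$shape`.
#' @param grid a [vox_grid()].
#' @return the reflected array.
#' @export
mirror_volume <- function(vol, grid) {
  check_volume(vol, grid)
  a <- grid$lr_axis
  idx <- list(seq_len(grid$shape[1]), seq_len(grid$shape[2]),
              seq_len(grid$shape[3]))
  idx[[a]] <- rev(idx[[a]])
  do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
}

#' @rdname vox_grid
#' @param grid a `vox_grid`.
#' @return `voxel_volume_mm3`: scalar voxel volume in cubic mm.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_mm)
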