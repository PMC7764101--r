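# Orientation fields: per-voxel discrete mixtures of unit directions with
# nonnegative weights. These stand in for fiber orientation distributions:
# the tracker only ever needs to draw a direction from the voxel's mixture,
# so a discrete (direction, weight) set with N <= 4 components is sufficient.

#' Construct an orientation field
#'
#' @param dirs numeric array of dimension (nvox, N, 3): unit directions per
#'   voxel component, voxels flattened in column-major (x fastest) order.
#' @param weights numeric matrix (nvox, N): nonnegative component weights.
#'   Rows with any mass are renormalized to sum to 1.
#' @param grid integer 3-vector of voxel counts.
#' @param voxel_size isotropic voxel edge in mm.
#' @return an `orientation_field` object.
#' @export
orientation_field <- function(dirs, weights, grid, voxel_size = 1) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L))
  nvox <- prod(grid)
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1L)
  n_comp <- ncol(weights)
  stopifnot(nrow(weights) == nvox,
            length(dim(dirs)) == 3L,
            dim(dirs)[1L] == nvox, dim(dirs)[2L] == n_comp, dim(dirs)[3L] == 3L)
  if (any(weights < 0)) stop("orientation weights must be nonnegative")
  tot <- rowSums(weights)
  nz <- tot > 0
  weights[nz, ] <- weights[nz, , drop = FALSE] / tot[nz]
  structure(list(dirs = dirs, weights = weights, grid = grid,
                 voxel_size = voxel_size, n_comp = n_comp),
            class = "orientation_field")
}

#' An all-zero orientation field (tracking terminates everywhere)
#' @param grid integer 3-vector; @param n_comp mixture size; @param voxel_size mm.
#' @export
empty_field <- function(grid, n_comp = 2L, voxel_size = 1) {
  nvox <- prod(grid)
  orientation_field(array(0, c(nvox, n_comp, 3L)),
                    matrix(0, nvox, n_comp), grid, voxel_size)
}

#' @export
print.orientation_field <- function(x, ...) {
  nz <- sum(rowSums(x$weights) > 0)
  cat(sprintf("orientation_field: %d x %d x %d grid (%.3g mm), %d components, %d voxels with mass\n",
              x$grid[1], x$grid[2], x$grid[3], x$voxel_size, x$n_comp, nz))
  invisible(x)
}

#' Add a weighted direction to a set of voxels of a field (in place value)
#'
#' Directions go into the first free component of each voxel; voxels whose
#' N components are all taken raise an error.
#' @keywords internal
field_add <- function(field, lin_idx, direction, weight) {
  direction <- direction / sqrt(sum(direction^2))
  for (i in lin_idx) {
    slot <- which(field$weights[i, ] == 0)
    if (length(slot) == 0L)
      stop("orientation mixture overflow: more bundles than components at a voxel")
    s <- slot[1L]
    field$weights[i, s] <- weight
    field$dirs[i, s, ] <- direction
  }
  field
}

# --- NIfTI serialization -----------------------------------------------------
# Layout: a single 4-D volume with 4N components per voxel:
# components [1..3N] are the N direction triplets (x1,y1,z1,x2,...),
# components [3N+1..4N] the N weights. Documented in the package README.

#' Write an orientation field as a 4-D NIfTI volume
#' @param field an `orientation_field`. @param path output .nii/.nii.gz path.
#' @export
write_field <- function(field, path) {
  g <- field$grid; N <- field$n_comp
  arr <- array(0, c(g, 4L * N))
  for (k in seq_len(N)) for (a in 1:3) {
    arr[, , , 3L * (k - 1L) + a] <- array(field$dirs[, k, a], g)
  }
  for (k in seq_len(N)) arr[, , , 3L * N + k] <- array(field$weights[, k], g)
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- c(rep_len(field$voxel_size, 3L), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an orientation field written by [write_field()]
#' @param path .nii/.nii.gz path. @return an `orientation_field`.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4L, dim(arr)[4L] %% 4L == 0L)
  N <- dim(arr)[4L] %/% 4L
  g <- dim(arr)[1:3]
  nvox <- prod(g)
  dirs <- array(0, c(nvox, N, 3L))
  for (k in seq_len(N)) for (a in 1:3) {
    dirs[, k, a] <- as.vector(arr[, , , 3L * (k - 1L) + a])
  }
  weights <- matrix(0, nvox, N)
  for (k in seq_len(N)) weights[, k] <- as.vector(arr[, , , 3L * N + k])
  vs <- RNifti::pixdim(img)[1L]
  orientation_field(dirs, weights, g, vs)
}
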