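# Grid/geometry helpers shared across modules.
#
# Conventions (fixed package-wide):
#   * 0-based voxel indices; voxel centers at index * voxel_size (mm), RAS
#     axis order; all streamline coordinates are in mm.
#   * A position maps to its nearest voxel by round(pos / voxel_size).
#   * Label/mask volumes are plain 3-D R arrays.

# divide the columns of an n x 3 matrix by a length-1 or length-3 voxel size
scale_cols <- function(pos, voxel_size) {
  if (length(voxel_size) == 1L) return(pos / voxel_size)
  vs <- rep_len(voxel_size, 3L)
  cbind(pos[, 1L] / vs[1L], pos[, 2L] / vs[2L], pos[, 3L] / vs[3L])
}

#' Convert mm positions to 0-based nearest-voxel indices
#'
#' @param pos numeric matrix (n x 3) of positions in mm.
#' @param voxel_size voxel edges in mm (scalar, or length 3 for anisotropic).
#' @return integer matrix (n x 3), 0-based voxel indices (may be out of grid).
#' @keywords internal
pos_to_voxel <- function(pos, voxel_size) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  matrix(as.integer(round(scale_cols(pos, voxel_size))), ncol = 3L)
}

#' 1-based linear index into a 3-D array from 0-based voxel triplets
#'
#' Out-of-grid voxels get NA.
#' @keywords internal
voxel_to_linear <- function(vox, grid) {
  if (is.null(dim(vox))) vox <- matrix(vox, ncol = 3L)
  ok <- vox[, 1L] >= 0L & vox[, 1L] < grid[1L] &
        vox[, 2L] >= 0L & vox[, 2L] < grid[2L] &
        vox[, 3L] >= 0L & vox[, 3L] < grid[3L]
  idx <- 1L + vox[, 1L] + grid[1L] * (vox[, 2L] + grid[2L] * vox[, 3L])
  idx[!ok] <- NA_integer_
  idx
}

#' Normalize rows of a 3-column matrix to unit length
#' @keywords internal
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

#' Trilinear interpolation of a scalar volume at mm positions
#'
#' Positions are clamped to the grid hull (voxel-center convention), so
#' sampling at or slightly beyond the border uses the border value.
#'
#' @param vol 3-D numeric array.
#' @param pos numeric matrix (n x 3) of mm positions.
#' @param voxel_size isotropic voxel edge in mm.
#' @param method "trilinear" (default) or "nearest".
#' @return numeric vector of length n.
#' @export
interp_volume <- function(vol, pos, voxel_size = 1, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  grid <- dim(vol)
  p <- scale_cols(pos, voxel_size)  # continuous 0-based voxel coordinates
  for (a in 1:3) p[, a] <- pmin(pmax(p[, a], 0), grid[a] - 1L)
  if (method == "nearest") {
    return(vol[voxel_to_linear(matrix(as.integer(round(p)), ncol = 3L), grid)])
  }
  i0 <- pmin(floor(p), matrix(rep(grid - 2L, each = nrow(p)), ncol = 3L))
  i0 <- pmax(i0, 0)
  f <- p - i0
  lin <- function(dx, dy, dz) {
    voxel_to_linear(matrix(as.integer(cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)),
                           ncol = 3L), grid)
  }
  w <- function(dx, dy, dz) {
    (if (dx == 1) f[, 1] else 1 - f[, 1]) *
    (if (dy == 1) f[, 2] else 1 - f[, 2]) *
    (if (dz == 1) f[, 3] else 1 - f[, 3])
  }
  out <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    out <- out + w(dx, dy, dz) * vol[lin(dx, dy, dz)]
  }
  out
}

#' Derive per-subject (or per-stage) RNG seeds from a master seed
#'
#' Deterministic, collision-avoiding derivation kept below 2^31 so the
#' results are valid R integer seeds.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @param stream small integer distinguishing independent uses.
#' @return integer vector of n seeds.
#' @export
derive_seeds <- function(master, n, stream = 0L) {
  # splitmix-like integer hash, folded into [1, 2^31 - 2]
  x <- (as.double(master) %% 2147483647) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (x * 48271 + 3949 * (stream + 1) + 7919 * i) %% 2147483647
    out[i] <- as.integer(x) + 1L
  }
  out
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical/0-1 arrays of identical dimension.
#' @return 2|A∩B| / (|A|+|B|); NaN if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
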