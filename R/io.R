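# Formats and configuration: NIfTI-1 volumes (via RNifti), the TCK
# streamline format (mm coordinates, RAS), YAML run configuration with an
# md5 stamp carried into every output.

#' Write a 3-D volume as NIfTI-1
#'
#' Integer-valued arrays are written as int32 so label volumes round-trip
#' exactly; others as float64.
#'
#' @param vol 3-D array (logical masks are written as 0/1 integers).
#' @param path output .nii or .nii.gz path.
#' @param voxel_size isotropic voxel edge in mm.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  if (length(dim(vol)) != 3L) stop("write_volume expects a 3-D array")
  if (is.logical(vol)) vol <- array(as.integer(vol), dim(vol))
  int_like <- is.integer(vol) || (is.numeric(vol) && all(vol == round(vol), na.rm = TRUE))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep_len(voxel_size, 3L)
  RNifti::writeNifti(img, path, datatype = if (int_like) "int32" else "double")
  invisible(path)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path .nii/.nii.gz path.
#' @return 3-D array with attributes `voxel_size` and `pixdim`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), "-D: ", path)
  pd <- RNifti::pixdim(img)
  attr(arr, "voxel_size") <- pd[1L]
  attr(arr, "pixdim") <- pd
  arr
}

#' Check two volumes share grid and voxel geometry
#' @param a,b arrays from [read_volume()] (or plain arrays).
#' @export
check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volume grids differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  pa <- attr(a, "pixdim"); pb <- attr(b, "pixdim")
  if (!is.null(pa) && !is.null(pb) && any(abs(pa[1:3] - pb[1:3]) > 1e-6))
    stop("volume voxel sizes differ")
  invisible(TRUE)
}

# --- TCK ---------------------------------------------------------------------

#' Write a tractogram to the TCK streamline format
#'
#' Standard layout: ASCII header ("mrtrix tracks", count, datatype
#' Float32LE, file offset), then little-endian float32 point triplets with a
#' NaN triplet between streamlines and an Inf triplet at the end. A JSON
#' sidecar (same path + ".json") records counts, statuses and parameters.
#'
#' @param tractogram a `tractogram`. @param path output .tck path.
#' @param sidecar write the JSON metadata sidecar (default TRUE).
#' @export
write_tck <- function(tractogram, path, sidecar = TRUE) {
  n <- length(tractogram$lengths)
  hdr_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "count: ", n, "\n",
           "datatype: Float32LE\n",
           "file: . ", offset, "\n",
           "END\n")
  }
  offset <- nchar(hdr_for(0), type = "bytes")
  while (nchar(hdr_for(offset), type = "bytes") != offset)
    offset <- nchar(hdr_for(offset), type = "bytes")
  hdr <- hdr_for(offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (i in seq_len(n)) {
    p <- get_streamline(tractogram, i)
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  if (sidecar) {
    meta <- list(count = n,
                 status_table = as.list(table(tractogram$status)),
                 counts = as.list(tractogram$counts),
                 params = unclass(tractogram$params))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a TCK streamline file
#'
#' @param path .tck path.
#' @return list of k x 3 point matrices (mm), with `attr(,"count")` from
#'   the header.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readChar(con, 1L)
    buf <- line
    while (!endsWith(buf, "\n")) buf <- paste0(buf, readChar(con, 1L))
    buf <- sub("\n$", "", buf)
    hdr <- c(hdr, buf)
    if (buf == "END") break
    if (length(hdr) > 1000L) stop("malformed TCK header")
  }
  if (hdr[1L] != "mrtrix tracks") stop("not a TCK file: ", path)
  kv <- strsplit(grep(":", hdr, value = TRUE, fixed = TRUE), ":\\s*")
  keys <- vapply(kv, `[`, "", 1L); vals <- vapply(kv, `[`, "", 2L)
  offset <- as.integer(strsplit(vals[keys == "file"], " ")[[1L]][2L])
  count <- as.integer(vals[keys == "count"])
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(m) & !is.infinite(m)) == 3L
  is_inf <- rowSums(is.infinite(m)) == 3L
  m <- m[!is_inf, , drop = FALSE]
  is_nan <- is_nan[!is_inf]
  grp <- cumsum(c(0L, head(is_nan, -1L))) + 1L
  keep <- !is_nan
  out <- split.data.frame(m[keep, , drop = FALSE], grp[keep])
  out <- lapply(out, function(x) { dimnames(x) <- NULL; x })
  names(out) <- NULL
  attr(out, "count") <- count
  out
}

# --- configuration -----------------------------------------------------------

#' Build a run configuration
#'
#' All knobs of the end-to-end run in one round-trippable list: phantom
#' geometry, cohort, tracking, parcellation and stats options, output
#' directory and master seed.
#'
#' @param master_seed integer; every stage seed derives from it.
#' @param grid_shape phantom grid.
#' @param crossing_fraction,angular_noise_deg,asymmetry phantom knobs.
#' @param n_hc,n_sz,fa_baseline,fa_group_offset,fa_noise_sd cohort knobs.
#' @param n_streamlines,step_size,max_angle_deg,max_steps tracking knobs.
#' @param fa_streamlines streamlines per parcel for FA sampling.
#' @param mpm_threshold MPM sample fraction.
#' @param endpoints_only,share_fa_tracking pipeline variants.
#' @param ss_type ANOVA sums-of-squares type. @param alpha significance level.
#' @param out_dir output directory or NULL (in-memory run).
#' @export
run_config <- function(master_seed = 1L,
                       grid_shape = c(64L, 64L, 64L),
                       crossing_fraction = 0, angular_noise_deg = 0,
                       asymmetry = 0L,
                       n_hc = 24L, n_sz = 30L, fa_baseline = 0.47,
                       fa_group_offset = -0.036, fa_noise_sd = 0.05,
                       n_streamlines = 5000L, step_size = 1.25,
                       max_angle_deg = 30, max_steps = 2000L,
                       fa_streamlines = 10000L,
                       mpm_threshold = 0.5, endpoints_only = FALSE,
                       share_fa_tracking = FALSE,
                       ss_type = "III", alpha = 0.05, out_dir = NULL) {
  cfg <- list(master_seed = as.integer(master_seed),
              phantom = list(grid_shape = as.integer(grid_shape),
                             crossing_fraction = crossing_fraction,
                             angular_noise_deg = angular_noise_deg,
                             asymmetry = as.integer(asymmetry)),
              cohort = list(n_hc = as.integer(n_hc), n_sz = as.integer(n_sz),
                            fa_baseline = fa_baseline,
                            fa_group_offset = fa_group_offset,
                            fa_noise_sd = fa_noise_sd),
              tracking = list(n_streamlines = as.integer(n_streamlines),
                              step_size = step_size,
                              max_angle_deg = max_angle_deg,
                              max_steps = as.integer(max_steps)),
              parcellation = list(mpm_threshold = mpm_threshold,
                                  endpoints_only = endpoints_only),
              metrics = list(fa_streamlines = as.integer(fa_streamlines),
                             share_fa_tracking = share_fa_tracking),
              stats = list(ss_type = ss_type, alpha = alpha),
              out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' md5 stamp of a configuration (canonical JSON serialization)
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL                       # hash covers science, not paths
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a run configuration as YAML (lossless round-trip)
#' @param config a `run_config`. @param path .yaml path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(master_seed = cfg$master_seed),
                        cfg$phantom, cfg$cohort, cfg$tracking,
                        list(mpm_threshold = cfg$parcellation$mpm_threshold,
                             endpoints_only = cfg$parcellation$endpoints_only,
                             fa_streamlines = cfg$metrics$fa_streamlines,
                             share_fa_tracking = cfg$metrics$share_fa_tracking,
                             ss_type = cfg$stats$ss_type, alpha = cfg$stats$alpha,
                             out_dir = cfg$out_dir)))
}

#' Write a long-format table as TSV with the config hash stamped in a
#' comment line
#' @keywords internal
write_stamped_tsv <- function(tab, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the config hash stamped into a TSV written by the pipeline
#' @keywords internal
read_tsv_hash <- function(path) {
  l1 <- readLines(path, n = 1L)
  sub("^# config_hash: ", "", l1)
}
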