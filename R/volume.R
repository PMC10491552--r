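#' 3D ultrasound volume
#'
#' A gray-value volume with per-axis spacing and origin. Array axes are
#' axial x lateral x elevation, matching the package-wide convention (image
#' rows = depth, columns = lateral, slice index = sweep direction).
#'
#' @param data 3D numeric array, values in `[0, 255]`.
#' @param spacing Length-3 numeric, mm per voxel (axial, lateral, elevation).
#' @param origin Length-3 numeric, world mm of voxel (1,1,1) in
#'   (axial, lateral, elevation) order.
#' @param method Provenance label (e.g. `"stack"`, `"pnn"`).
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(data, spacing, origin = c(0, 0, 0), method = "unknown") {
  if (length(dim(data)) != 3) {
    stop_us("volume data must be a 3D array", "us_invalid_volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_us("spacing must be 3 positive values (mm)", "us_invalid_volume")
  }
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255) {
    stop_us("volume gray values must lie in [0, 255]", "us_invalid_volume")
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 method = method), class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<us_volume> %d x %d x %d (axial x lateral x elevation), spacing %.3g x %.3g x %.3g mm, method %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$method))
  invisible(x)
}

#' @export
dim.us_volume <- function(x) dim(x$data)

#' Stack a motorized frame stream into a volume
#'
#' Motorized sweeps move only in elevation with a motor-controlled step, so
#' no reconstruction algorithm is needed: voxel `(i, j, k)` is exactly pixel
#' `(i, j)` of frame `k` and the elevation spacing equals the step size.
#'
#' @param frames A [frame_stream()] of equal-shaped frames.
#' @param step_size_mm Elevation step between consecutive frames (mm).
#' @param origin_elevation World elevation (mm) of the first frame.
#' @return An `us_volume` with spacing
#'   `(axial pixel, lateral pixel, step_size_mm)`.
#' @export
stack_volume <- function(frames, step_size_mm, origin_elevation = 0) {
  stopifnot(inherits(frames, "us_frames"), step_size_mm > 0)
  d <- dim(frames$frames[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(frames$frames)))
  for (k in seq_along(frames$frames)) arr[, , k] <- frames$frames[[k]]
  us_volume(arr,
            spacing = c(frames$geom$pixel_spacing_axial,
                        frames$geom$pixel_spacing_lateral,
                        step_size_mm),
            origin = c(0, 0, origin_elevation),
            method = "stack")
}

#' Map world millimetres to voxel indices
#'
#' @param volume An `us_volume`.
#' @param x,y,z Lateral, axial and elevation world coordinates (mm).
#' @return Integer vector `(i, j, k)` = (axial, lateral, elevation) indices.
#' @export
mm_to_voxel <- function(volume, x, y, z) {
  idx <- round((c(y, x, z) - volume$origin) / volume$spacing) + 1
  as.integer(idx)
}

#' Read and write volumes
#'
#' Lossless round trip of the gray array, spacing and origin through a
#' standard volume format, chosen by file extension: `.nrrd` (raw-encoded
#' NRRD, primary) or `.nii`/`.nii.gz` (NIfTI via RNifti).
#'
#' @param volume An `us_volume`.
#' @param path Output/input file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` an
#'   `us_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "us_volume"))
  switch(volume_format(path),
         nrrd = write_nrrd(volume, path),
         nifti = write_nifti_vol(volume, path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_us(sprintf("volume file not found: %s", path), "us_file_not_found")
  }
  switch(volume_format(path),
         nrrd = read_nrrd(path),
         nifti = read_nifti_vol(path))
}

volume_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop_us(sprintf("unknown volume format for '%s'; supported: .nrrd, .nii, .nii.gz",
                  path), "us_unknown_format")
}

# --- minimal NRRD (raw encoding); first array axis is fastest-varying -------

write_nrrd <- function(volume, path) {
  d <- dim(volume$data)
  v <- as.vector(volume$data)
  int8 <- all(v == round(v)) && min(v) >= 0 && max(v) <= 255
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (int8) "unsigned char" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    sprintf("content: us3dqa %s", volume$method),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (int8) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  type <- field("type")
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.]+(e-?[0-9]+)?", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(field("space origin") %||% "(0,0,0)")
  n <- prod(sizes)
  v <- if (type == "unsigned char") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  meth <- field("content")
  us_volume(array(v, dim = sizes), spacing = spacing, origin = origin,
            method = if (!is.null(meth)) sub("^us3dqa ", "", meth) else "unknown")
}

# --- NIfTI via RNifti; origin carried in the sform translation ---------------

write_nifti_vol <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  # sform: scaled identity with the origin as translation
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  origin <- xf[1:3, 4]
  us_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp,
            origin = as.numeric(origin), method = "unknown")
}
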