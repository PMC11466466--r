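# Internal fixture format: one NIfTI volume per image plus a JSON sidecar
# that is authoritative for geometry (size/spacing/origin/direction), unit,
# role and prescription.  Structures, plans, reports and ground truth are
# plain JSON.  DICOM support covers uncompressed explicit-VR little-endian
# image series (CT/CBCT); RT Plan / Structure / Dose inputs use the JSON
# sidecar representation.

grid_to_list <- function(grid) {
  list(size = grid$size, spacing = grid$spacing, origin = grid$origin,
       direction = as.numeric(grid$direction))
}

grid_from_list <- function(x) {
  image_grid(unlist(x$size), unlist(x$spacing), unlist(x$origin),
             matrix(unlist(x$direction), 3, 3))
}

#' Write an image volume to the internal fixture format
#'
#' Writes `<path>.nii.gz` (float64 voxel data) and `<path>.json` (geometry,
#' unit, role, prescription).  The sidecar is authoritative on read, so the
#' round trip is lossless.
#'
#' @param vol an [image_volume].
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$spacing
  RNifti::writeNifti(img, paste0(path, ".nii.gz"), datatype = "double")
  side <- list(grid = grid_to_list(vol$grid), unit = vol$unit, role = vol$role)
  if (!is.null(vol$prescription)) side$prescription <- vol$prescription
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume from the internal fixture format
#'
#' @param path file path without extension (expects `<path>.nii.gz` and
#'   `<path>.json`).
#' @return An [image_volume] (a [dose_volume] when the sidecar carries a
#'   prescription).
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_from_list(side$grid)
  vals <- array(as.double(RNifti::readNifti(paste0(path, ".nii.gz"))), grid$size)
  if (!is.null(side$prescription))
    dose_volume(vals, grid, prescription = side$prescription)
  else
    image_volume(vals, grid, unit = side$unit, role = side$role)
}

#' Read a CT/CBCT image series
#'
#' Accepts either a directory of uncompressed explicit-VR little-endian DICOM
#' slice files, or an internal-format volume (path prefix of a
#' `.nii.gz`/`.json` pair).  Slices are sorted by position along the slice
#' normal; mixed series UIDs or a non-uniform slice gap are errors.
#'
#' @param path directory (DICOM) or volume path prefix (internal format).
#' @param role role tag for the returned volume.
#' @return An [image_volume] in HU.
#' @export
read_image_series <- function(path, role = "planning_ct") {
  if (file.exists(paste0(path, ".json"))) {
    vol <- read_volume(path)
    vol$role <- role
    return(vol)
  }
  if (!dir.exists(path)) stop("no such series: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!grepl("\\.json$", files)]
  if (!length(files)) stop("no files in series directory: ", path)
  slices <- lapply(files, read_dicom_slice)
  uids <- vapply(slices, `[[`, character(1), "series_uid")
  if (length(unique(uids)) > 1L)
    stop("mixed series UIDs in one directory: ", paste(unique(uids), collapse = ", "))
  row_dir <- slices[[1]]$iop[1:3]
  col_dir <- slices[[1]]$iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  pos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  if (length(slices) > 1L) {
    gaps <- diff(pos)
    if (max(gaps) - min(gaps) > 1e-3 * max(gaps))
      stop(sprintf("non-uniform slice gap: gaps range %.4f to %.4f mm",
                   min(gaps), max(gaps)))
    dz <- gaps[1]
  } else dz <- 1
  sp <- c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1], dz)
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  vals <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) vals[, , k] <- slices[[k]]$hu
  grid <- image_grid(c(nx, ny, length(slices)), sp, slices[[1]]$ipp,
                     cbind(row_dir, col_dir, normal))
  image_volume(vals, grid, unit = "HU", role = role)
}

# Minimal explicit-VR little-endian DICOM slice parser; extracts geometry,
# rescale and pixel data only.
read_dicom_slice <- function(file) {
  raw <- readBin(file, "raw", file.info(file)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", file)
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2L)
  while (pos + 8L <= length(raw) + 1L) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (vr == "SQ" || len >= 4294967295)
      stop("unsupported DICOM encoding (sequence/undefined length) in ", file)
    key <- sprintf("%04x,%04x", grp, ele)
    tags[[key]] <- list(vr = vr, bytes = raw[(pos + hdr):(pos + hdr + len - 1L)][seq_len(len)])
    pos <- pos + hdr + len
  }
  need <- function(key, name) {
    if (is.null(tags[[key]]))
      stop("missing geometry tag ", name, " (", key, ") in ", file)
    tags[[key]]
  }
  ds <- function(tag) as.numeric(strsplit(trimws(rawToChar(tag$bytes)), "\\\\")[[1]])
  us <- function(tag) as.integer(tag$bytes[1]) + 256L * as.integer(tag$bytes[2])
  series_uid <- trimws(rawToChar(need("0020,000e", "SeriesInstanceUID")$bytes))
  ipp <- ds(need("0020,0032", "ImagePositionPatient"))
  iop <- ds(need("0020,0037", "ImageOrientationPatient"))
  psp <- ds(need("0028,0030", "PixelSpacing"))
  rows <- us(need("0028,0010", "Rows"))
  cols <- us(need("0028,0011", "Columns"))
  slope <- if (!is.null(tags[["0028,1053"]])) ds(tags[["0028,1053"]]) else 1
  inter <- if (!is.null(tags[["0028,1052"]])) ds(tags[["0028,1052"]]) else 0
  px <- need("7fe0,0010", "PixelData")
  stored <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                    signed = TRUE, endian = "little")
  hu <- matrix(stored * slope + inter, nrow = cols, ncol = rows)
  list(series_uid = series_uid, ipp = ipp, iop = iop, pixel_spacing = psp,
       rows = rows, cols = cols, hu = hu)
}

# ---- structures -------------------------------------------------------------

rle_encode <- function(mask) {
  r <- rle(as.logical(mask))
  list(first = r$values[1], lengths = as.integer(r$lengths))
}

rle_decode <- function(x, size) {
  vals <- rep(c(x$first, !x$first), length.out = length(x$lengths))
  array(inverse.rle(structure(list(lengths = unlist(x$lengths), values = vals),
                              class = "rle")), size)
}

#' Write a structure set to a JSON sidecar
#'
#' Masks are stored run-length encoded (lossless); the shared grid is
#' embedded.
#'
#' @param ss a [structure_set].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(ss, path) {
  out <- list(grid = grid_to_list(ss$grid),
              structures = lapply(names(ss$masks), function(nm) {
                list(name = nm, role = ss$roles[[nm]],
                     rle = rle_encode(ss$masks[[nm]]))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure set from a JSON sidecar
#'
#' Structures may be stored run-length encoded (read verbatim) or as closed
#' planar contour polygons (rasterized onto `grid` with the even-odd rule;
#' a voxel counts as inside when its center is inside).  Degenerate rings
#' (< 3 points) are skipped with a warning; structures that rasterize to
#' zero voxels are kept and flagged in the `"empty"` attribute.
#'
#' @param path JSON file path.
#' @param grid target [image_grid] for contour rasterization; defaults to the
#'   grid embedded in the file.
#' @return A [structure_set]; attribute `"empty"` names empty structures.
#' @export
read_structures <- function(path, grid = NULL) {
  x <- jsonlite::read_json(path)
  file_grid <- if (!is.null(x$grid)) grid_from_list(x$grid) else NULL
  if (is.null(grid)) grid <- file_grid
  if (is.null(grid)) stop("no grid given and none embedded in ", path)
  masks <- list(); roles <- character(0); empty <- character(0)
  for (s in x$structures) {
    if (!is.null(s$rle)) {
      if (is.null(file_grid) || !all(file_grid$size == grid$size))
        stop("run-length masks require the embedded grid")
      m <- rle_decode(s$rle, grid$size)
    } else {
      rings <- lapply(s$contours, function(ring)
        matrix(unlist(ring), ncol = 3, byrow = TRUE))
      m <- rasterize_structure(rings, grid)
    }
    if (!any(m)) empty <- c(empty, s$name)
    masks[[s$name]] <- m
    roles[s$name] <- if (!is.null(s$role)) s$role else default_role(s$name)
  }
  ss <- structure_set(masks, grid, roles)
  attr(ss, "empty") <- empty
  ss
}

# ---- plan -------------------------------------------------------------------

#' Construct plan information
#'
#' @param isocenter mm triple, or `NULL` when the plan has no isocenter (this
#'   drives the prealignment branch).
#' @param prescription_dose prescription in Gy over the full course.
#' @param number_of_fractions integer.
#' @param beams list of beams: `gantry_angle` (deg), `source_axis_distance`
#'   (mm), `aperture` (list with `half_x`, `half_y` mm at the isocenter
#'   plane), `weight` (relative).
#' @param output_factor frozen absolute-dose scale from the reference
#'   calculation; `NULL` until set by [compute_plan_dose].
#' @return An object of class `plan_info`.
#' @export
plan_info <- function(isocenter = NULL, prescription_dose = 45,
                      number_of_fractions = 25L, beams = list(),
                      output_factor = NULL) {
  if (!is.null(isocenter)) {
    isocenter <- as.numeric(isocenter)
    if (length(isocenter) != 3L || any(!is.finite(isocenter)))
      stop("isocenter must be a finite mm triple or NULL")
  }
  if (!is.finite(prescription_dose) || prescription_dose <= 0)
    stop("prescription dose must be positive")
  if (length(beams)) {
    w <- vapply(beams, function(b) as.numeric(b$weight %||% 1), numeric(1))
    if (any(w < 0) || !any(w > 0))
      stop("beam weights must be >= 0 with at least one > 0")
  }
  structure(list(isocenter = isocenter, prescription_dose = prescription_dose,
                 number_of_fractions = as.integer(number_of_fractions),
                 beams = beams, output_factor = output_factor),
            class = "plan_info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read plan information from a JSON sidecar
#'
#' An absent isocenter is not an error: it is recorded as `NULL` and selects
#' the geometric-center prealignment branch downstream.
#'
#' @param path JSON file path.
#' @return A [plan_info].
#' @export
read_plan <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("unparseable plan file ", path, ": ",
                                         conditionMessage(e)))
  iso <- if (!is.null(x$isocenter)) unlist(x$isocenter) else NULL
  plan_info(isocenter = iso,
            prescription_dose = x$prescription_dose %||% 45,
            number_of_fractions = x$number_of_fractions %||% 25L,
            beams = x$beams %||% list(),
            output_factor = x$output_factor)
}

#' Write plan information to JSON
#' @param plan a [plan_info].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a dose volume
#'
#' Internal-format dose: `<path>.nii.gz` plus `<path>.json` carrying the
#' prescription and, optionally, a `scaling` factor applied to the stored
#' values (the RTDOSE dose-grid-scaling convention).
#'
#' @param path volume path prefix.
#' @return A [dose_volume].
#' @export
read_dose <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_from_list(side$grid)
  vals <- array(as.double(RNifti::readNifti(paste0(path, ".nii.gz"))), grid$size)
  if (!is.null(side$scaling)) vals <- vals * side$scaling
  if (any(vals < 0)) stop("negative scaled dose in ", path)
  dose_volume(vals, grid, prescription = side$prescription)
}
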