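# Structure-guided ROI registration: organs around the target are rendered
# into a label volume (fixed label order, higher = more target-important),
# converted to per-label signed distance channels, and registered with the
# shared B-spline machinery; the resulting DVF propagates CTV/PTV.

#' The fixed ROI label order
#'
#' Air through bladder in increasing importance for the target; overlaps
#' resolve to the higher label.
#' @return Named integer vector (`air = 0` ... `bladder = 8`).
#' @export
roi_label_order <- function() {
  c(air = 0L, skin = 1L, femoral_head_l = 2L, femoral_head_r = 3L,
    pelvis = 4L, spinal_cord = 5L, rectum = 6L, small_intestine = 7L,
    bladder = 8L)
}

#' Create a label volume
#'
#' @param labels integer 3D array with values 0..8.
#' @param grid [image_grid].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid) {
  if (!all(dim(labels) == grid$size))
    stop("label array shape does not match grid")
  if (any(labels < 0 | labels > 8))
    stop("labels must lie in 0..8")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid, mapping = roi_label_order()),
            class = "label_volume")
}

#' Build the ROI label mask from a structure set
#'
#' Every voxel receives the highest applicable label; voxels inside the skin
#' but no organ are 1 (skin); voxels outside every structure are 0 (air).
#' Missing ROIs are allowed and logged; a missing skin/body outline is an
#' error.
#'
#' @param structures a [structure_set].
#' @return A [label_volume] on the structures' grid.
#' @export
build_label_mask <- function(structures) {
  order <- roi_label_order()
  if (is.null(get_mask(structures, "skin")))
    stop("no skin structure: the body outline is required to build the label mask")
  labels <- array(0L, structures$grid$size)
  missing <- character(0)
  for (nm in names(order)[-1]) {
    m <- get_mask(structures, nm)
    if (is.null(m)) { missing <- c(missing, nm); next }
    labels[m] <- order[[nm]]
  }
  if (length(missing))
    message("label mask built without: ", paste(missing, collapse = ", "))
  out <- label_volume(labels, structures$grid)
  attr(out, "missing") <- missing
  out
}

#' Write/read a label volume (lossless run-length JSON)
#' @param lv a [label_volume].
#' @param path JSON file path.
#' @return `path` (write) or the [label_volume] (read).
#' @export
write_label_volume <- function(lv, path) {
  r <- rle(as.integer(lv$labels))
  jsonlite::write_json(list(grid = grid_to_list(lv$grid),
                            lengths = r$lengths, values = r$values),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- grid_from_list(x$grid)
  labels <- array(inverse.rle(structure(list(lengths = x$lengths,
                                             values = x$values),
                                        class = "rle")), grid$size)
  label_volume(labels, grid)
}

#' Structure-guided ROI registration
#'
#' Registers the planning-CT label mask to the fraction-day label mask.
#' Raw integer labels carry no meaningful arithmetic, so each shared label
#' is converted to a signed Euclidean distance map clamped to +/-20 mm and
#' the multi-channel sum of squared differences is minimized with the
#' B-spline machinery (control spacing 25 mm by default: the guidance is
#' sparse but clean).  Only the masks enter, so CBCT intensity content
#' cannot affect the result.
#'
#' The returned field lives on the fraction-side grid and maps fraction-day
#' points to planning-CT points (pull convention), i.e. it propagates
#' planning contours onto the fraction anatomy.
#'
#' @param mask_ct planning-side [label_volume].
#' @param mask_cbct fraction-side [label_volume] (same grid).
#' @param config [registration_config].
#' @param clamp_mm signed-distance clamp.
#' @param smoothness bending-penalty weight for this stage; the distance-map
#'   guidance is noise-free, so it tolerates (and profits from) weaker
#'   regularization than intensity DIR.
#' @return A [displacement_field].
#' @export
register_roi <- function(mask_ct, mask_cbct, config = registration_config(),
                         clamp_mm = 20, smoothness = 0.01) {
  if (!grid_equal(mask_ct$grid, mask_cbct$grid, tol = 1e-6))
    stop("label volumes must share one grid (resample the fraction labels first)")
  grid <- mask_ct$grid
  order <- roi_label_order()
  shared <- integer(0); dropped <- character(0)
  for (nm in names(order)[-1]) {
    l <- order[[nm]]
    if (any(mask_ct$labels == l) && any(mask_cbct$labels == l))
      shared <- c(shared, l)
    else dropped <- c(dropped, nm)
  }
  if (length(dropped))
    message("ROI registration drops absent label channel(s): ",
            paste(dropped, collapse = ", "))
  if (length(shared) < 3L)
    stop("fewer than 3 shared non-air labels: insufficient guidance for ROI registration")
  channels <- lapply(shared, function(l) {
    list(fixed = mask_signed_distance(mask_cbct$labels == l, grid, clamp_mm),
         moving = mask_signed_distance(mask_ct$labels == l, grid, clamp_mm),
         fill = clamp_mm)
  })
  spacings <- c(40, 25)
  .ffd_register(channels, grid, config, ctrl_spacings = spacings,
                lambda = smoothness)
}

#' Propagate target contours through the ROI registration field
#'
#' CTV/PTV are pull-warped and thresholded at 0.5; if the propagated PTV no
#' longer contains the CTV the containment is repaired by union (logged).
#'
#' @param targets [structure_set] containing CTV and/or PTV on the planning
#'   grid.
#' @param dvf [displacement_field] from [register_roi].
#' @param target_grid output grid (defaults to the targets' grid).
#' @return A [structure_set] of propagated targets.
#' @export
propagate_targets <- function(targets, dvf, target_grid = targets$grid) {
  names_t <- names(targets$masks)[targets$roles == "target"]
  if (!length(names_t)) stop("no target structures (CTV/PTV) to propagate")
  out <- list()
  for (nm in names_t) {
    m <- targets$masks[[nm]]
    if (!any(m)) stop("target '", nm, "' is empty before propagation")
    w <- propagate_mask(m, targets$grid, dvf, target_grid)
    if (!any(w))
      stop("target '", nm, "' is empty after propagation: implausible deformation")
    out[[nm]] <- w
  }
  if (!is.null(out$CTV) && !is.null(out$PTV) && any(out$CTV & !out$PTV)) {
    message("propagated PTV did not contain CTV; repaired by union")
    out$PTV <- out$PTV | out$CTV
  }
  structure_set(out, target_grid,
                roles = setNames(rep("target", length(out)), names(out)))
}
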