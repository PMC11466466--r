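#' Create an image volume
#'
#' A scalar 3D volume (HU, Gy or dimensionless) on a physical grid, tagged
#' with its modality role in the workflow.
#'
#' @param values numeric 3D array whose dimensions equal `grid$size`.
#' @param grid an [image_grid].
#' @param unit one of `"HU"`, `"Gy"`, `"dimensionless"`.
#' @param role one of `"planning_ct"`, `"cbct"`, `"sct"`, `"combined_ct"`,
#'   `"dpct"`, `"dose"`, `"density"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, grid,
                         unit = c("HU", "Gy", "dimensionless"),
                         role = c("planning_ct", "cbct", "sct", "combined_ct",
                                  "dpct", "dose", "density")) {
  unit <- match.arg(unit)
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$size))
    stop(sprintf("value-array shape (%s) does not match grid size (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(grid$size, collapse = "x")))
  if (unit == "HU" && any(!is.finite(values)))
    stop("HU volumes must be finite everywhere")
  if (unit == "Gy" && any(values < 0, na.rm = TRUE))
    stop("dose volumes must be non-negative")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, unit = unit, role = role),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s, %s] %dx%dx%d, range [%.1f, %.1f]\n",
              x$role, x$unit, x$grid$size[1], x$grid$size[2], x$grid$size[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Create a dose volume
#'
#' An [image_volume] in Gy carrying the plan's prescription, needed whenever
#' V_100% (volume at 100% of prescription) is requested.
#'
#' @param values non-negative 3D array of dose in Gy.
#' @param grid an [image_grid].
#' @param prescription prescription dose in Gy, or `NULL`.
#' @return An object of classes `dose_volume`, `image_volume`.
#' @export
dose_volume <- function(values, grid, prescription = NULL) {
  vol <- image_volume(values, grid, unit = "Gy", role = "dose")
  vol$prescription <- prescription
  class(vol) <- c("dose_volume", class(vol))
  vol
}

default_fill <- function(vol) {
  if (vol$unit == "HU") -1000 else 0
}

# downsample a volume by an integer factor with block-mean antialiasing
downsample_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  vals <- block_mean_cpp(vol$values, dim(vol$values), as.integer(f))
  nsz <- dim(vals)
  # block centers: first block covers indices 0..f-1, center at (f-1)/2
  off <- drop(.v2p(matrix((f - 1) / 2, ncol = 3L), vol$grid)) - vol$grid$origin
  g <- image_grid(nsz, vol$grid$spacing * f, vol$grid$origin + off, vol$grid$direction)
  v <- vol
  v$values <- array(vals, nsz)
  v$grid <- g
  v
}
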