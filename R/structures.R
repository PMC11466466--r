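#' Create a structure set
#'
#' Named binary masks sharing one grid, each tagged with one of the three
#' structure classes used by the workflow: *influencers* (deformable organs
#' near the target: bladder, rectum, small intestine, plus the skin/body
#' outline), *rigid organs* (femoral heads, pelvis, spinal cord, bone
#' marrow), and *targets* (CTV/PTV).
#'
#' @param masks named list of logical 3D arrays on `grid`.
#' @param grid shared [image_grid].
#' @param roles named character vector mapping structure name to
#'   `"influencer"`, `"rigid_organ"` or `"target"`; missing entries are
#'   guessed from standard names.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, grid, roles = NULL) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all masks must be named")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || !all(dim(m) == grid$size))
      stop("mask '", nm, "' does not match the shared grid")
    masks[[nm]] <- array(as.logical(m), grid$size)
  }
  full <- vapply(names(masks), function(nm) {
    if (!is.null(roles) && nm %in% names(roles)) roles[[nm]]
    else default_role(nm)
  }, character(1))
  bad <- setdiff(unique(full), c("influencer", "rigid_organ", "target"))
  if (length(bad)) stop("unknown structure role(s): ", paste(bad, collapse = ", "))
  structure(list(masks = masks, grid = grid, roles = full),
            class = "structure_set")
}

default_role <- function(name) {
  key <- tolower(name)
  if (key %in% c("ctv", "ptv")) "target"
  else if (key %in% c("bladder", "rectum", "small_intestine", "bowel", "skin",
                      "body")) "influencer"
  else "rigid_organ"
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set with %d structures on %dx%dx%d grid:\n",
              length(x$masks), x$grid$size[1], x$grid$size[2], x$grid$size[3]))
  for (nm in names(x$masks))
    cat(sprintf("  %-18s %-11s %d voxels\n", nm, x$roles[[nm]], sum(x$masks[[nm]])))
  invisible(x)
}

# case-insensitive structure lookup
get_mask <- function(ss, name) {
  hit <- which(tolower(names(ss$masks)) == tolower(name))
  if (!length(hit)) return(NULL)
  ss$masks[[hit[1]]]
}

#' Rasterize planar contours to a binary mask
#'
#' Each ring is a closed planar polygon (N x 3 mm points with constant z in
#' grid-slice orientation).  Rings are assigned to the nearest grid slice
#' within half a slice spacing (farther rings are skipped with a warning),
#' and combined per slice with the even-odd rule; a voxel is counted if its
#' *center* lies inside.
#'
#' @param contours list of N x 3 numeric matrices (mm), each a closed ring
#'   (the closing edge last-to-first is implied).
#' @param grid target [image_grid].
#' @return Logical 3D array on `grid`.
#' @export
rasterize_structure <- function(contours, grid) {
  mask <- array(FALSE, grid$size)
  if (!length(contours)) return(mask)
  ax <- grid_axis_coords(grid)
  for (ring in contours) {
    ring <- as.matrix(ring)
    if (nrow(ring) < 3L) {
      warning("skipping degenerate contour ring with fewer than 3 points")
      next
    }
    idx <- .p2v(ring, grid)
    kz <- idx[1, 3]
    k <- round(kz)
    if (abs(kz - k) > 0.5 + 1e-9 || k < 0 || k > grid$size[3] - 1) {
      warning("skipping contour ring farther than half a spacing from any slice")
      next
    }
    inside <- .ring_raster(idx[, 1:2, drop = FALSE], grid$size[1:2])
    mask[, , k + 1L] <- xor(mask[, , k + 1L], inside)
  }
  mask
}

# even-odd crossing test of integer voxel centers against one ring given in
# continuous index coords; vectorized over points, loop over edges
.ring_raster <- function(xy, sz) {
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  i0 <- max(0L, floor(xr[1])); i1 <- min(sz[1] - 1L, ceiling(xr[2]))
  j0 <- max(0L, floor(yr[1])); j1 <- min(sz[2] - 1L, ceiling(yr[2]))
  out <- matrix(FALSE, sz[1], sz[2])
  if (i1 < i0 || j1 < j0) return(out)
  px <- rep(i0:i1, times = j1 - j0 + 1L)
  py <- rep(j0:j1, each = i1 - i0 + 1L)
  crossings <- integer(length(px))
  n <- nrow(xy)
  for (e in seq_len(n)) {
    x1 <- xy[e, 1]; y1 <- xy[e, 2]
    f <- if (e == n) 1L else e + 1L
    x2 <- xy[f, 1]; y2 <- xy[f, 2]
    if (y1 == y2) next
    straddle <- which((y1 > py) != (y2 > py))
    if (!length(straddle)) next
    xint <- x1 + (py[straddle] - y1) / (y2 - y1) * (x2 - x1)
    hit <- straddle[px[straddle] < xint]
    crossings[hit] <- crossings[hit] + 1L
  }
  out[cbind(px + 1L, py + 1L)] <- (crossings %% 2L) == 1L
  out
}

#' Extract per-slice boundary contours from a binary mask
#'
#' Traces the boundary of the voxel-square union on each slice; vertices lie
#' on voxel edges (half-integer indices).  Rasterizing the result with
#' [rasterize_structure] reproduces the mask exactly (voxel centers are
#' strictly interior to their squares), so rasterize -> extract -> rasterize
#' is idempotent.
#'
#' @param mask logical 3D array.
#' @param grid the mask's [image_grid].
#' @return List of N x 3 mm rings.
#' @export
structure_contours <- function(mask, grid) {
  rings <- list()
  for (k in seq_len(grid$size[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    loops <- .trace_slice(sl)
    for (lp in loops) {
      idx <- cbind(lp[, 1], lp[, 2], k - 1)
      rings[[length(rings) + 1L]] <- .v2p(idx, grid)
    }
  }
  rings
}

# Chain directed boundary edges (inside on the left) into closed loops.
# Vertices at half-integer (i,j); keys use doubled integer coordinates.
.trace_slice <- function(sl) {
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sl
  ins <- which(pad, arr.ind = TRUE)
  segs <- list()
  add <- function(x1, y1, x2, y2) segs[[length(segs) + 1L]] <<- c(x1, y1, x2, y2)
  for (r in seq_len(nrow(ins))) {
    i <- ins[r, 1]; j <- ins[r, 2]
    # doubled, 0-based interior coords: voxel center (i-2, j-2), corners +-1
    cx <- 2L * (i - 2L); cy <- 2L * (j - 2L)
    if (!pad[i, j - 1L]) add(cx - 1L, cy - 1L, cx + 1L, cy - 1L)  # bottom, ->
    if (!pad[i + 1L, j]) add(cx + 1L, cy - 1L, cx + 1L, cy + 1L)  # right, ^
    if (!pad[i, j + 1L]) add(cx + 1L, cy + 1L, cx - 1L, cy + 1L)  # top, <-
    if (!pad[i - 1L, j]) add(cx - 1L, cy + 1L, cx - 1L, cy - 1L)  # left, v
  }
  if (!length(segs)) return(list())
  seg <- do.call(rbind, segs)
  keys <- paste(seg[, 1], seg[, 2])
  from <- split(seq_len(nrow(seg)), keys)
  used <- logical(nrow(seg))
  loops <- list()
  for (s0 in seq_len(nrow(seg))) {
    if (used[s0]) next
    loop <- list()
    cur <- s0
    repeat {
      used[cur] <- TRUE
      loop[[length(loop) + 1L]] <- seg[cur, 1:2]
      nxt_key <- paste(seg[cur, 3], seg[cur, 4])
      cand <- from[[nxt_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # saddle vertex: prefer the left turn to keep loops consistent
        dir_in <- seg[cur, 3:4] - seg[cur, 1:2]
        left <- c(-dir_in[2], dir_in[1])
        dots <- vapply(cand, function(s) sum((seg[s, 3:4] - seg[s, 1:2]) * left),
                       numeric(1))
        cand <- cand[which.max(dots)]
      }
      cur <- cand[1]
      if (cur == s0) break
    }
    if (length(loop) >= 3L)
      loops[[length(loops) + 1L]] <- do.call(rbind, loop) / 2
  }
  loops
}

# ---- mask morphology via the Euclidean distance transform -------------------

# mm distance from every voxel center to the nearest TRUE voxel center
mask_distance_to <- function(mask, grid) {
  sqrt(array(edt_sq_cpp(mask, dim(mask), grid$spacing), dim(mask)))
}

#' Signed distance map of a binary mask
#'
#' Positive outside, negative inside, in mm; optionally clamped.
#'
#' @param mask logical 3D array.
#' @param grid the mask's [image_grid].
#' @param clamp_mm clamp distances to `[-clamp_mm, clamp_mm]`; `NULL` for none.
#' @return Numeric 3D array.
#' @export
mask_signed_distance <- function(mask, grid, clamp_mm = NULL) {
  if (!any(mask)) {
    d <- array(if (is.null(clamp_mm)) Inf else clamp_mm, dim(mask))
    return(d)
  }
  d_out <- mask_distance_to(mask, grid)
  d_in <- mask_distance_to(!mask, grid)
  sd <- d_out - d_in
  if (!is.null(clamp_mm)) sd <- pmin(pmax(sd, -clamp_mm), clamp_mm)
  array(sd, dim(mask))
}

mask_dilate <- function(mask, grid, mm) {
  if (mm <= 0) return(mask)
  mask_distance_to(mask, grid) <= mm
}

mask_erode <- function(mask, grid, mm) {
  if (mm <= 0) return(mask)
  mask & !(mask_distance_to(!mask, grid) <= mm)
}
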