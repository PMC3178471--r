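#' Labelled voxel mask
#'
#' Container for a 3D binary (or branch-labelled) vessel mask on an
#' anisotropic voxel grid. Voxel values are 0 for background and positive
#' integers for vessel (1 = CCA, 2 = ICA, 3 = ECA in phantoms with branch
#' labels). World coordinates are in mm: the centre of voxel
#' `[i, j, k]` is at `origin + (c(i, j, k) - 1) * spacing`, with array
#' axis order fixed as (x, y, z).
#'
#' @param voxels 3D integer array of voxel labels (0 = background).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel `[1,1,1]`.
#' @return An object of class `labeled_mask`.
#' @examples
#' arr <- array(0L, c(8, 8, 8)); arr[3:6, 3:6, 3:6] <- 1L
#' m <- labeled_mask(arr, spacing = c(0.5, 0.5, 0.5))
#' m
#' @export
labeled_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3) stopf("voxels must be a 3D array")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive values (mm)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stopf("origin must be three finite values (mm)")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<labeled_mask> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  vessel voxels: %d (labels: %s)\n",
              sum(x$voxels > 0),
              paste(sort(unique(x$voxels[x$voxels > 0])), collapse = ", ")))
  invisible(x)
}

# TRUE if the world point falls on a vessel voxel (nearest-voxel lookup)
point_in_mask <- function(mask, p) {
  p <- as.numeric(p)
  idx <- round(world_to_index(p, mask$spacing, mask$origin))
  d <- dim(mask$voxels)
  if (any(idx < 1) || any(idx > d)) return(FALSE)
  mask$voxels[idx[1], idx[2], idx[3]] > 0
}

# nearest voxel (1-based linear index) to a world point, error if outside
# the vessel; `what` names the offending point in the error message
nearest_vessel_voxel <- function(mask, p, what = "point") {
  p <- as.numeric(p)
  idx <- round(world_to_index(p, mask$spacing, mask$origin))
  d <- dim(mask$voxels)
  if (any(idx < 1) || any(idx > d) ||
      mask$voxels[idx[1], idx[2], idx[3]] <= 0)
    stopf("%s (%.2f, %.2f, %.2f) mm is outside the vessel mask",
          what, p[1], p[2], p[3])
  linear_index(idx, d)
}
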