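#' Centerline curve
#'
#' An ordered polyline (world mm) describing one vessel branch, with its
#' arc length `L`, endpoint chord `D` and tortuosity `L/D - 1` attached.
#' By convention branch curves run from the free end toward the
#' bifurcation point (the last point).
#'
#' @param points numeric matrix (n x 3) of mm coordinates, n >= 2 with
#'   distinct endpoints.
#' @return object of class `centerline_curve`: the points matrix with
#'   attributes `L`, `D`, `tortuosity`.
#' @export
centerline_curve <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2)
    stopf("a centerline needs at least 2 points in 3D")
  L <- polyline_length(points)
  D <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (D <= 0) stopf("degenerate centerline: coincident endpoints")
  structure(points, class = "centerline_curve",
            L = L, D = D, tortuosity = L / D - 1)
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("<centerline_curve> %d points, L = %.2f mm, D = %.2f mm, tortuosity = %.4f\n",
              nrow(x), attr(x, "L"), attr(x, "D"), attr(x, "tortuosity")))
  invisible(x)
}

#' Tortuosity of a curve
#'
#' Tortuosity is `(L / D) - 1` where `L` is the arc length along the
#' curve and `D` the Euclidean distance between its endpoints: 0 for a
#' straight segment, `pi/2 - 1` for a semicircle. For curves extracted
#' from masks it is computed on the smoothed, resampled polyline (so `L`
#' depends mildly on the resampling step, documented in
#' [minimal_cost_path()]).
#'
#' @param curve a [centerline_curve()] or an n x 3 matrix of points.
#' @return dimensionless tortuosity (>= 0).
#' @examples
#' th <- seq(0, pi, length.out = 500)
#' tortuosity(cbind(cos(th), sin(th), 0))  # ~ pi/2 - 1
#' @export
tortuosity <- function(curve) {
  curve <- centerline_curve(unclass(curve))
  attr(curve, "tortuosity")
}

#' Euclidean distance map of a vessel mask
#'
#' Distance (mm) from each vessel voxel centre to the nearest background
#' voxel centre, aware of anisotropic spacing; 0 outside the vessel.
#' This is the radius of the maximally inscribed sphere used by radius
#' measurement method A and by the minimal-cost-path edge weights.
#'
#' @param mask a [labeled_mask()] with at least one vessel voxel.
#' @return object of class `distance_map` (list: `values` 3D array in mm,
#'   `spacing`, `origin`).
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (!any(mask$voxels > 0)) stopf("empty mask: no vessel voxels")
  d <- dim(mask$voxels)
  vals <- cpp_edt(as.integer(mask$voxels), d, mask$spacing)
  dim(vals) <- d
  structure(list(values = vals, spacing = mask$spacing,
                 origin = mask$origin),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> max inscribed-sphere radius %.2f mm\n",
              max(x$values)))
  invisible(x)
}

# trilinear sample of a distance map (or any voxel field) at world points
sample_field <- function(field, points) {
  cpp_trilinear(as.double(field$values), dim(field$values),
                field$spacing, field$origin, as.matrix(points))
}

#' Minimal cost path between two points inside a vessel
#'
#' Shortest path on the 26-connected voxel graph restricted to vessel
#' voxels, with edge cost `step_length / (1 + DT)` where `DT` is the
#' distance-map value at the target voxel. The `1/(1+DT)` medialness
#' weight pulls the path onto the lumen centre, so the result is a
#' centerline sketch of the vessel. The voxel path is resampled at
#' `0.5 * min(spacing)` and smoothed by a 5-point moving average
#' (endpoints preserved) before being returned.
#'
#' @param mask a [labeled_mask()].
#' @param a,b world coordinates (mm) of the endpoints; both must lie on
#'   vessel voxels and be connected through the mask.
#' @param dmap optional precomputed [distance_map()] of `mask`.
#' @return a [centerline_curve()] from `a` to `b`, with attributes
#'   `cost` (accumulated edge cost) and `voxel_path` (1-based linear
#'   indices of the raw voxel path).
#' @export
minimal_cost_path <- function(mask, a, b, dmap = NULL) {
  stopifnot(inherits(mask, "labeled_mask"))
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (isTRUE(all.equal(a, b)))
    stopf("degenerate path: endpoints a and b coincide")
  va <- nearest_vessel_voxel(mask, a, "endpoint a")
  vb <- nearest_vessel_voxel(mask, b, "endpoint b")
  if (is.null(dmap)) dmap <- distance_map(mask)
  res <- cpp_dijkstra(as.integer(mask$voxels), dim(mask$voxels),
                      mask$spacing, as.double(dmap$values), va, vb)
  if (!isTRUE(res$reachable))
    stopf("endpoints a and b are not connected through the vessel mask")
  pts <- index_to_world(linear_to_ijk(res$path, dim(mask$voxels)),
                        matrix(mask$spacing, length(res$path), 3,
                               byrow = TRUE),
                        matrix(mask$origin, length(res$path), 3,
                               byrow = TRUE))
  smoothed <- smooth_polyline(resample_polyline(pts,
                                                0.5 * min(mask$spacing)),
                              5L)
  # ridge refinement corrects sub-voxel bias but adds transverse jitter;
  # a second smoothing pass removes it so arc lengths stay honest
  refined <- smooth_polyline(refine_to_ridge(smoothed, dmap), 5L)
  curve <- centerline_curve(refined)
  attr(curve, "cost") <- res$cost
  attr(curve, "voxel_path") <- res$path
  curve
}

# snap centerline points onto the ridge of the interpolated distance
# map: one bounded quadratic-peak step per iteration in each of the two
# directions perpendicular to the local tangent.  Corrects the
# half-voxel bias of discrete paths whose corridor straddles voxel rows.
refine_to_ridge <- function(pts, dmap, delta = NULL, iters = 3L) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  if (is.null(delta)) delta <- 0.25 * min(dmap$spacing)
  for (it in seq_len(iters)) {
    tang <- pts[c(2:n, n), , drop = FALSE] -
      pts[c(1, 1:(n - 1)), , drop = FALSE]
    bs <- plane_bases(tang)
    for (e in list(bs$e1, bs$e2)) {
      d0 <- sample_field(dmap, pts)
      dm_ <- sample_field(dmap, pts - delta * e)
      dp_ <- sample_field(dmap, pts + delta * e)
      denom <- 2 * d0 - dm_ - dp_
      off <- ifelse(denom > 0,
                    pmax(-delta, pmin(delta,
                                      0.5 * delta * (dp_ - dm_) / denom)),
                    0)                         # flat or saddle: stay put
      cand <- pts + off * e
      ok <- sample_field(dmap, cand) > 0
      pts[ok, ] <- cand[ok, , drop = FALSE]
    }
  }
  pts
}

# choose, for each branch, the marker farthest from the centroid of all
# markers: the free-end marker under the two-markers-per-branch layout
pick_end_markers <- function(markers) {
  markers$branch <- tolower(markers$branch)
  ctr <- colMeans(markers[, c("x_mm", "y_mm", "z_mm")])
  out <- list()
  for (b in unique(markers$branch)) {
    m <- markers[markers$branch == b, , drop = FALSE]
    d <- sqrt((m$x_mm - ctr[1])^2 + (m$y_mm - ctr[2])^2 +
              (m$z_mm - ctr[3])^2)
    out[[b]] <- as.numeric(m[which.max(d), c("x_mm", "y_mm", "z_mm")])
  }
  out
}

#' Extract the three branch centerlines of a bifurcation
#'
#' Computes minimal cost paths from the CCA end marker to the ICA and
#' ECA end markers, locates the bifurcation point as the last voxel the
#' two paths share (ties broken toward the CCA side), and splits the
#' paths there into three branch curves. Each branch curve runs from
#' its free end to the bifurcation point and is smoothed/resampled as in
#' [minimal_cost_path()], with the bifurcation point preserved as the
#' exact shared terminus.
#'
#' @param mask a [labeled_mask()].
#' @param markers data.frame with columns `branch` (values cca/ica/eca,
#'   at least one marker each; with two markers per branch the outer one
#'   is used as the branch end), `x_mm`, `y_mm`, `z_mm`.
#' @param dmap optional precomputed [distance_map()].
#' @return object of class `bifurcation_centerlines`: list with
#'   `cca`, `ica`, `eca` ([centerline_curve]s) and `bifurcation_point`.
#' @export
extract_bifurcation <- function(mask, markers, dmap = NULL) {
  stopifnot(inherits(mask, "labeled_mask"))
  need <- c("cca", "ica", "eca")
  ends <- pick_end_markers(markers)
  if (!all(need %in% names(ends)))
    stopf("markers must include branches cca, ica and eca")
  for (b in need)
    nearest_vessel_voxel(mask, ends[[b]], paste(toupper(b), "marker"))
  if (is.null(dmap)) dmap <- distance_map(mask)

  p_ica <- minimal_cost_path(mask, ends$cca, ends$ica, dmap)
  p_eca <- minimal_cost_path(mask, ends$cca, ends$eca, dmap)
  v1 <- attr(p_ica, "voxel_path")
  v2 <- attr(p_eca, "voxel_path")
  dims <- dim(mask$voxels)
  to_world <- function(idx) {
    n <- length(idx)
    index_to_world(linear_to_ijk(idx, dims),
                   matrix(mask$spacing, n, 3, byrow = TRUE),
                   matrix(mask$origin, n, 3, byrow = TRUE))
  }
  # smooth, resample and ridge-refine both full paths: in the shared
  # parent corridor the two refined paths snap onto the same medial
  # ridge, so their pointwise separation stays near zero until the
  # ridge itself bifurcates
  polish <- function(v) {
    sm <- smooth_polyline(resample_polyline(to_world(v),
                                            0.5 * min(mask$spacing)), 5L)
    smooth_polyline(refine_to_ridge(sm, dmap), 5L)
  }
  p1 <- polish(v1)
  p2 <- polish(v2)

  # preliminary split: last point of the CCA->ICA path still within one
  # voxel diagonal of the CCA->ECA path (ties toward the CCA side).
  # Equal-cost discrete paths can run on adjacent voxel rows of the
  # parent corridor, so proximity -- not identity -- defines "common";
  # and because minimal cost paths merge smoothly through the junction
  # bulb, this point lies a little downstream of the anatomical apex.
  thr <- sqrt(sum(mask$spacing^2))
  cross2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * tcrossprod(p1, p2)
  near1 <- sqrt(pmax(apply(cross2, 1, min), 0)) <= thr
  near2 <- sqrt(pmax(apply(cross2, 2, min), 0)) <= thr
  i_bif <- if (near1[1]) which(c(!near1, TRUE))[1] - 1L else 0L
  j_bif <- if (near2[1]) which(c(!near2, TRUE))[1] - 1L else 0L
  if (i_bif < 2L || j_bif < 2L)
    stopf(paste("paths to ICA and ECA share no common prefix;",
                "markers appear misplaced"))

  # apex reconstruction: fit a straight axis to each branch over a short
  # window clear of the junction bulb and take the least-squares point
  # closest to the three lines
  s1 <- cumulative_arc(p1)
  s2 <- cumulative_arc(p2)
  fit_line <- function(pts) {
    ctr <- colMeans(pts)
    u <- svd(sweep(pts, 2, ctr))$v[, 1]
    list(p = ctr, u = u)
  }
  seg_window <- function(pts, s_rel, lo = 3, hi = 9) {
    sel <- s_rel >= lo & s_rel <= hi
    if (sum(sel) < 5) sel <- s_rel >= lo   # short branch: use what exists
    pts[sel, , drop = FALSE]
  }
  lines3 <- list(
    fit_line(seg_window(p1, s1[i_bif] - s1)),                 # CCA side
    fit_line(seg_window(p1, s1 - s1[i_bif])),                 # ICA side
    fit_line(seg_window(p2, s2 - s2[j_bif])))                 # ECA side
  A <- matrix(0, 3, 3)
  bvec <- numeric(3)
  for (ln in lines3) {
    P <- diag(3) - tcrossprod(ln$u)
    A <- A + P
    bvec <- bvec + P %*% ln$p
  }
  apex <- as.numeric(solve(A, bvec))
  # accept the reconstruction only if it stays within the junction bulb
  # (whose size scales with the parent calibre); guards against strongly
  # curved branches where straight-axis fits are meaningless
  bulb <- max(4 * max(mask$spacing),
              1.5 * sample_field(dmap, p1[i_bif, , drop = FALSE]))
  if (sqrt(sum((apex - p1[i_bif, ])^2)) <= bulb &&
      point_in_mask(mask, apex)) {
    i_bif <- which.min(rowSums(sweep(p1, 2, apex)^2))
    j_bif <- which.min(rowSums(sweep(p2, 2, apex)^2))
    bif <- apex
  } else {
    bif <- as.numeric(p1[i_bif, ])
  }

  as_branch <- function(pts_free_to_bif) {
    pts <- pts_free_to_bif
    pts[nrow(pts), ] <- bif
    centerline_curve(pts)
  }
  cca <- as_branch(p1[seq_len(i_bif), , drop = FALSE])  # free end first
  ica <- as_branch(p1[nrow(p1):i_bif, , drop = FALSE])
  eca <- as_branch(p2[nrow(p2):j_bif, , drop = FALSE])

  structure(list(cca = cca, ica = ica, eca = eca,
                 bifurcation_point = bif),
            class = "bifurcation_centerlines")
}

#' @export
print.bifurcation_centerlines <- function(x, ...) {
  cat(sprintf("<bifurcation_centerlines> bifurcation at (%.1f, %.1f, %.1f) mm\n",
              x$bifurcation_point[1], x$bifurcation_point[2],
              x$bifurcation_point[3]))
  for (b in c("cca", "ica", "eca"))
    cat(sprintf("  %s: L = %.1f mm, tortuosity = %.4f\n",
                toupper(b), attr(x[[b]], "L"), attr(x[[b]], "tortuosity")))
  invisible(x)
}
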