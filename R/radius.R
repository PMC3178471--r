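#' Radius profile of a branch
#'
#' Internal constructor for the per-branch radius-versus-arc-length
#' profile. `s_mm` is measured along the centerline starting at the
#' branch terminus (the bifurcation point for branch curves), strictly
#' increasing; `r_mm` > 0.
#'
#' @param s_mm,r_mm numeric vectors.
#' @param method `"A"` (inscribed sphere) or `"B"` (equivalent radius).
#' @return data.frame of class `radius_profile` with attribute `method`.
#' @keywords internal
radius_profile <- function(s_mm, r_mm, method) {
  keep <- is.finite(r_mm) & r_mm > 0
  s_mm <- s_mm[keep]
  r_mm <- r_mm[keep]
  if (!length(s_mm)) stopf("empty radius profile")
  o <- order(s_mm)
  structure(data.frame(s_mm = s_mm[o], r_mm = r_mm[o]),
            class = c("radius_profile", "data.frame"),
            method = method)
}

# arc position of each curve point measured from the LAST point (the
# bifurcation end by convention); same order as the points
arc_from_terminus <- function(curve) {
  s <- cumulative_arc(unclass(curve))
  s[length(s)] - s
}

#' Radius by maximally inscribed sphere (method A)
#'
#' At every centerline point the radius is the distance-map value, i.e.
#' the radius of the maximally inscribed sphere centred there. This is
#' the closest analogue of clinical calliper measurements but
#' underestimates the equivalent radius of non-circular lumens (for an
#' elliptical cross-section it returns the minor semi-axis).
#'
#' The distance map is sampled with a ridge-aware (tent-peak) scheme:
#' along each of the two directions perpendicular to the local tangent
#' the inscribed-sphere radius falls off linearly away from the medial
#' axis, so the on-axis value is reconstructed as
#' `(D(p + d e) + D(p - d e)) / 2 + d` with `d` half a voxel; the
#' binding (smaller) of the two directional estimates is returned.
#' Plain trilinear sampling flattens this linear peak and reads up to
#' half a voxel low whenever the axis passes between voxel rows.
#'
#' @param curve a [centerline_curve()] lying inside the mask.
#' @param dmap the [distance_map()] of the mask.
#' @return a `radius_profile` (method "A") with `s_mm` measured from the
#'   curve terminus (bifurcation end).
#' @export
radius_method_a <- function(curve, dmap) {
  stopifnot(inherits(dmap, "distance_map"))
  pts <- unclass(curve)
  d0 <- sample_field(dmap, pts)
  if (any(d0 <= 0))
    stopf("centerline point outside the vessel mask (distance map <= 0)")
  n <- nrow(pts)
  tang <- pts[c(2:n, n), , drop = FALSE] -
    pts[c(1, 1:(n - 1)), , drop = FALSE]
  bs <- plane_bases(tang)
  delta <- 0.5 * min(dmap$spacing)
  est1 <- (sample_field(dmap, pts + delta * bs$e1) +
           sample_field(dmap, pts - delta * bs$e1)) / 2 + delta
  est2 <- (sample_field(dmap, pts + delta * bs$e2) +
           sample_field(dmap, pts - delta * bs$e2)) / 2 + delta
  r <- pmax(d0, pmin(est1, est2))
  radius_profile(arc_from_terminus(curve), r, method = "A")
}

#' Radius by perpendicular cross-sectional area (method B)
#'
#' At selected centerline points the tangent is estimated by central
#' differences on the smoothed curve; the lumen cross-sectional area in
#' the perpendicular plane is estimated by sampling the mask with
#' trilinear interpolation on a 2D grid (pitch `0.2 * min(spacing)`,
#' extent `4 * u` centred on the point, threshold 0.5), and the
#' equivalent radius is `sqrt(A / pi)`. Equals method A for circular
#' cross-sections; larger than method A for non-circular convex lumens.
#'
#' @param curve a [centerline_curve()] with at least 5 points.
#' @param mask the [labeled_mask()].
#' @param u scale radius (mm) fixing the sampling extent; defaults to
#'   the median method-A radius along the curve (requires `dmap`).
#' @param at_s optional arc positions (mm from the curve terminus) at
#'   which to evaluate; default: every centerline point.
#' @param dmap optional [distance_map()], needed only when `u` is NULL.
#' @return a `radius_profile` (method "B").
#' @export
radius_method_b <- function(curve, mask, u = NULL, at_s = NULL,
                            dmap = NULL) {
  stopifnot(inherits(mask, "labeled_mask"))
  pts <- unclass(curve)
  if (nrow(pts) < 5)
    stopf("curve too short to estimate tangents (need >= 5 points)")
  if (is.null(u)) {
    if (is.null(dmap)) dmap <- distance_map(mask)
    u <- median(radius_method_a(curve, dmap)$r_mm)
  }
  s_all <- arc_from_terminus(curve)
  if (is.null(at_s)) at_s <- s_all

  # tangents by central differences (one-sided at the ends)
  n <- nrow(pts)
  tang <- (pts[c(2:n, n), ] - pts[c(1, 1:(n - 1)), ])
  pitch <- 0.2 * min(mask$spacing)
  half <- 2 * u
  g <- seq(-half, half, by = pitch)
  grid2 <- as.matrix(expand.grid(a = g, b = g))
  maskd <- list(values = array(as.double(mask$voxels > 0),
                               dim(mask$voxels)),
                spacing = mask$spacing, origin = mask$origin)

  # map requested arc positions to curve points (nearest sample)
  idx <- vapply(at_s, function(s) which.min(abs(s_all - s)), integer(1))
  r_out <- numeric(length(idx))
  for (m in seq_along(idx)) {
    i <- idx[m]
    tg <- tang[i, ]
    if (sqrt(sum(tg^2)) == 0) stopf("tangent undefined on degenerate curve")
    bs <- plane_basis(tg)
    pp <- cbind(pts[i, 1] + grid2[, 1] * bs$e1[1] + grid2[, 2] * bs$e2[1],
                pts[i, 2] + grid2[, 1] * bs$e1[2] + grid2[, 2] * bs$e2[2],
                pts[i, 3] + grid2[, 1] * bs$e1[3] + grid2[, 2] * bs$e2[3])
    vals <- cpp_trilinear(maskd$values, dim(mask$voxels), mask$spacing,
                          mask$origin, pp)
    area <- sum(vals >= 0.5) * pitch^2
    r_out[m] <- sqrt(area / pi)
  }
  radius_profile(s_all[idx], r_out, method = "B")
}

#' Measured radius triple of a bifurcation
#'
#' Applies the artery-scaled measurement windows to the three branch
#' profiles: the CCA radius is taken at 2 unit radii from the
#' bifurcation point, the ICA radius is the median over 6 to 12 unit
#' radii (avoiding the carotid sinus), and the ECA radius is the median
#' over 2 to 7 unit radii (avoiding the ECA's own bifurcation
#' artifacts). The unit radius `u` of each branch is its median
#' method-A radius over the full branch profile, computed once before
#' windowing; distances are arc lengths along the centerline from the
#' bifurcation point. Medians over an even number of samples are the
#' mean of the middle two.
#'
#' @param bc a `bifurcation_centerlines` from [extract_bifurcation()].
#' @param dmap the [distance_map()] of the mask.
#' @param mask the [labeled_mask()]; required for `method` "B" or
#'   "both".
#' @param method `"A"`, `"B"` or `"both"`.
#' @return for a single method, a `radius_triple` (named list `r_cca`,
#'   `r_ica`, `r_eca` in mm plus `method`); for "both", a list with
#'   elements `A` and `B`.
#' @export
measure_triple <- function(bc, dmap, mask = NULL,
                           method = c("A", "B", "both")) {
  method <- match.arg(method)
  stopifnot(inherits(bc, "bifurcation_centerlines"))
  if (method != "A" && is.null(mask))
    stopf("method B needs the mask")

  prof_a <- lapply(bc[c("cca", "ica", "eca")], radius_method_a,
                   dmap = dmap)
  u <- vapply(prof_a, function(p) median(p$r_mm), numeric(1))
  win <- list(cca = c(2, 2), ica = c(6, 12), eca = c(2, 7))

  check_length <- function(branch) {
    need <- win[[branch]][2] * u[[branch]]
    have <- max(prof_a[[branch]]$s_mm)
    if (have < need)
      stopf("%s branch too short: window needs centerline length >= %.1f mm, have %.1f mm",
            toupper(branch), need, have)
  }
  for (b in c("cca", "ica", "eca")) check_length(b)

  one_method <- function(tag) {
    get_r <- function(branch, at_s) {
      if (tag == "A") {
        p <- prof_a[[branch]]
        interp_at(p$s_mm, p$r_mm, at_s)
      } else {
        radius_method_b(bc[[branch]], mask, u = u[[branch]],
                        at_s = at_s)$r_mm
      }
    }
    window_s <- function(branch) {
      p <- prof_a[[branch]]
      w <- win[[branch]] * u[[branch]]
      p$s_mm[p$s_mm >= w[1] & p$s_mm <= w[2]]
    }
    r_cca <- get_r("cca", 2 * u[["cca"]])
    r_ica <- median(get_r("ica", window_s("ica")))
    r_eca <- median(get_r("eca", window_s("eca")))
    radius_triple(r_cca, r_ica, r_eca, method = tag)
  }

  switch(method,
         A = one_method("A"),
         B = one_method("B"),
         both = list(A = one_method("A"), B = one_method("B")))
}

#' Radius triple
#'
#' The measured (parent, daughter, daughter) radii of one bifurcation
#' under one measurement method.
#'
#' @param r_cca,r_ica,r_eca radii in mm (> 0).
#' @param method measurement method tag ("A" or "B").
#' @return object of class `radius_triple`.
#' @export
radius_triple <- function(r_cca, r_ica, r_eca, method = "A") {
  v <- c(r_cca = r_cca, r_ica = r_ica, r_eca = r_eca)
  if (any(!is.finite(v)) || any(v <= 0))
    stopf("all radii must be positive and finite")
  structure(list(r_cca = r_cca, r_ica = r_ica, r_eca = r_eca,
                 method = method),
            class = "radius_triple")
}

#' @export
print.radius_triple <- function(x, ...) {
  cat(sprintf("<radius_triple method %s> CCA %.2f, ICA %.2f, ECA %.2f mm\n",
              x$method, x$r_cca, x$r_ica, x$r_eca))
  invisible(x)
}
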