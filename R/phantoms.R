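#' Specification of a bifurcation phantom
#'
#' Describes a synthetic carotid-like bifurcation: a parent tube (CCA)
#' dividing into two daughter tubes (ICA, ECA) at known angles, with an
#' optional carotid-sinus bulge on the proximal ICA and optional
#' sinusoidal curvature (tortuosity) of the ICA centerline.
#'
#' Branch lengths must be at least 14 times the branch radius so that the
#' distal ICA measurement window (6 to 12 radii from the bifurcation)
#' fits inside the branch with slack at the free end.
#'
#' @param r_cca,r_ica,r_eca branch radii in mm (all > 0).
#' @param branch_lengths named numeric (cca, ica, eca) lengths in mm;
#'   default 14.5 radii per branch.
#' @param branch_angles named numeric (ica, eca): angle in degrees between
#'   each daughter axis and the parent axis.
#' @param sinus_bulge_factor dimensionless >= 1; local ICA dilation,
#'   applied over arc length 0 to 5 `r_ica` from the bifurcation so the
#'   6r-12r measurement window is unaffected.
#' @param curvature_amplitude mm; amplitude of a sinusoidal out-of-plane
#'   displacement of the ICA centerline (controls ICA tortuosity).
#' @param spacing voxel spacing (mm); default 0.5 mm isotropic.
#' @param margin mm of background padding around the vessel.
#' @return An object of class `phantom_spec`.
#' @seealso [make_bifurcation_phantom()]
#' @export
phantom_spec <- function(r_cca, r_ica, r_eca,
                         branch_lengths = NULL,
                         branch_angles = c(ica = 25, eca = 25),
                         sinus_bulge_factor = 1,
                         curvature_amplitude = 0,
                         spacing = c(0.5, 0.5, 0.5),
                         margin = 4) {
  radii <- c(cca = r_cca, ica = r_ica, eca = r_eca)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stopf("all radii must be positive")
  if (is.null(branch_lengths)) branch_lengths <- 14.5 * radii
  branch_lengths <- branch_lengths[c("cca", "ica", "eca")]
  if (any(is.na(branch_lengths)))
    stopf("branch_lengths must be named (cca, ica, eca)")
  short <- branch_lengths < 14 * radii
  if (any(short))
    stopf("branch length must be >= 14 * radius (violated for %s)",
          paste(names(radii)[short], collapse = ", "))
  if (any(spacing <= 0)) stopf("spacing components must be > 0")
  if (sinus_bulge_factor < 1) stopf("sinus_bulge_factor must be >= 1")
  if (curvature_amplitude < 0) stopf("curvature_amplitude must be >= 0")
  structure(list(r_cca = r_cca, r_ica = r_ica, r_eca = r_eca,
                 branch_lengths = branch_lengths,
                 branch_angles = branch_angles[c("ica", "eca")],
                 sinus_bulge_factor = sinus_bulge_factor,
                 curvature_amplitude = curvature_amplitude,
                 spacing = as.numeric(spacing), margin = margin),
            class = "phantom_spec")
}

# sinusoidal centerline used by tube/ICA curvature: straight axis of
# chord `length` with transverse displacement A * sin(2*pi*s/length), so
# the endpoints stay on the axis and chord length equals `length`
sine_curve_points <- function(length, amplitude, step) {
  t <- seq(0, length, by = step)
  if (t[length(t)] < length) t <- c(t, length)
  cbind(t, amplitude * sin(2 * pi * t / length), 0)
}

sine_arc_length <- function(length, amplitude) {
  w <- 2 * pi / length
  integrate(function(t) sqrt(1 + (amplitude * w * cos(w * t))^2),
            0, length, rel.tol = 1e-10)$value
}

#' Sinusoid amplitude achieving a target tortuosity
#'
#' For the single-period sinusoidal centerline used by [make_tube_mask()]
#' (chord `length`, transverse displacement `A * sin(2*pi*t/length)`),
#' finds the amplitude `A` whose arc length gives tortuosity
#' `L/D - 1 = tortuosity`.
#'
#' @param length chord length of the tube centerline, mm.
#' @param tortuosity target tortuosity (>= 0, dimensionless).
#' @return amplitude in mm.
#' @examples
#' a <- tube_amplitude_for_tortuosity(40, 0.1)
#' @export
tube_amplitude_for_tortuosity <- function(length, tortuosity) {
  if (tortuosity < 0) stopf("tortuosity must be >= 0")
  if (tortuosity == 0) return(0)
  target <- length * (1 + tortuosity)
  uniroot(function(a) sine_arc_length(length, a) - target,
          interval = c(0, length), tol = 1e-10)$root
}

# shared finishing step: shift geometry into a padded grid and voxelize
build_phantom_mask <- function(centerlines, radii_fun, labels, spacing,
                               margin, rmax) {
  allpts <- do.call(rbind, centerlines)
  lo <- apply(allpts, 2, min) - rmax - margin
  hi <- apply(allpts, 2, max) + rmax + margin
  shift <- -lo
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)

  segs <- NULL
  for (b in seq_along(centerlines)) {
    pts <- sweep(centerlines[[b]], 2, shift, "+")
    s <- cumulative_arc(pts)
    r <- radii_fun[[b]](s)
    n <- nrow(pts)
    segs <- rbind(segs, cbind(pts[-n, , drop = FALSE],
                              pts[-1, , drop = FALSE],
                              r[-n], r[-1], labels[b]))
  }
  vox <- cpp_voxelize(dims, spacing, c(0, 0, 0), segs)
  dim(vox) <- dims
  list(mask = labeled_mask(vox, spacing), shift = shift)
}

#' Voxelized tube phantom
#'
#' Generates a binary mask of a constant-radius tube around a straight or
#' sinusoidally curved centerline, together with its analytic ground
#' truth. A voxel is vessel iff its centre lies within `radius` of the
#' centerline curve.
#'
#' @param radius tube radius, mm; must be at least `2 * max(spacing)` to
#'   be resolved by the grid.
#' @param length centerline chord length, mm (>= 4 radii).
#' @param spacing voxel spacing, mm.
#' @param curvature_amplitude mm; sinusoidal displacement amplitude
#'   (0 = straight cylinder). See [tube_amplitude_for_tortuosity()].
#' @param margin background padding, mm.
#' @return list with elements `mask` ([labeled_mask]) and `truth` (class
#'   `ground_truth`: centerline polyline in world mm, constant radius,
#'   tortuosity, and marker endpoints).
#' @examples
#' ph <- make_tube_mask(3, 40, spacing = c(0.5, 0.5, 0.5))
#' ph$truth$tortuosity
#' @export
make_tube_mask <- function(radius, length, spacing = c(0.5, 0.5, 0.5),
                           curvature_amplitude = 0, margin = 4) {
  if (radius < 2 * max(spacing))
    stopf(paste("radius %.2f mm is under-resolved at spacing (%g, %g, %g) mm;",
                "need radius >= 2 * max(spacing)"),
          radius, spacing[1], spacing[2], spacing[3])
  if (length < 4 * radius) stopf("length must be >= 4 * radius")

  step <- min(spacing) / 4
  cl <- sine_curve_points(length, curvature_amplitude, step)
  built <- build_phantom_mask(list(cl), list(function(s) rep(radius,
                                                             length(s))),
                              1L, spacing, margin, radius)
  cl_w <- sweep(cl, 2, built$shift, "+")
  L <- polyline_length(cl_w)
  D <- sqrt(sum((cl_w[nrow(cl_w), ] - cl_w[1, ])^2))
  markers <- data.frame(branch = "tube",
                        x_mm = cl_w[c(1, nrow(cl_w)), 1],
                        y_mm = cl_w[c(1, nrow(cl_w)), 2],
                        z_mm = cl_w[c(1, nrow(cl_w)), 3])
  truth <- structure(list(centerlines = list(tube = cl_w),
                          radius = list(tube = radius),
                          tortuosity = L / D - 1,
                          markers = markers),
                     class = "ground_truth")
  list(mask = built$mask, truth = truth)
}

#' Voxelized bifurcation phantom
#'
#' Builds the union of three constant-radius tubes (CCA, ICA, ECA)
#' meeting at a bifurcation point, with optional proximal-ICA sinus
#' bulge and ICA centerline curvature, and records the analytic ground
#' truth (per-branch centerlines from the bifurcation outward, radius
#' profiles, bifurcation point, marker endpoints, ICA tortuosity).
#'
#' The parent axis lies along -x; the daughters leave the bifurcation at
#' `branch_angles` above/below the +x axis in the xy plane. Branch
#' voxel labels are 1 (CCA), 2 (ICA), 3 (ECA), assigned by the most
#' interior claim where tubes overlap near the junction. The sinus
#' bulge scales the ICA radius by up to `sinus_bulge_factor` inside arc
#' length `[0, 5 r_ica]` from the bifurcation (a sin^2 window), leaving
#' the 6r-12r ICA measurement window untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `mask` and `truth` as in [make_tube_mask()].
#' @examples
#' sp <- phantom_spec(4, 2.68, 2.44)
#' ph <- make_bifurcation_phantom(sp)
#' @export
make_bifurcation_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  th_i <- spec$branch_angles[["ica"]] * pi / 180
  th_e <- spec$branch_angles[["eca"]] * pi / 180
  l <- spec$branch_lengths
  step <- min(spec$spacing) / 4

  # bifurcation at the (pre-shift) origin
  s_cca <- seq(0, l[["cca"]], by = step)
  cl_cca <- cbind(-s_cca, 0, 0)

  u_i <- c(cos(th_i), sin(th_i), 0)
  s_ica <- seq(0, l[["ica"]], by = step)
  cl_ica <- outer(s_ica, u_i)
  if (spec$curvature_amplitude > 0)
    cl_ica[, 3] <- spec$curvature_amplitude *
      sin(2 * pi * s_ica / l[["ica"]])

  u_e <- c(cos(th_e), -sin(th_e), 0)
  s_eca <- seq(0, l[["eca"]], by = step)
  cl_eca <- outer(s_eca, u_e)

  r_ica_fun <- function(s) {
    r <- rep(spec$r_ica, length(s))
    w <- 5 * spec$r_ica
    inb <- s < w
    r[inb] <- spec$r_ica *
      (1 + (spec$sinus_bulge_factor - 1) * sin(pi * s[inb] / w)^2)
    r
  }
  r_cca_fun <- function(s) rep(spec$r_cca, length(s))
  r_eca_fun <- function(s) rep(spec$r_eca, length(s))

  # daughters must separate beyond the junction region, else the two
  # measurement windows would sample one merged lumen
  s0 <- 4 * max(spec$r_ica, spec$r_eca)
  chk_i <- s_ica[s_ica > s0]
  chk_e <- s_eca[s_eca > s0]
  if (length(chk_i) && length(chk_e)) {
    ci <- cl_ica[s_ica > s0, , drop = FALSE]
    ce <- cl_eca[s_eca > s0, , drop = FALSE]
    keep <- seq(1, nrow(ci), by = max(1L, nrow(ci) %/% 50))
    keep2 <- seq(1, nrow(ce), by = max(1L, nrow(ce) %/% 50))
    d2 <- outer(rowSums(ci[keep, , drop = FALSE]^2),
                rowSums(ce[keep2, , drop = FALSE]^2), "+") -
      2 * tcrossprod(ci[keep, , drop = FALSE], ce[keep2, , drop = FALSE])
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < spec$r_ica * spec$sinus_bulge_factor + spec$r_eca)
      stopf(paste("daughter branches overlap beyond the junction region;",
                  "increase the branch angles"))
  }

  rmax <- max(spec$r_cca, spec$r_ica * spec$sinus_bulge_factor, spec$r_eca)
  built <- build_phantom_mask(list(cl_cca, cl_ica, cl_eca),
                              list(r_cca_fun, r_ica_fun, r_eca_fun),
                              c(1L, 2L, 3L), spec$spacing, spec$margin,
                              rmax)
  shift <- built$shift
  cl <- lapply(list(cca = cl_cca, ica = cl_ica, eca = cl_eca),
               function(p) sweep(p, 2, shift, "+"))
  bif <- shift

  # two markers per branch: one at the free end, one mid-branch
  mk <- function(pts, branch) {
    n <- nrow(pts)
    data.frame(branch = branch,
               x_mm = pts[c(n, round(n * 0.6)), 1],
               y_mm = pts[c(n, round(n * 0.6)), 2],
               z_mm = pts[c(n, round(n * 0.6)), 3])
  }
  markers <- rbind(mk(cl$cca, "cca"), mk(cl$ica, "ica"), mk(cl$eca, "eca"))

  ica_L <- polyline_length(cl$ica)
  ica_D <- sqrt(sum((cl$ica[nrow(cl$ica), ] - cl$ica[1, ])^2))
  truth <- structure(list(
    centerlines = cl,
    radius = list(cca = data.frame(s_mm = s_cca, r_mm = r_cca_fun(s_cca)),
                  ica = data.frame(s_mm = s_ica, r_mm = r_ica_fun(s_ica)),
                  eca = data.frame(s_mm = s_eca, r_mm = r_eca_fun(s_eca))),
    bifurcation_point = bif,
    markers = markers,
    tortuosity = c(cca = 0, ica = ica_L / ica_D - 1, eca = 0)),
    class = "ground_truth")
  list(mask = built$mask, truth = truth)
}
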