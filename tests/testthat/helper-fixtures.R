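# shared phantom fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# straight 3 mm cylinder, 40 mm long, 0.5 mm isotropic, with its
# distance map and extracted axis curve
cyl3 <- function() fixture("cyl3", function() {
  ph <- make_tube_mask(3, 40, spacing = c(0.5, 0.5, 0.5))
  ph$dmap <- distance_map(ph$mask)
  ends <- ph$truth$markers
  ph$curve <- minimal_cost_path(ph$mask, as.numeric(ends[1, 2:4]),
                                as.numeric(ends[2, 2:4]), ph$dmap)
  ph
})

# default carotid-like bifurcation phantom (4, 2.68, 2.44) mm
default_phantom <- function() fixture("bp_default", function() {
  bp <- make_bifurcation_phantom(phantom_spec(4, 2.68, 2.44))
  bp$dmap <- distance_map(bp$mask)
  bp$bc <- extract_bifurcation(bp$mask, bp$truth$markers, bp$dmap)
  bp
})

# same geometry with a 1.4x carotid-sinus bulge on the proximal ICA
bulge_phantom <- function() fixture("bp_bulge", function() {
  bp <- make_bifurcation_phantom(
    phantom_spec(4, 2.68, 2.44, sinus_bulge_factor = 1.4))
  bp$dmap <- distance_map(bp$mask)
  bp$bc <- extract_bifurcation(bp$mask, bp$truth$markers, bp$dmap)
  bp
})

# straight tube with elliptical cross-section (semi-axes a >= b), built
# directly from the voxel-centre membership rule
make_ellipse_tube <- function(a, b, len, spacing = c(0.5, 0.5, 0.5),
                              margin = 4) {
  cx <- margin + a
  nx <- ceiling((len + 2 * margin) / spacing[1]) + 1
  ny <- ceiling(2 * (a + margin) / spacing[2]) + 1
  nz <- ceiling(2 * (b + margin) / spacing[3]) + 1
  xs <- (seq_len(nx) - 1) * spacing[1]
  ys <- (seq_len(ny) - 1) * spacing[2] - (ny - 1) * spacing[2] / 2
  zs <- (seq_len(nz) - 1) * spacing[3] - (nz - 1) * spacing[3] / 2
  inx <- xs >= margin & xs <= margin + len
  sl <- array(0L, c(ny, nz))
  sl[outer((ys / a)^2, (zs / b)^2, "+") <= 1] <- 1L
  vox <- array(0L, c(nx, ny, nz))
  for (i in which(inx)) vox[i, , ] <- sl
  mask <- labeled_mask(vox, spacing, origin = c(0, ys[1], zs[1]))
  axis_pts <- cbind(seq(margin + 2, margin + len - 2, by = 0.25), 0, 0)
  list(mask = mask, curve = centerline_curve(axis_pts), a = a, b = b)
}
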