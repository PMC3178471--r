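test_that("methods A and B agree on circular cross-sections", {
  ph <- cyl3()
  pa <- radius_method_a(ph$curve, ph$dmap)
  pb <- radius_method_b(ph$curve, ph$mask, dmap = ph$dmap)
  expect_true(all(abs(pa$r_mm - 3) <= 0.5 * max(ph$mask$spacing)))
  expect_lt(max(abs(pb$r_mm - pa$r_mm)), 0.25 * max(ph$mask$spacing))
})

test_that("elliptical lumens separate the two radius methods", {
  et <- make_ellipse_tube(3, 2, 40)
  dm <- distance_map(et$mask)
  pa <- radius_method_a(et$curve, dm)
  pb <- radius_method_b(et$curve, et$mask, dmap = dm)
  # inscribed sphere = minor semi-axis; equivalent radius = sqrt(a*b)
  expect_equal(median(pa$r_mm), 2, tolerance = 0.25 / 2)
  expect_equal(median(pb$r_mm), sqrt(3 * 2), tolerance = 0.1 / sqrt(6))
  expect_true(all(pb$r_mm > pa$r_mm))
})

test_that("radius profile rejects curves outside the mask", {
  ph <- cyl3()
  bad <- centerline_curve(rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5),
                                c(2.5, 0.5, 0.5)))
  expect_error(radius_method_a(bad, ph$dmap), "outside")
  short <- centerline_curve(unclass(ph$curve)[1:3, ])
  expect_error(radius_method_b(short, ph$mask, u = 3), "5 points")
})

test_that("measured triple recovers the construction radii", {
  bp <- default_phantom()
  tri <- measure_triple(bp$bc, bp$dmap, bp$mask, method = "both")
  tol <- 0.5 * max(bp$mask$spacing)
  for (m in c("A", "B")) {
    expect_lt(abs(tri[[m]]$r_cca - 4), tol)
    expect_lt(abs(tri[[m]]$r_ica - 2.68), tol)
    expect_lt(abs(tri[[m]]$r_eca - 2.44), tol)
  }
})

test_that("the ICA window avoids the carotid sinus bulge", {
  bp <- default_phantom()
  bb <- bulge_phantom()
  tri0 <- measure_triple(bp$bc, bp$dmap, method = "A")
  tri1 <- measure_triple(bb$bc, bb$dmap, method = "A")
  # window estimate unaffected by the proximal bulge
  expect_lt(abs(tri1$r_ica - tri0$r_ica), 0.1)
  # but the bulge itself is visible in the proximal profile
  prof <- radius_method_a(bb$bc$ica, bb$dmap)
  u <- median(prof$r_mm)
  proximal <- prof$r_mm[prof$s_mm < 5 * u]
  expect_equal(max(proximal), 1.4 * 2.68, tolerance = 0.3 / 3.75)
})

test_that("branches shorter than their window are refused by name", {
  bp <- default_phantom()
  bc <- bp$bc
  # truncate the ICA curve to ~10 unit radii (window needs 12)
  ica <- unclass(bc$ica)
  s <- bifex:::arc_from_terminus(bc$ica)
  keep <- s <= 10 * 2.68
  bc_short <- structure(list(cca = bc$cca,
                             ica = centerline_curve(ica[keep, ]),
                             eca = bc$eca,
                             bifurcation_point = bc$bifurcation_point),
                        class = "bifurcation_centerlines")
  expect_error(measure_triple(bc_short, bp$dmap, method = "A"),
               "ICA branch too short")
})

test_that("the median window is robust to a localized artifact", {
  bp <- default_phantom()
  tri0 <- measure_triple(bp$bc, bp$dmap, bp$mask, method = "A")

  # graft a localized dilation (width ~2.5 mm < half the 2u-7u window)
  # onto the ECA at ~4 unit radii from the bifurcation
  u <- 2.44
  th <- 25 * pi / 180
  ctr <- bp$truth$bifurcation_point +
    4 * u * c(cos(th), -sin(th), 0)
  dims <- dim(bp$mask$voxels)
  sp <- bp$mask$spacing
  grid <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 1) * sp[1],
                                y = (seq_len(dims[2]) - 1) * sp[2],
                                z = (seq_len(dims[3]) - 1) * sp[3]))
  ball <- sqrt(rowSums(sweep(grid, 2, ctr)^2)) <= 1.3 * u
  vox <- bp$mask$voxels
  vox[array(ball, dims)] <- 3L
  m2 <- labeled_mask(vox, sp, bp$mask$origin)
  dm2 <- distance_map(m2)
  bc2 <- extract_bifurcation(m2, bp$truth$markers, dm2)
  tri1 <- measure_triple(bc2, dm2, m2, method = "A")
  expect_lt(abs(tri1$r_eca - tri0$r_eca) / tri0$r_eca, 0.05)
})

test_that("random phantoms are recovered within half a voxel, both methods", {
  set.seed(2024)
  n_ok <- 0
  for (rep in 1:20) {
    r_cca <- runif(1, 3.2, 4.4)
    r_ica <- r_cca * runif(1, 0.62, 0.74)
    r_eca <- r_cca * runif(1, 0.56, 0.68)
    bulge <- sample(c(1, runif(1, 1.1, 1.35)), 1)
    sp <- phantom_spec(r_cca, r_ica, r_eca,
                       branch_angles = c(ica = runif(1, 23, 32),
                                         eca = runif(1, 23, 32)),
                       sinus_bulge_factor = bulge)
    bp <- make_bifurcation_phantom(sp)
    dm <- distance_map(bp$mask)
    bc <- extract_bifurcation(bp$mask, bp$truth$markers, dm)
    tri <- measure_triple(bc, dm, bp$mask, method = "both")
    tol <- 0.5 * max(bp$mask$spacing)
    for (m in c("A", "B")) {
      expect_lt(abs(tri[[m]]$r_cca - r_cca), tol)
      expect_lt(abs(tri[[m]]$r_ica - r_ica), tol)
      expect_lt(abs(tri[[m]]$r_eca - r_eca), tol)
    }
    # ratio recovery within 5% relative at 0.5 mm isotropic spacing
    expect_lt(abs(tri$A$r_ica / tri$A$r_cca - r_ica / r_cca) /
                (r_ica / r_cca), 0.05)
    expect_lt(abs(tri$A$r_eca / tri$A$r_cca - r_eca / r_cca) /
                (r_eca / r_cca), 0.05)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 20)
})
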