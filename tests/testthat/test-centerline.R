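test_that("distance map reproduces analytic radii", {
  ph <- cyl3()
  expect_equal(max(ph$dmap$values), 3, tolerance = 0.5 / 3)

  # single vessel voxel: nearest background centre is one step away
  arr <- array(0L, c(7, 7, 7)); arr[4, 4, 4] <- 1L
  m1 <- labeled_mask(arr, c(0.5, 0.6, 0.7))
  expect_lte(max(distance_map(m1)$values), min(c(0.5, 0.6, 0.7)) + 1e-12)

  expect_error(distance_map(labeled_mask(array(0L, c(4, 4, 4)),
                                         c(1, 1, 1))), "empty")
})

test_that("anisotropic distance map equals brute force on a sphere", {
  sp <- c(2, 0.5, 0.5)
  dims <- c(13, 41, 41)
  ctr <- (dims - 1) / 2 * sp
  grid <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 1) * sp[1],
                                y = (seq_len(dims[2]) - 1) * sp[2],
                                z = (seq_len(dims[3]) - 1) * sp[3]))
  d2ctr <- sqrt(rowSums(sweep(grid, 2, ctr)^2))
  vox <- array(as.integer(d2ctr <= 4), dims)
  mask <- labeled_mask(vox, sp)
  dm <- distance_map(mask)

  # brute-force oracle: minimum distance from the centre voxel to any
  # background voxel centre
  bg <- grid[vox == 0L, , drop = FALSE]
  oracle <- min(sqrt(rowSums(sweep(bg, 2, ctr)^2)))
  centre_val <- dm$values[(dims[1] + 1) / 2, (dims[2] + 1) / 2,
                          (dims[3] + 1) / 2]
  expect_equal(centre_val, oracle, tolerance = 1e-9)
  expect_lt(abs(centre_val - 4), 1.0)
})

test_that("minimal cost path follows the axis of a straight cylinder", {
  ph <- cyl3()
  cl <- ph$curve
  axis <- ph$truth$centerlines$tube
  # distance from each path point to the analytic axis (a straight line)
  a0 <- axis[1, ]; dir <- axis[nrow(axis), ] - a0
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(unclass(cl), 2, a0)
  perp <- rel - outer(rel %*% dir, dir)[, 1, ]
  expect_lt(max(sqrt(rowSums(perp^2))), sqrt(3) * 0.5)  # 1 voxel diagonal
  expect_lt(attr(cl, "tortuosity"), 0.01)
})

test_that("minimal cost path recovers the arc length of a curved tube", {
  amp <- tube_amplitude_for_tortuosity(40, 0.1)
  ph <- make_tube_mask(3, 40, curvature_amplitude = amp)
  dm <- distance_map(ph$mask)
  ends <- ph$truth$markers
  cl <- minimal_cost_path(ph$mask, as.numeric(ends[1, 2:4]),
                          as.numeric(ends[2, 2:4]), dm)
  L_true <- bifex:::polyline_length(ph$truth$centerlines$tube)
  expect_lt(abs(attr(cl, "L") - L_true) / L_true, 0.02)
})

test_that("path endpoints are validated", {
  ph <- cyl3()
  p <- ph$truth$markers
  a <- as.numeric(p[1, 2:4])
  expect_error(minimal_cost_path(ph$mask, a, a), "degenerate")
  outside <- a + c(0, 20, 0)
  expect_error(minimal_cost_path(ph$mask, a, outside), "endpoint b")
  expect_error(minimal_cost_path(ph$mask, outside, a), "endpoint a")
})

test_that("disconnected components are reported as unreachable", {
  arr <- array(0L, c(20, 10, 10))
  arr[2:6, 4:7, 4:7] <- 1L
  arr[14:18, 4:7, 4:7] <- 1L
  m <- labeled_mask(arr, c(1, 1, 1))
  expect_error(minimal_cost_path(m, c(3, 4, 4), c(15, 4, 4)),
               "not connected")
})

test_that("path cost matches an exhaustive shortest-path oracle", {
  # small random blob mask; oracle = igraph Dijkstra over the full
  # 26-connected voxel graph with identical edge weights
  set.seed(42)
  dims <- c(18, 16, 14)
  sp <- c(1, 0.8, 0.9)
  vox <- array(0L, dims)
  grid <- as.matrix(expand.grid(i = 1:dims[1], j = 1:dims[2],
                                k = 1:dims[3]))
  ctrs <- cbind(runif(5, 4, dims[1] - 3), runif(5, 4, dims[2] - 3),
                runif(5, 4, dims[3] - 3))
  ctrs[, 1] <- sort(ctrs[, 1])   # overlapping chain, keeps it connected
  for (c_i in seq_len(nrow(ctrs))) {
    w <- sweep(grid, 2, ctrs[c_i, ]) %*% diag(sp)
    vox[grid[sqrt(rowSums(w^2)) <= 4.5, , drop = FALSE]] <- 1L
  }
  mask <- labeled_mask(vox, sp)
  dm <- distance_map(mask)

  vessel <- which(vox == 1L)
  a_lin <- vessel[1]
  b_lin <- vessel[length(vessel)]
  ijk <- bifex:::linear_to_ijk(c(a_lin, b_lin), dims)
  a <- (ijk[1, ] - 1) * sp
  b <- (ijk[2, ] - 1) * sp
  cl <- minimal_cost_path(mask, a, b, dm)

  # build the full graph edge list in R
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vij <- bifex:::linear_to_ijk(vessel, dims)
  edges <- NULL
  wts <- NULL
  for (o in seq_len(nrow(offs))) {
    nij <- sweep(vij, 2, offs[o, ], "+")
    ok <- nij[, 1] >= 1 & nij[, 1] <= dims[1] &
          nij[, 2] >= 1 & nij[, 2] <= dims[2] &
          nij[, 3] >= 1 & nij[, 3] <= dims[3]
    from <- vessel[ok]
    to <- nij[ok, 1] + dims[1] * ((nij[ok, 2] - 1) +
                                  dims[2] * (nij[ok, 3] - 1))
    keep <- vox[to] == 1L
    step <- sqrt(sum((offs[o, ] * sp)^2))
    edges <- rbind(edges, cbind(from[keep], to[keep]))
    wts <- c(wts, step / (1 + dm$values[to[keep]]))
  }
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = TRUE)
  oracle <- igraph::distances(g, v = as.character(a_lin),
                              to = as.character(b_lin),
                              weights = wts, mode = "out")[1, 1]
  expect_equal(attr(cl, "cost"), oracle, tolerance = 1e-10)
})

test_that("bifurcation extraction localizes the junction and labels branches", {
  bp <- default_phantom()
  bc <- bp$bc
  err <- sqrt(sum((bc$bifurcation_point - bp$truth$bifurcation_point)^2))
  expect_lt(err, 1.5 * max(bp$mask$spacing))

  # each branch curve should lie predominantly in its labelled branch
  labs <- c(cca = 1L, ica = 2L, eca = 3L)
  for (b in names(labs)) {
    pts <- unclass(bc[[b]])
    idx <- round(sweep(sweep(pts, 2, bp$mask$origin), 2,
                       bp$mask$spacing, "/")) + 1
    v <- bp$mask$voxels[idx]
    expect_gte(mean(v == labs[[b]]), 0.9)
  }
})

test_that("misplaced markers are detected", {
  bp <- default_phantom()
  mk <- bp$truth$markers
  # marker in a disconnected blob
  arr <- bp$mask$voxels
  arr[2:4, 2:4, 2:4] <- 1L
  m2 <- labeled_mask(arr, bp$mask$spacing, bp$mask$origin)
  mk2 <- mk
  mk2[mk2$branch == "ica", c("x_mm", "y_mm", "z_mm")] <-
    matrix(rep(c(1, 1, 1), 2), 2, byrow = TRUE)
  expect_error(extract_bifurcation(m2, mk2), "not connected")
  # marker outside the vessel entirely
  mk3 <- mk
  mk3[1, c("x_mm", "y_mm", "z_mm")] <- c(0.5, 0.5, 0.5)
  expect_error(extract_bifurcation(bp$mask, mk3), "outside")
})

test_that("tortuosity closed forms and invariances hold", {
  straight <- cbind(seq(0, 10, 0.5), 0, 0)
  expect_equal(tortuosity(straight), 0, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 4001)
  semi <- cbind(5 * cos(th), 5 * sin(th), 0)
  expect_equal(tortuosity(semi), pi / 2 - 1, tolerance = 1e-4)

  expect_error(tortuosity(rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0))),
               "coincident")

  set.seed(11)
  for (rep in 1:20) {
    pts <- cbind(sort(runif(15)), runif(15), runif(15))
    t0 <- tortuosity(pts)
    expect_gte(t0, 0)
    # rigid rotation about z plus translation
    ang <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
    moved <- sweep(pts %*% t(R), 2, runif(3, -5, 5), "+")
    expect_equal(tortuosity(moved), t0, tolerance = 1e-10)
    # uniform scaling
    expect_equal(tortuosity(pts * 7.3), t0, tolerance = 1e-10)
  }
})

test_that("tortuosity filtering separates phantoms by construction", {
  # cohorts labelled by ground-truth tortuosity, margin away from 0.1
  torts <- c(0.02, 0.05, 0.15, 0.3)
  records <- data.frame(r_cca_mm = 4, r_ica_mm = 2.68, r_eca_mm = 2.44,
                        ica_tortuosity = torts)
  kept <- filter_low_tortuosity(records)
  expect_equal(nrow(kept), sum(torts < 0.1))
  expect_true(all(kept$ica_tortuosity < 0.1))
})
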