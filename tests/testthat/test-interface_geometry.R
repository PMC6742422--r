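# Bend/twist angle decomposition, superposition, and the per-frame series.

test_that("superposition recovers exact and noisy rigid transforms", {
  set.seed(1)
  X <- matrix(rnorm(600), ncol = 3) * 5

  tr0 <- superpose_core(X, X)
  expect_lt(max(abs(tr0$R - diag(3))), 1e-12)
  expect_lt(max(abs(tr0$t)), 1e-12)
  expect_equal(tr0$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation(); t <- c(4, -7, 2)
  Y <- sweep(X %*% t(R), 2, t, "+")
  tr <- superpose_core(X, Y)
  expect_lt(max(abs(tr$R - R)), 1e-9)
  expect_lt(max(abs(tr$t - t)), 1e-9)

  # noisy correspondence: reported RMSD equals the directly evaluated
  # residual of the fitted transform, and sits near the sqrt(3) sigma
  # noise-theory value
  X <- matrix(rnorm(6000), ncol = 3) * 5
  Y <- sweep(X %*% t(R), 2, t, "+")
  sigma <- 0.5
  Yn <- Y + matrix(rnorm(6000, sd = sigma), ncol = 3)
  trn <- superpose_core(X, Yn)
  res_direct <- sqrt(mean(rowSums((apply_transform(X, trn) - Yn)^2)))
  expect_equal(trn$rmsd, res_direct, tolerance = 1e-12)
  expect_lt(abs(trn$rmsd / (sigma * sqrt(3)) - 1), 0.05)

  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose_core(line, line), "degenerate")
})

test_that("angle decomposition handles identity, pure radial tilt and twist", {
  L <- diag(3)
  a0 <- interface_angles(L, L)
  expect_lt(max(abs(a0)), 1e-12)
  expect_true(attr(a0, "degenerate"))

  # tilting z outward (toward +x) by 15 deg = rotation about the y-axis:
  # strictly radial bending, so phi = 0, delta = 0
  U <- rotation_about(c(0, 1, 0), tubemech:::deg2rad(15)) %*% L
  a <- interface_angles(L, U)
  expect_equal(a[["phi"]], 0, tolerance = 1e-10)
  expect_equal(a[["theta"]], 15, tolerance = 1e-10)
  expect_equal(a[["delta"]], 0, tolerance = 1e-10)

  # pure twist about z: theta 0, delta signed by handedness
  Ut <- rotation_about(c(0, 0, 1), tubemech:::deg2rad(25)) %*% L
  at <- interface_angles(L, Ut)
  expect_equal(at[["theta"]], 0, tolerance = 1e-10)
  expect_equal(at[["delta"]], 25, tolerance = 1e-10)
})

test_that("decomposition agrees with an independent quaternion oracle", {
  set.seed(7)
  for (i in 1:200) {
    M <- random_rotation()
    th <- acos(max(-1, min(1, M[3, 3]))) * 180 / pi
    if (th > 89 || th < 1e-3) next
    a <- interface_angles(diag(3), M)
    o <- swing_twist_oracle(M)
    expect_lt(abs(a[["phi"]] - o[["phi"]]), 1e-9)
    expect_lt(abs(a[["theta"]] - o[["theta"]]), 1e-9)
    expect_lt(abs(a[["delta"]] - o[["delta"]]), 1e-9)
  }
})

test_that("compose/decompose round-trips 1000 random angle triples", {
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    ph <- runif(1, -179.9, 180); th <- runif(1, 1e-3, 89); de <- runif(1, -179.9, 180)
    a <- interface_angles(diag(3), compose_interface_rotation(ph, th, de))
    worst <- max(worst, abs(a[["phi"]] - ph), abs(a[["theta"]] - th),
                 abs(a[["delta"]] - de))
  }
  expect_lt(worst, 1e-8)
})

test_that("theta is invariant under common rotations; delta flips sign", {
  set.seed(13)
  M <- compose_interface_rotation(-48, 9.4, 5.2)
  for (i in 1:20) {
    G <- random_rotation()
    a <- interface_angles(G %*% diag(3), G %*% M)
    expect_equal(a[["theta"]], 9.4, tolerance = 1e-9)
  }
  Mneg <- compose_interface_rotation(-48, 9.4, -5.2)
  an <- interface_angles(diag(3), Mneg)
  expect_equal(an[["delta"]], -5.2, tolerance = 1e-9)
  expect_equal(an[["theta"]], 9.4, tolerance = 1e-9)
})

test_that("monomer triads track prescribed rigid placements", {
  w <- generate_wall_fragment()
  # straight protofilament in lattice register: upper triad == lower triad
  pf0 <- generate_bent_protofilament(data.frame(phi = 0, theta = 0, delta = 0))
  tri0 <- monomer_triads(pf0$structure$xyz, pf0$subunits[[1]],
                         pf0$subunits[[2]], w$lattice, "A", "B")
  expect_lt(max(abs(tri0$upper - tri0$lower)), 1e-6)
  expect_lt(tri0$rmsd_lower, 1e-9)

  # upper subunit rotated rigidly by a known relative rotation
  set.seed(17)
  M <- compose_interface_rotation(33, 12, -7)
  pf <- generate_bent_protofilament(data.frame(phi = 33, theta = 12, delta = -7))
  tri <- monomer_triads(pf$structure$xyz, pf$subunits[[1]], pf$subunits[[2]],
                        w$lattice, "A", "B")
  expect_lt(max(abs(tri$upper - tri$lower %*% M)), 1e-9)
})

test_that("angle series is flat for a rigid interface and empty for no frames", {
  w <- generate_wall_fragment()
  truth <- interface_ground_truth(theta0 = 9.4, phi0 = -48, delta0 = 5.2,
                                  kappa_theta = 1e12, kappa_delta = 1e12)
  tr <- generate_interface_trajectory(truth, 25, seed = 5)
  iface <- list(label = "intra", class = "intra-dimer",
                lower_sel = tr$subunits[[1]], upper_sel = tr$subunits[[2]],
                lower_site = "A", upper_site = "B")
  s <- angle_series(tr$trajectory, iface, w$lattice)
  expect_equal(nrow(s), 25)
  expect_lt(max(abs(s$theta_deg - 9.4)), 1e-3)
  expect_lt(max(abs(s$phi_deg + 48)), 1e-2)
  expect_lt(max(abs(s$delta_deg - 5.2)), 1e-3)

  tr0 <- generate_interface_trajectory(truth, 0, seed = 5)
  s0 <- angle_series(tr0$trajectory, iface, w$lattice)
  expect_equal(nrow(s0), 0)
})

test_that("harmonic angle series has the prescribed mean within 3 SE", {
  w <- generate_wall_fragment()
  truth <- interface_ground_truth(theta0 = 9.4, phi0 = -48, delta0 = 5.2,
                                  kappa_theta = 1000, kappa_delta = 1000)
  tr <- generate_interface_trajectory(truth, 5000, seed = 23)
  iface <- list(label = "intra", class = "intra-dimer",
                lower_sel = tr$subunits[[1]], upper_sel = tr$subunits[[2]],
                lower_site = "A", upper_site = "B")
  s <- angle_series(tr$trajectory, iface, w$lattice)
  se <- sd(s$theta_deg) / sqrt(nrow(s))
  expect_lt(abs(mean(s$theta_deg) - 9.4), 3 * se + 0.02)
})

test_that("unit-vector projection follows the plotted sign convention", {
  # theta = 0 -> origin
  expect_equal(unlist(unit_vector_projection(
    data.frame(phi_deg = 0, theta_deg = 0))), c(tangential = 0, radial = 0))
  # pure outward tilt: radial component negative on the plot (outward =
  # away from the axis)
  p <- unit_vector_projection(data.frame(phi_deg = 0, theta_deg = 10))
  expect_equal(p$tangential, 0, tolerance = 1e-12)
  expect_equal(p$radial, -sin(10 * pi / 180), tolerance = 1e-12)
  # random triads: components equal the direct dot products
  set.seed(3)
  for (i in 1:50) {
    M <- random_rotation()
    a <- suppressWarnings(interface_angles(diag(3), M))
    pr <- unit_vector_projection(data.frame(phi_deg = a[["phi"]],
                                            theta_deg = a[["theta"]]))
    expect_equal(pr$tangential, M[2, 3], tolerance = 1e-9)  # Z . y
    expect_equal(pr$radial, -M[1, 3], tolerance = 1e-9)     # -(Z . x)
  }
})

test_that("center-of-mass projection reports base-frame coordinates", {
  w <- generate_wall_fragment()
  truth <- interface_ground_truth(kappa_theta = 1e10, kappa_delta = 1e10,
                                  theta0 = 0, phi0 = 0, delta0 = 0)
  tr <- generate_interface_trajectory(truth, 6, seed = 2)
  lower <- tr$subunits[[1]]; upper <- tr$subunits[[2]]

  # rigid translation of the upper subunit by (3, 4, 0) in the base frame
  shifted <- tr$trajectory
  cols <- as.vector(rbind(3 * upper$atom_idx - 2, 3 * upper$atom_idx - 1,
                          3 * upper$atom_idx))
  dxy <- rep(c(3, 4, 0), times = length(upper$atom_idx))
  shifted$frames[, cols] <- sweep(shifted$frames[, cols], 2, dxy, "+")
  base <- com_projection(tr$trajectory, upper, lower, w$lattice, "A")
  moved <- com_projection(shifted, upper, lower, w$lattice, "A")
  expect_equal(moved$x - base$x, rep(3, 6), tolerance = 1e-9)
  expect_equal(moved$y - base$y, rep(4, 6), tolerance = 1e-9)

  # the base subunit's own center of mass projects to the origin
  own <- com_projection(tr$trajectory, lower, lower, w$lattice, "A")
  expect_lt(max(abs(own$x)), 1e-9)
  expect_lt(max(abs(own$y)), 1e-9)

  # smoothing window 1 is the identity
  sm1 <- com_projection(tr$trajectory, upper, lower, w$lattice, "A", window = 1L)
  expect_identical(sm1$x, base$x)
})

test_that("deposited-structure angle wrapper pairs cores by residue number", {
  w <- generate_wall_fragment()
  pf <- generate_bent_protofilament(data.frame(phi = -28, theta = 9, delta = 5.9))
  a <- published_structure_angles(pf$structure, w$lattice,
                                  lower_chain = "A", upper_chain = "B",
                                  lower_site = "A", upper_site = "B")
  expect_equal(a[["phi"]], -28, tolerance = 1e-8)
  expect_equal(a[["theta"]], 9, tolerance = 1e-8)
  expect_equal(a[["delta"]], 5.9, tolerance = 1e-8)
  expect_lt(attr(a, "rmsd_lower"), 1e-9)

  # excluding residues shrinks the fitted core but not the rigid answer
  a2 <- published_structure_angles(pf$structure, w$lattice, "A", "B", "A", "B",
                                   exclude_resno = 15:20)
  expect_equal(a2[["theta"]], 9, tolerance = 1e-8)
})
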