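# Elastic networks: construction, Hessian, normal modes, heterogeneous
# parametrization and mode overlaps.

test_that("network construction matches brute-force pair enumeration", {
  two_far <- list(xyz = rbind(c(0, 0, 0), c(9, 0, 0)), mass = c(1, 1))
  expect_warning(n0 <- build_network(two_far, 0.8), "disconnected")
  expect_equal(nrow(n0$springs), 0)

  two_near <- list(xyz = rbind(c(0, 0, 0), c(5, 0, 0)), mass = c(1, 1))
  n1 <- build_network(two_near, 0.8)
  expect_equal(nrow(n1$springs), 1)
  expect_equal(n1$springs$rest_A, 5)

  set.seed(71)
  cloud <- list(xyz = matrix(runif(150, 0, 25), ncol = 3), mass = rep(1, 50))
  net <- suppressWarnings(build_network(cloud, 0.8))
  brute <- 0L
  for (i in 1:49) for (j in (i + 1):50)
    if (sqrt(sum((cloud$xyz[i, ] - cloud$xyz[j, ])^2)) < 8) brute <- brute + 1L
  expect_equal(nrow(net$springs), brute)
  expect_true(all(net$springs$rest_A < 8))
})

test_that("Hessian matches the analytic single-spring block and finite differences", {
  net <- build_network(list(xyz = rbind(c(0, 0, 0), c(4, 3, 0)),
                            mass = c(100, 100)), 0.8, k0 = 2)
  H <- enm_hessian(net, mass_weighted = FALSE)
  e <- c(4, 3, 0) / 5
  blk <- 2 * tcrossprod(e)
  expect_equal(H[1:3, 1:3], blk, tolerance = 1e-12)
  expect_equal(H[1:3, 4:6], -blk, tolerance = 1e-12)

  net10 <- make_helix_network()
  H10 <- enm_hessian(net10, mass_weighted = FALSE)
  expect_equal(H10, t(H10), tolerance = 1e-12)
  # rigid-body displacements cost no energy: translations and rotations
  # are annihilated
  n <- nrow(net10$xyz)
  rig <- cbind(rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n))
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    rot <- as.vector(t(t(apply(sweep(net10$xyz, 2, colMeans(net10$xyz)), 1,
                               function(r) tubemech:::cross3(ax, r)))))
    rig <- cbind(rig, rot)
  }
  expect_lt(max(abs(H10 %*% rig)), 1e-9 * max(abs(H10)))

  # finite-difference oracle on the spring potential energy
  energy <- function(xvec) {
    xm <- matrix(xvec, ncol = 3, byrow = TRUE)
    sum(vapply(seq_len(nrow(net10$springs)), function(r) {
      s <- net10$springs[r, ]
      d <- sqrt(sum((xm[s$i, ] - xm[s$j, ])^2))
      0.5 * s$k * (d - s$rest_A)^2
    }, numeric(1)))
  }
  x0 <- as.vector(t(net10$xyz))
  h <- 1e-4
  idx <- c(1, 5, 14, 22)
  for (a in idx) for (b in idx) {
    ea <- eb <- numeric(length(x0)); ea[a] <- h; eb[b] <- h
    fd <- (energy(x0 + ea + eb) - energy(x0 + ea - eb) -
             energy(x0 - ea + eb) + energy(x0 - ea - eb)) / (4 * h^2)
    # H is in N/m with meter coordinates; energy above is per A^2
    expect_equal(H10[a, b] * 1e-20, fd * 1e-20, tolerance = 1e-5)
  }
})

test_that("normal modes: rigid-mode count and closed-form frequencies", {
  net <- make_helix_network()
  Hm <- enm_hessian(net, mass_weighted = TRUE)
  eg <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(eg < 1e-8 * max(eg)), 6)

  modes <- normal_modes(Hm)
  expect_equal(modes$n_rigid, 6)
  expect_true(all(diff(modes$values) >= -1e-9 * max(modes$values)))

  # two beads, one spring: omega = sqrt(k (1/m1 + 1/m2))
  dal <- 1.66053906660e-27
  net2 <- build_network(list(xyz = rbind(c(0, 0, 0), c(4, 0, 0)),
                             mass = c(100, 300)), 0.8, k0 = 2)
  m2 <- normal_modes(enm_hessian(net2))
  expect_equal(length(m2$omega), 1)
  expect_equal(m2$omega[1], sqrt(2 * (1 / (100 * dal) + 1 / (300 * dal))),
               tolerance = 1e-12)

  # uniform 20-bead chain along a line: longitudinal spectrum matches the
  # analytic free-chain eigenvalues lambda_n = (4k/m) sin^2(n pi / 2N)
  N <- 20; k <- 3; mass <- 200
  line <- list(xyz = cbind(rep(0, N), rep(0, N), 4 * seq_len(N)),
               mass = rep(mass, N))
  netl <- build_network(line, 0.45, k0 = k)  # nearest neighbors only
  Hl <- enm_hessian(netl, mass_weighted = TRUE)
  lam <- sort(eigen(Hl, symmetric = TRUE, only.values = TRUE)$values)
  nonzero <- lam[lam > 1e-8 * max(lam)]
  analytic <- sort((4 * k / (mass * dal)) * sin(seq_len(N - 1) * pi / (2 * N))^2)
  expect_equal(nonzero, analytic, tolerance = 1e-9)
})

test_that("mode overlaps are correlation cosines with unit row norms", {
  net <- make_helix_network()
  modes <- normal_modes(enm_hessian(net))
  expect_equal(mode_overlap(modes, modes), diag(ncol(modes$vectors)),
               tolerance = 1e-10)

  a <- list(vectors = diag(6)[, 1:3])
  b <- list(vectors = diag(6)[, 4:6])
  expect_equal(mode_overlap(a, b), matrix(0, 3, 3))

  # rotating within a 2-subspace preserves completeness: squared overlaps
  # against the full basis sum to 1 per row
  th <- 0.6
  rot <- diag(6)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ov <- mode_overlap(list(vectors = rot), list(vectors = diag(6)))
  expect_equal(rowSums(ov^2), rep(1, 6), tolerance = 1e-10)
})

test_that("Hessian spectrum is invariant under rigid motion and scales with k", {
  net <- make_helix_network()
  lam0 <- normal_modes(enm_hessian(net))$values
  set.seed(73)
  R <- random_rotation()
  net_rot <- net
  net_rot$xyz <- sweep(net$xyz %*% t(R), 2, c(11, -3, 6), "+")
  lam1 <- normal_modes(enm_hessian(net_rot))$values
  expect_equal(lam1, lam0, tolerance = 1e-9)

  net_scaled <- net
  net_scaled$springs$k <- net$springs$k * 3.7
  lam2 <- normal_modes(enm_hessian(net_scaled))$values
  expect_equal(lam2, 3.7 * lam0, tolerance = 1e-12)
})

test_that("heterogeneous parametrization recovers generating constants", {
  net <- make_helix_network(k0 = 10)
  set.seed(11)
  ktrue <- runif(nrow(net$springs), 0.5, 2) * 10
  net$springs$k <- ktrue

  # exact model targets: the fit is a fixed point of the iteration
  vt <- tubemech:::predicted_pair_variance(net, enm_covariance(net, 300))
  fitA <- parametrize_heterogeneous(net, target_var_A2 = vt,
                                    temperature_K = 300, max_iter = 300)
  expect_lt(max(abs(fitA$springs$k / ktrue - 1)), 0.02)
  expect_true(attr(fitA, "converged"))

  # sampled ensemble: recovery within 5%
  ens <- generate_enm_ensemble(net, 300, 20000, seed = 4)
  fitS <- suppressWarnings(
    parametrize_heterogeneous(net, ens$frames, 300, max_iter = 300))
  expect_lt(max(abs(fitS$springs$k / ktrue - 1)), 0.05)

  # uniform and Boltzmann initializations agree at the fixed point
  fitU <- suppressWarnings(
    parametrize_heterogeneous(net, ens$frames, 300, init = "uniform",
                              max_iter = 300))
  expect_lt(max(abs(fitU$springs$k / fitS$springs$k - 1)), 0.01)

  expect_error(parametrize_heterogeneous(net, matrix(0, 5, 12)), "topology")
})

test_that("softer inter-block springs lower the soft-mode stiffness", {
  # two rigid clusters joined by a few springs: softening the joint
  # lowers the first non-rigid frequency, hence any beam stiffness
  set.seed(74)
  blk <- matrix(runif(21, 0, 6), ncol = 3)
  xyz <- rbind(blk, sweep(blk, 2, c(0, 0, 8.5), "+"))
  bm <- list(xyz = xyz, mass = rep(300, nrow(xyz)))
  uni <- suppressWarnings(build_network(bm, 0.9, k0 = 5))
  inter <- uni$springs$i <= 7 & uni$springs$j > 7
  expect_gt(sum(inter), 0)
  soft <- uni
  soft$springs$k[inter] <- 1
  w_uni <- normal_modes(enm_hessian(uni))$omega[1]
  w_soft <- normal_modes(enm_hessian(soft))$omega[1]
  expect_lt(w_soft, w_uni)
  geo <- beam_geometry(1.5e-9)
  expect_lt(beam_stiffness(w_soft, "bend", geo),
            beam_stiffness(w_uni, "bend", geo))
})
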