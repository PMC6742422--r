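# Calpha contact counting, rupture tracking and nucleotide compaction.

mk_two_blobs <- function(nA = 8, nB = 8, sep = 6, jitter = 0) {
  ca <- function(n, base, chain, start_resno) {
    xyz <- cbind(seq_len(n) * 3, 0, 0) + matrix(rep(base, each = n), n)
    if (jitter > 0) xyz <- xyz + matrix(rnorm(3 * n, sd = jitter), n)
    data.frame(elety = "CA", elesy = "C", resno = start_resno + seq_len(n) - 1,
               resid = "ALA", chain = chain, insert = "", occ = 1,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  a <- ca(nA, c(0, 0, 0), "A", 1)
  b <- ca(nB, c(0, sep, 0), "B", 1)
  at <- rbind(a, b); at$eleno <- seq_len(nrow(at))
  s <- structure_model(at[, c("eleno", "elety", "elesy", "resno", "resid",
                              "chain", "insert", "occ")],
                       as.matrix(at[, c("x", "y", "z")]))
  sels <- define_subunits(s, list(
    list(label = "A", chain = "A", role = "alpha", exclude_cterm = 0L),
    list(label = "B", chain = "B", role = "beta", exclude_cterm = 0L)))
  list(structure = s, sels = sels)
}

test_that("contact threshold is strict and selections must be sane", {
  fx <- mk_two_blobs(nA = 1, nB = 1, sep = 7.99)
  expect_equal(contact_count(fx$structure$xyz, fx$structure,
                             fx$sels[[1]], fx$sels[[2]]), 1L)
  fx2 <- mk_two_blobs(nA = 1, nB = 1, sep = 8.01)
  expect_equal(contact_count(fx2$structure$xyz, fx2$structure,
                             fx2$sels[[1]], fx2$sels[[2]]), 0L)
  fx3 <- mk_two_blobs(nA = 1, nB = 1, sep = 8.00)
  expect_equal(contact_count(fx3$structure$xyz, fx3$structure,
                             fx3$sels[[1]], fx3$sels[[2]]), 0L)

  # empty selection counts zero contacts
  empty_sel <- fx$sels[[2]]
  empty_sel$atom_idx <- integer(0)
  expect_equal(contact_count(fx$structure$xyz, fx$structure,
                             fx$sels[[1]], empty_sel), 0L)
  # overlapping selections are refused
  expect_error(contact_count(fx$structure$xyz, fx$structure,
                             fx$sels[[1]], fx$sels[[1]]), "disjoint")
})

test_that("neighbor-list counting equals brute force on random configurations", {
  set.seed(81)
  for (i in 1:1000) {
    nA <- sample(5:30, 1); nB <- sample(5:30, 1)
    span <- runif(1, 10, 40)
    A <- matrix(runif(3 * nA, 0, span), ncol = 3)
    B <- matrix(runif(3 * nB, 0, span), ncol = 3)
    expect_identical(tubemech:::contact_count_cells(A, B, 8),
                     tubemech:::contact_count_brute(A, B, 8))
  }
})

test_that("contact counts are symmetric and rigid-motion invariant", {
  set.seed(82)
  fx <- mk_two_blobs(nA = 20, nB = 20, sep = 5, jitter = 2)
  c_ab <- contact_count(fx$structure$xyz, fx$structure, fx$sels[[1]], fx$sels[[2]])
  c_ba <- contact_count(fx$structure$xyz, fx$structure, fx$sels[[2]], fx$sels[[1]])
  expect_identical(c_ab, c_ba)
  expect_gt(c_ab, 0)

  R <- random_rotation()
  moved <- sweep(fx$structure$xyz %*% t(R), 2, c(100, -50, 20), "+")
  expect_identical(contact_count(moved, fx$structure, fx$sels[[1]], fx$sels[[2]]),
                   c_ab)
})

test_that("contact series tracks splaying and flags rupture", {
  fx <- mk_two_blobs(nA = 6, nB = 6, sep = 5)
  n_fr <- 40
  bcols <- as.vector(rbind(3 * fx$sels[[2]]$atom_idx - 2,
                           3 * fx$sels[[2]]$atom_idx - 1,
                           3 * fx$sels[[2]]$atom_idx))
  base <- as.vector(t(fx$structure$xyz))
  frames <- matrix(rep(base, each = n_fr), n_fr)
  # blocks separate linearly: +0.5 A along y per frame
  sepy <- 0.5 * (seq_len(n_fr) - 1)
  ycols <- bcols[seq(2, length(bcols), 3)]
  frames[, ycols] <- frames[, ycols] + sepy
  trj <- trajectory_ensemble(fx$structure, frames)

  s <- contact_series(trj, fx$sels[[1]], fx$sels[[2]], rupture_dwell = 5)
  expect_true(all(diff(s$count) <= 0))
  # construction: pairs at 5 + 0.5 (t - 1) A; the last pair drops below
  # 8 A when separation reaches 8, i.e. frame index 1 + 3/0.5 = 7
  first_zero <- which(s$count == 0)[1]
  expect_equal(s$time_ns[first_zero], 6, tolerance = 1)
  expect_equal(attr(s, "rupture_time_ns"), s$time_ns[first_zero])

  # frozen structure: constant counts, no rupture
  frozen <- trajectory_ensemble(fx$structure, matrix(rep(base, each = 10), 10))
  sf <- contact_series(frozen, fx$sels[[1]], fx$sels[[2]])
  expect_equal(length(unique(sf$count)), 1L)
  expect_true(is.na(attr(sf, "rupture_time_ns")))

  # stride 2 equals every other element of the stride-1 series
  s2 <- contact_series(trj, fx$sels[[1]], fx$sels[[2]], stride = 2L)
  expect_equal(s2$count, s$count[seq(1, n_fr, 2)])
})

test_that("windowed contact summaries pool runs correctly", {
  const <- function(val, n = 20) {
    d <- data.frame(time_ns = seq_len(n) - 1, count = rep(val, n))
    class(d) <- c("contact_series", "data.frame")
    d
  }
  s42 <- interface_contact_summary(list(const(42)), t_cut_ns = 0)
  expect_equal(s42$mean, 42); expect_equal(s42$sd, 0)

  s4044 <- interface_contact_summary(list(const(40), const(44)), t_cut_ns = 0)
  expect_equal(s4044$mean, 42)

  set.seed(83)
  runs <- lapply(1:3, function(i) {
    d <- data.frame(time_ns = 0:199, count = rpois(200, 30))
    class(d) <- c("contact_series", "data.frame"); d
  })
  sp <- interface_contact_summary(runs, t_cut_ns = 100)
  pooled <- unlist(lapply(runs, function(r) r$count[r$time_ns > 100]))
  expect_equal(sp$mean, mean(pooled))
  expect_equal(sp$sd, sd(pooled))
  expect_equal(sp$n_frames, length(pooled))
})

test_that("compaction distance is the ribose-ring center-of-mass separation", {
  dimer <- make_dimer_structure(offset = c(0, 0, 45))
  sels <- define_subunits(dimer, list(
    list(label = "a", chain = "A", role = "alpha", nucleotide = "GTP"),
    list(label = "b", chain = "B", role = "beta", nucleotide = "GDP")))

  # chain B is chain A's nucleotide cloud translated by 45 A in z, so the
  # ring separation is exactly 45
  d <- compaction_distance(dimer$xyz, dimer, sels[[1]], sels[[2]])
  expect_equal(d, 45, tolerance = 1e-9)

  # direct center-of-mass oracle
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  com <- function(sel) {
    idx <- sel$nuc_idx[dimer$atoms$elety[sel$nuc_idx] %in% ring]
    m <- atom_masses(dimer)[idx]
    colSums(dimer$xyz[idx, ] * m) / sum(m)
  }
  expect_equal(d, sqrt(sum((com(sels[[1]]) - com(sels[[2]]))^2)),
               tolerance = 1e-9)

  # identical ring placed twice -> zero
  expect_equal(compaction_distance(dimer$xyz, dimer, sels[[1]], sels[[1]]), 0)

  # missing ring atoms are named in the error
  broken <- dimer
  drop <- which(broken$atoms$elety == "O4'" & broken$atoms$chain == "B")
  broken <- structure_model(broken$atoms[-drop, ], broken$xyz[-drop, ])
  sels_b <- define_subunits(broken, list(
    list(label = "a", chain = "A", role = "alpha", nucleotide = "GTP"),
    list(label = "b", chain = "B", role = "beta", nucleotide = "GDP")))
  expect_error(compaction_distance(broken$xyz, broken, sels_b[[1]], sels_b[[2]]),
               "O4'")

  # series over a frozen trajectory is constant
  base <- as.vector(t(dimer$xyz))
  trj <- trajectory_ensemble(dimer, matrix(rep(base, each = 4), 4))
  cs <- compaction_series(trj, sels[[1]], sels[[2]])
  expect_equal(cs$distance_A, rep(45, 4), tolerance = 1e-9)
})
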