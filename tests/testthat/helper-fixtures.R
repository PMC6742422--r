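# Shared fixtures and independent oracles used across the suite.

# ---- quaternion swing-twist oracle (independent of the package's
# Rodrigues-based decomposition) --------------------------------------

quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

quat_conj <- function(q) c(q[1], -q[2:4])

# decompose relative rotation M into: swing (minimal rotation z -> Z)
# followed by twist about the tilted axis Z; returns phi/theta/delta in
# degrees with the same conventions as the bend/twist decomposition
swing_twist_oracle <- function(M) {
  z <- c(0, 0, 1)
  Z <- M[, 3]
  ct <- max(-1, min(1, sum(z * Z)))
  theta <- acos(ct)
  phi <- atan2(Z[2], Z[1])
  ax <- c(z[2] * Z[3] - z[3] * Z[2],
          z[3] * Z[1] - z[1] * Z[3],
          z[1] * Z[2] - z[2] * Z[1])
  nax <- sqrt(sum(ax^2))
  q_swing <- if (nax < 1e-14) c(1, 0, 0, 0)
             else c(cos(theta / 2), sin(theta / 2) * ax / nax)
  q_full <- quat_from_matrix(M)
  q_twist <- quat_mult(q_full, quat_conj(q_swing))
  # canonicalize the double cover (w >= 0), then the rotation angle is in
  # [0, pi] and its sign follows the axis projection on Z
  if (q_twist[1] < 0) q_twist <- -q_twist
  ang <- 2 * atan2(sqrt(sum(q_twist[2:4]^2)), q_twist[1])
  sgn <- sum(q_twist[2:4] * Z)
  delta <- ang * if (sgn < 0) -1 else 1
  c(phi = phi * 180 / pi, theta = theta * 180 / pi, delta = delta * 180 / pi)
}

# ---- synthetic nucleotide-bearing dimer ------------------------------

# atom names of a GTP (or GDP when gamma = FALSE) residue, placed on a
# deterministic cloud; includes the ribose ring used for compaction
make_nucleotide_atoms <- function(gamma = TRUE) {
  nm <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4",
          "C1'", "C2'", "C3'", "C4'", "O4'", "O2'", "O3'", "C5'", "O5'",
          "PA", "O1A", "O2A", "O3A", "PB", "O1B", "O2B", "O3B")
  if (gamma) nm <- c(nm, "PG", "O1G", "O2G", "O3G")
  nm
}

# two-chain dimer: each chain has n_res CA pseudo-residues plus a bound
# nucleotide (GTP in chain A with Mg, GDP in chain B); offset shifts the
# B chain along z
make_dimer_structure <- function(n_res = 12, offset = c(0, 0, 40)) {
  mk_chain <- function(chain, nuc, base, gamma, with_mg) {
    i <- seq_len(n_res)
    ca <- cbind(8 * cos(0.7 * i), 8 * sin(0.7 * i), 3 * i)
    atoms_ca <- data.frame(eleno = 0, elety = "CA", elesy = "C", resno = i,
                           resid = "ALA", chain = chain, insert = "", occ = 1,
                           stringsAsFactors = FALSE)
    nm <- make_nucleotide_atoms(gamma)
    k <- seq_along(nm)
    nxyz <- cbind(2 * cos(1.3 * k) + 3, 2 * sin(1.3 * k) - 2, 0.8 * k + 5)
    atoms_nuc <- data.frame(eleno = 0, elety = nm,
                            elesy = tubemech:::guess_element(nm),
                            resno = n_res + 1, resid = nuc, chain = chain,
                            insert = "", occ = 1, stringsAsFactors = FALSE)
    xyz <- rbind(ca, nxyz)
    atoms <- rbind(atoms_ca, atoms_nuc)
    if (with_mg) {
      atoms <- rbind(atoms, data.frame(eleno = 0, elety = "MG", elesy = "MG",
                                       resno = n_res + 2, resid = "MG",
                                       chain = chain, insert = "", occ = 1,
                                       stringsAsFactors = FALSE))
      xyz <- rbind(xyz, c(5, -1, 10))
    }
    xyz <- sweep(xyz, 2, base, "+")
    list(atoms = atoms, xyz = xyz)
  }
  a <- mk_chain("A", "GTP", c(0, 0, 0), gamma = TRUE, with_mg = TRUE)
  b <- mk_chain("B", "GDP", offset, gamma = FALSE, with_mg = FALSE)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms, rbind(a$xyz, b$xyz))
}

# ---- elastic-network fixtures ----------------------------------------

# over-constrained 10-bead helical chain: generically rigid with springs
# up to 4th neighbors at the 0.8 nm cutoff
make_helix_network <- function(n = 10, k0 = 10, cutoff_nm = 0.8,
                               rise = 1.0, astep = 0.7, rad = 2.8,
                               mass = 600) {
  t <- seq_len(n)
  xyz <- cbind(rad * cos(astep * t), rad * sin(astep * t), rise * t)
  build_network(list(xyz = xyz, mass = rep(mass, n)), cutoff_nm, k0)
}

# square-cross-section discretized rod: nring rings of 4 beads
make_rod_network <- function(nring = 30, spacing = 3, halfwidth = 2,
                             k0 = 8, cutoff_nm = 0.75, mass = 500) {
  ring <- rbind(c(halfwidth, halfwidth, 0), c(-halfwidth, halfwidth, 0),
                c(-halfwidth, -halfwidth, 0), c(halfwidth, -halfwidth, 0))
  xyz <- do.call(rbind, lapply(seq_len(nring) - 1, function(r)
    sweep(ring, 2, c(0, 0, r * spacing), "+")))
  build_network(list(xyz = xyz, mass = rep(mass, nrow(xyz))), cutoff_nm, k0)
}

# random proper rotation (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
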