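# Structure-based Hamiltonian: contact map, native stationarity, analytic
# forces vs finite differences, invariances.

fd_check <- function(top, xyz, f_pull = 0, wall_x = -1, wall_k = 0,
                     n_atoms = 20, h = 1e-5, seed = 1) {
  ef <- energy_forces(top, xyz, f_pull, wall_x, wall_k)
  scale <- max(1, max(abs(ef$forces)))
  idx <- with_seed_local(seed, sample(nrow(xyz), min(n_atoms, nrow(xyz))))
  worst <- 0
  for (i in idx) {
    for (c in 1:3) {
      xp <- xyz; xp[i, c] <- xp[i, c] + h
      xm <- xyz; xm[i, c] <- xm[i, c] - h
      fd <- -(energy_forces(top, xp, f_pull, wall_x, wall_k)$energy[["total"]] -
                energy_forces(top, xm, f_pull, wall_x, wall_k)$energy[["total"]]) / (2 * h)
      worst <- max(worst, abs(fd - ef$forces[i, c]) / scale)
    }
  }
  worst
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

test_that("contact map matches a brute-force scan and its contract", {
  s <- dna_hexamer()
  cm <- contact_map(s, cutoff = 4.5, residue_exclusion = 1)
  d <- attr(cm, "distance")
  expect_true(all(d <= 4.5))
  a <- s$atoms
  # no same/adjacent-residue same-chain pairs
  same <- a$chain[cm[, 1]] == a$chain[cm[, 2]]
  expect_true(all(abs(a$resno[cm[same, 1]] - a$resno[cm[same, 2]]) >= 2))
  # brute-force oracle: exhaustive O(N^2) scan with the same exclusions
  xyz <- atom_xyz(s)
  n <- nrow(xyz)
  bonds <- unwindr:::covalent_bonds(s)
  adj <- unwindr:::.adjacency(bonds, n)
  excl <- unwindr:::.bonded_within(adj, 3L)
  exset <- paste(excl[, 1], excl[, 2])
  got <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > 4.5) next
      if (a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) <= 1) next
      if (paste(i, j) %in% exset) next
      got <- c(got, paste(i, j))
    }
  }
  expect_setequal(paste(cm[, 1], cm[, 2]), got)
  # cutoff is respected: shrinking it drops the long contacts
  cm2 <- contact_map(s, cutoff = 3.5)
  expect_true(all(attr(cm2, "distance") <= 3.5))
  expect_lt(nrow(cm2), nrow(cm))
  expect_error(contact_map(s, cutoff = -1), "positive")
})

test_that("native state is a stationary minimum of the topology", {
  top <- dna_topology()
  s <- dna_hexamer()
  xyz <- atom_xyz(s)
  ef <- energy_forces(top, xyz)
  expect_lt(max(abs(ef$forces)), 1e-6)
  # each contact at its minimum: total contact energy = -eps * n_contacts
  expect_equal(ef$energy[["contact"]], -nrow(top$contact_atoms),
               tolerance = 1e-9)
  # perturbations only raise the energy
  e0 <- ef$energy[["total"]]
  with_seed_local(4, {
    for (rep in 1:20) {
      dx <- matrix(rnorm(length(xyz), 0, 0.1 / sqrt(3)), ncol = 3)
      e1 <- energy_forces(top, xyz + dx)$energy[["total"]]
      expect_gt(e1, e0)
    }
  })
})

test_that("analytic forces agree with finite differences", {
  top <- dna_topology()
  s <- dna_hexamer()
  with_seed_local(7, {
    for (rep in 1:3) {
      xyz <- atom_xyz(s) + matrix(rnorm(3 * nrow(atom_xyz(s)), 0, 0.2), ncol = 3)
      expect_lt(fd_check(top, xyz, f_pull = 0.4, wall_x = 30, wall_k = 2,
                         n_atoms = 12, seed = rep), 1e-4)
    }
  })
})

test_that("energy breakdown sums to the total and is frame-invariant", {
  top <- dna_topology()
  xyz <- atom_xyz(dna_hexamer())
  with_seed_local(3, xyz <- xyz + matrix(rnorm(length(xyz), 0, 0.15), ncol = 3))
  e <- energy_forces(top, xyz, 0.3, 40, 1)$energy
  expect_equal(e[["total"]], sum(e[names(e) != "total"]), tolerance = 1e-10)
  # rigid-body invariance of the internal terms
  R <- unwindr:::rot_z(77) %*% unwindr:::rot_x(31)
  x2 <- sweep(t(R %*% t(xyz)), 2, c(-4, 2, 9))
  e2 <- energy_forces(top, x2)$energy
  e1 <- energy_forces(top, xyz)$energy
  expect_lt(abs(e2[["total"]] - e1[["total"]]), 1e-9)
  # net internal force vanishes
  f <- energy_forces(top, xyz)$forces
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("pulling force acts equally and oppositely on the attachment atoms", {
  top <- dna_topology()
  xyz <- atom_xyz(dna_hexamer())
  f0 <- energy_forces(top, xyz, f_pull = 0)$forces
  f1 <- energy_forces(top, xyz, f_pull = 0.7)$forces
  df <- f1 - f0
  pp <- top$pull_pair
  u <- unname(xyz[pp[1], ] - xyz[pp[2], ])
  u <- u / sqrt(sum(u^2))
  expect_equal(unname(df[pp[1], ]), 0.7 * u, tolerance = 1e-9)
  expect_equal(unname(df[pp[2], ]), -0.7 * u, tolerance = 1e-9)
  others <- setdiff(seq_len(nrow(xyz)), pp)
  expect_lt(max(abs(df[others, ])), 1e-12)
  expect_lt(max(abs(colSums(f1))), 1e-9)
})

test_that("bond energy follows the harmonic convention k (r - r0)^2", {
  top <- toy_topology(2, bond = c(1, 2), k_bond = 50, r0 = 1.5)
  for (delta in c(-0.2, 0.1, 0.35)) {
    xyz <- rbind(c(0, 0, 0), c(1.5 + delta, 0, 0))
    e <- energy_forces(top, xyz)$energy
    expect_equal(e[["bond"]], 50 * delta^2, tolerance = 1e-12)
  }
})

test_that("removing inter-strand contacts leaves intra-strand minima intact", {
  top <- dna_topology()
  s <- dna_hexamer()
  a <- s$atoms
  cross <- a$chain[top$contact_atoms[, 1]] != a$chain[top$contact_atoms[, 2]]
  top2 <- top
  top2$contact_atoms <- top$contact_atoms[!cross, , drop = FALSE]
  top2$contact_params <- top$contact_params[!cross, , drop = FALSE]
  ef <- energy_forces(top2, atom_xyz(s))
  expect_lt(max(abs(ef$forces)), 1e-6)
})

test_that("topology JSON round-trips", {
  top <- dna_topology()
  f <- withr::local_tempfile(fileext = ".json")
  write_topology_json(top, f)
  top2 <- read_topology_json(f)
  expect_equal(unname(top2$bond_atoms), unname(top$bond_atoms))
  expect_equal(unname(top2$contact_params), unname(top$contact_params),
               tolerance = 1e-12)
  e1 <- energy_forces(top, top$native_xyz)$energy[["total"]]
  e2 <- energy_forces(top2, top2$native_xyz)$energy[["total"]]
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  top <- dna_topology()
  expect_error(energy_forces(top, matrix(0, 3, 3)), "match")
  xyz <- atom_xyz(dna_hexamer())
  xyz[1, ] <- NA
  expect_error(energy_forces(top, xyz), "finite")
})
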