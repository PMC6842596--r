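# Structure-based (Go-type) Hamiltonian: topology construction and energy
# evaluation.  The native structure defines every equilibrium value: bond
# lengths, angles and dihedral phases are read off the native geometry and
# each native contact's Lennard-Jones minimum sits at its native distance,
# so the native state is an exact stationary minimum of the potential.

# Covalent connectivity (atom-name pairs) within one residue.
.BACKBONE_BONDS <- list(
  c("P", "O5'"), c("O5'", "C5'"), c("C5'", "C4'"), c("C4'", "C3'"),
  c("C3'", "O3'"), c("C4'", "O4'"), c("O4'", "C1'"), c("C1'", "C2'"),
  c("C2'", "C3'")
)

.BASE_BONDS <- list(
  purine = list(
    c("N1", "C6"), c("C6", "C5"), c("C5", "C4"), c("C4", "N3"),
    c("N3", "C2"), c("C2", "N1"), c("C4", "N9"), c("N9", "C8"),
    c("C8", "N7"), c("N7", "C5"), c("C1'", "N9")
  ),
  pyrimidine = list(
    c("N1", "C2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
    c("C5", "C6"), c("C6", "N1"), c("C1'", "N1")
  )
)

.EXO_BONDS <- list(
  A = list(c("C6", "N6")),
  G = list(c("C6", "O6"), c("C2", "N2")),
  C = list(c("C2", "O2"), c("C4", "N4")),
  U = list(c("C2", "O2"), c("C4", "O4")),
  T = list(c("C2", "O2"), c("C4", "O4"), c("C5", "C7"))
)

#' Default force-field parameters
#'
#' Reduced units: the contact well depth `eps_contact` defines the energy
#' unit, lengths are in Angstrom and all masses are 1.  Relative stiffnesses
#' follow common all-atom structure-based-model practice
#' (bond >> angle >> dihedral ~ contact).
#'
#' @return A list of parameters consumed by [build_topology()].
#' @export
ff_parameters <- function() {
  list(
    k_bond = 100,        # energy / A^2
    k_angle = 20,        # energy / rad^2
    k_dihedral = 0.5,    # energy
    eps_contact = 1,     # defines the energy unit
    eps_ex = 1,
    r_ex = 2.5,          # A, excluded-volume radius
    contact_cutoff = 4.5,    # A, heavy-atom contact distance
    residue_exclusion = 1    # minimum intervening residues for a contact
  )
}

residue_bond_names <- function(code, has_p, nucleic_type) {
  b <- .BACKBONE_BONDS
  if (!has_p) b <- b[-1]
  if (nucleic_type == "RNA") b <- c(b, list(c("C2'", "O2'")))
  cls <- if (code %in% PURINES) "purine" else "pyrimidine"
  c(b, .BASE_BONDS[[cls]], .EXO_BONDS[[code]])
}

# All covalent bonds of a structure, as a 2-column matrix of atom indices.
covalent_bonds <- function(structure) {
  a <- structure$atoms
  out <- list()
  for (ch in c("A", "B")) {
    resnos <- sort(unique(a$resno[a$chain == ch]))
    for (r in resnos) {
      code <- a$code[a$chain == ch & a$resno == r][1]
      nm <- residue_bond_names(code, has_p = r != 1L, structure$nucleic_type)
      for (bd in nm) {
        out[[length(out) + 1L]] <- c(
          atom_index(structure, ch, r, bd[1]),
          atom_index(structure, ch, r, bd[2])
        )
      }
      if (r != resnos[length(resnos)]) {
        out[[length(out) + 1L]] <- c(
          atom_index(structure, ch, r, "O3'"),
          atom_index(structure, ch, r + 1L, "P")
        )
      }
    }
  }
  do.call(rbind, out)
}

# Adjacency list from a bond matrix.
.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (t in seq_len(nrow(bonds))) {
    i <- bonds[t, 1]; j <- bonds[t, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, unique)
}

# Pairs of atoms within `depth` bonds of each other (i < j).
.bonded_within <- function(adj, depth) {
  n <- length(adj)
  pairs <- list()
  for (i in seq_len(n)) {
    frontier <- i
    seen <- i
    for (d in seq_len(depth)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, frontier)
    }
    js <- seen[seen > i]
    if (length(js)) pairs[[length(pairs) + 1L]] <- cbind(i, js)
  }
  do.call(rbind, pairs)
}

#' Native contact map by distance cutoff
#'
#' Heavy-atom pairs within `cutoff` in the native structure, excluding pairs
#' connected by three or fewer covalent bonds and same-chain pairs with
#' fewer than `residue_exclusion` intervening residues.  (A distance-cutoff
#' map; shadowing-type occlusion criteria are not applied.)
#'
#' @param structure A `native_structure`.
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param residue_exclusion Minimum number of intervening residues for a
#'   same-chain contact (1 means residues i and i+1 cannot form contacts).
#' @return Two-column matrix of atom-index pairs (i < j), with attribute
#'   `distance` holding the native distances.
#' @export
contact_map <- function(structure, cutoff = 4.5, residue_exclusion = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- atom_xyz(structure)
  a <- structure$atoms
  n <- nrow(xyz)
  bonds <- covalent_bonds(structure)
  adj <- .adjacency(bonds, n)
  excl <- .bonded_within(adj, 3L)
  excl_key <- excl[, 1] * (n + 1) + excl[, 2]

  d2 <- as.matrix(stats::dist(xyz))^2
  cand <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    m0 <- matrix(integer(0), 0, 2)
    attr(m0, "distance") <- numeric(0)
    return(m0)
  }
  i <- cand[, 1]; j <- cand[, 2]
  same_chain <- a$chain[i] == a$chain[j]
  near_res <- abs(a$resno[i] - a$resno[j]) <= residue_exclusion
  keep <- !(same_chain & near_res) & !((i * (n + 1) + j) %in% excl_key)
  i <- i[keep]; j <- j[keep]
  m <- cbind(i, j)
  colnames(m) <- NULL
  attr(m, "distance") <- sqrt(d2[cbind(i, j)])
  m
}

.angle_val <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  cs <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cs)))
}

.dihedral_val <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * n2[3] - n1[3] * n2[2],
    n1[3] * n2[1] - n1[1] * n2[3],
    n1[1] * n2[2] - n1[2] * n2[1]
  )
  atan2(sum(m1 * b2) / vec_norm(b2), sum(n1 * n2))
}

#' Build the structure-based topology
#'
#' Harmonic bonds and angles, periodicity-1+3 cosine dihedrals and 12-6
#' native contacts, all with equilibrium values taken from the native
#' geometry; a purely repulsive excluded-volume term (zero beyond `r_ex`)
#' acts on every remaining nonbonded pair.  The pulling pair is the 5'
#' hydroxyl oxygen of chain A residue 1 and the 3' hydroxyl oxygen of chain
#' B's last residue (the terminal base pair at the pulled end).
#'
#' @param structure A `native_structure`.
#' @param ff Force-field parameters, see [ff_parameters()].
#' @param check If `TRUE`, verify that the native state is a stationary
#'   point (max |force component| <= 1e-6).
#' @return An object of class `sbm_topology`.
#' @export
build_topology <- function(structure, ff = ff_parameters(), check = TRUE) {
  as_int <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  }
  xyz <- atom_xyz(structure)
  n <- nrow(xyz)
  bonds <- covalent_bonds(structure)
  adj <- .adjacency(bonds, n)
  comp_sizes <- table(.components(adj))
  a <- structure$atoms
  expected <- as.vector(table(a$chain))
  if (!setequal(as.vector(comp_sizes), expected) || length(comp_sizes) != 2L) {
    stop("covalent graph is not two connected strands")
  }

  bond_r0 <- sqrt(rowSums((xyz[bonds[, 1], ] - xyz[bonds[, 2], ])^2))

  # angles: all bonded triplets j as vertex
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      ang[[length(ang) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  angles <- do.call(rbind, ang)
  th0 <- vapply(
    seq_len(nrow(angles)),
    function(t) .angle_val(xyz, angles[t, 1], angles[t, 2], angles[t, 3]),
    numeric(1)
  )
  if (any(th0 < 0.15 | th0 > pi - 0.15)) {
    w <- which(th0 < 0.15 | th0 > pi - 0.15)[1]
    stop(sprintf(
      "near-collinear native angle (%.1f deg) at atoms %d-%d-%d",
      th0[w] * 180 / pi, angles[w, 1], angles[w, 2], angles[w, 3]
    ))
  }

  # dihedrals: one torsion per central bond (lowest-index flanking atoms,
  # deterministic), the usual structure-based-model convention
  dih <- list()
  for (t in seq_len(nrow(bonds))) {
    j <- bonds[t, 1]; k <- bonds[t, 2]
    is <- setdiff(adj[[j]], k)
    ls <- setdiff(adj[[k]], j)
    for (i in sort(is)) {
      lok <- sort(setdiff(ls, i))
      if (length(lok)) {
        dih[[length(dih) + 1L]] <- c(i, j, k, lok[1])
        break
      }
    }
  }
  dihedrals <- do.call(rbind, dih)
  phi0 <- vapply(
    seq_len(nrow(dihedrals)),
    function(t) .dihedral_val(xyz, dihedrals[t, 1], dihedrals[t, 2],
                              dihedrals[t, 3], dihedrals[t, 4]),
    numeric(1)
  )

  contacts <- contact_map(structure, ff$contact_cutoff, ff$residue_exclusion)
  sig <- attr(contacts, "distance")

  excl14 <- .bonded_within(adj, 3L)
  excluded_pairs <- rbind(excl14, unclass(contacts)[, , drop = FALSE])

  n_bp <- n_pairs(structure)
  wc <- as_int(t(vapply(seq_len(n_bp),
                        function(p) wc_atoms_of_pair(structure, p),
                        integer(2))))
  groups <- c(
    lapply(seq_len(n_bp), function(r) base_atom_indices(structure, "A", r)),
    lapply(seq_len(n_bp), function(r) base_atom_indices(structure, "B", r))
  )

  bonds <- as_int(bonds); angles <- as_int(angles)
  dihedrals <- as_int(dihedrals)
  contacts_m <- as_int(unclass(contacts)[, , drop = FALSE])
  attr(contacts_m, "distance") <- NULL
  excluded_pairs <- as_int(excluded_pairs)

  topo <- list(
    n_atoms = n,
    masses = rep(1, n),
    bond_atoms = bonds,
    bond_params = cbind(bond_r0, rep(ff$k_bond, nrow(bonds))),
    angle_atoms = angles,
    angle_params = cbind(th0, rep(ff$k_angle, nrow(angles))),
    dihedral_atoms = dihedrals,
    dihedral_params = cbind(phi0, rep(ff$k_dihedral, nrow(dihedrals))),
    contact_atoms = contacts_m,
    contact_params = cbind(sig, rep(ff$eps_contact, nrow(contacts))),
    excluded_pairs = excluded_pairs,
    r_ex = ff$r_ex,
    eps_ex = ff$eps_ex,
    pull_pair = pulling_pair(structure),
    wc_pairs = wc,
    base_groups = groups,
    n_bp = n_bp,
    seq1 = structure$seq1,
    seq2 = structure$seq2,
    nucleic_type = structure$nucleic_type,
    form = structure$form,
    ff = ff,
    native_xyz = xyz
  )
  class(topo) <- "sbm_topology"
  if (check) {
    ef <- energy_forces(topo, xyz)
    mf <- max(abs(ef$forces))
    if (mf > 1e-6) {
      stop(sprintf("native state is not stationary (max |force| = %g)", mf))
    }
  }
  topo
}

.components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf(
    "<sbm_topology> %d atoms | %d bonds, %d angles, %d dihedrals, %d contacts\n",
    x$n_atoms, nrow(x$bond_atoms), nrow(x$angle_atoms),
    nrow(x$dihedral_atoms), nrow(x$contact_atoms)
  ))
  invisible(x)
}

#' Potential energy and forces
#'
#' Evaluates the structure-based Hamiltonian (plus the optional constant
#' pulling force and confining wall on the end-to-end distance) at arbitrary
#' coordinates.
#'
#' @param topology An `sbm_topology`.
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom).
#' @param f_pull Constant pulling force in reduced units (energy/Angstrom),
#'   applied along the line joining the two attachment atoms, equal and
#'   opposite, favouring extension.
#' @param wall_x,wall_k Half-harmonic confining wall on the end-to-end
#'   distance (disabled when `wall_k = 0`).
#' @return List with `energy` (named breakdown: bond, angle, dihedral,
#'   contact, excluded, pulling, wall, total) and `forces` (n x 3 matrix).
#' @export
energy_forces <- function(topology, xyz, f_pull = 0, wall_x = -1, wall_k = 0) {
  stopifnot(inherits(topology, "sbm_topology"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != topology$n_atoms || ncol(xyz) != 3) {
    stop("coordinate matrix does not match topology")
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  res <- cpp_energy_forces(topology, xyz, f_pull, wall_x, wall_k)
  res$energy <- unlist(res$energy)
  res
}

#' Serialize a topology to JSON
#'
#' @param topology An `sbm_topology`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_topology_json <- function(topology, file) {
  x <- unclass(topology)
  x$base_groups <- lapply(x$base_groups, as.integer)
  jsonlite::write_json(x, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a topology from JSON
#'
#' @param file Path written by [write_topology_json()].
#' @return An `sbm_topology`.
#' @export
read_topology_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("bond_atoms", "angle_atoms", "dihedral_atoms", "contact_atoms",
               "excluded_pairs", "wc_pairs")) {
    x[[nm]] <- matrix(as.integer(x[[nm]]), ncol = ncol(as.matrix(x[[nm]])))
  }
  for (nm in c("bond_params", "angle_params", "dihedral_params",
               "contact_params", "native_xyz")) {
    x[[nm]] <- as.matrix(x[[nm]])
  }
  x$base_groups <- lapply(x$base_groups, as.integer)
  class(x) <- "sbm_topology"
  x
}
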