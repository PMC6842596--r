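# Idealized A-form / B-form duplex construction from sequence.
#
# The builder produces an all-heavy-atom native state for a structure-based
# model.  Base rings are regular polygons in the base-pair plane and the
# sugar-phosphate backbone follows the helical path on a cylinder; bonded
# native values are taken from this geometry, so chemical-accuracy bond
# lengths are not required -- only the duplex-level invariants are
# (Watson-Crick donor/acceptor separation, configured rise/twist, and the
# A-vs-B difference in how far terminal bases sit from the helix axis).

NUC_ALPHABET <- list(DNA = c("A", "C", "G", "T"), RNA = c("A", "C", "G", "U"))

WC_COMP <- list(
  DNA = c(A = "T", C = "G", G = "C", T = "A"),
  RNA = c(A = "U", C = "G", G = "C", U = "A")
)

PURINES <- c("A", "G")

# Geometry constants (Angstrom)
.RING6_BOND <- 1.39     # aromatic six-ring bond length
.RING5_BOND <- 1.40     # five-ring bond length
.GLYCO_BOND <- 1.47     # glycosidic C1'-N bond
.EXO_BOND <- 1.40       # exocyclic substituent bond
.WC_DIST <- 2.90        # purine N1 -- pyrimidine N3 donor/acceptor distance

#' Reverse complement of a nucleotide sequence
#'
#' @param sequence A 5'->3' nucleotide string.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return The Watson-Crick complement, read 5'->3'.
#' @examples
#' reverse_complement("AAAAAA", "DNA")
#' reverse_complement("GCGCGC", "RNA")
#' @export
reverse_complement <- function(sequence, nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  bases <- validate_sequence(sequence, nucleic_type)
  paste(rev(unname(WC_COMP[[nucleic_type]][bases])), collapse = "")
}

validate_sequence <- function(sequence, nucleic_type) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be nonempty")
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(bases), NUC_ALPHABET[[nucleic_type]])
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid %s base(s): %s", nucleic_type, paste(bad, collapse = ", ")
    ))
  }
  bases
}

#' Canonical helix parameters
#'
#' Standard fiber-diffraction values: A-form twist 32.7 deg, rise 2.81 A;
#' B-form twist 36.0 deg, rise 3.38 A.  `displacement` shifts the base pair
#' in-plane away from the helix axis (the A-form feature that leaves 5'
#' terminal bases less buried); `inclination` tilts the base-pair plane
#' about its long axis.
#'
#' @param form `"A"` or `"B"`.
#' @return A list with fields `form`, `twist` (deg/step), `rise` (A/step),
#'   `displacement` (A), `inclination` (deg).
#' @export
helix_parameters <- function(form = c("A", "B")) {
  form <- match.arg(form)
  p <- switch(form,
    A = list(form = "A", twist = 32.7, rise = 2.81,
             displacement = -2.5, inclination = 8),
    B = list(form = "B", twist = 36.0, rise = 3.38,
             displacement = 0.0, inclination = 0)
  )
  class(p) <- "helix_parameters"
  p
}

validate_helix_parameters <- function(p) {
  stopifnot(p$twist > 0, p$twist <= 60, p$rise > 2, p$rise < 4)
  invisible(p)
}

# Regular-polygon coordinates: n x 2 matrix, vertex k at angle theta0 + (k-1)*step.
.polygon_xy <- function(center, radius, angles_deg) {
  th <- angles_deg * pi / 180
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Base templates in the strand-I pair frame: the Watson-Crick donor/acceptor
# atom (purine N1 or pyrimidine N3) sits at (-WC_DIST/2, 0, 0) and the ring
# extends toward -x (the strand-I side).  Templates include C1' so the
# glycosidic direction is defined; all other sugar/phosphate atoms are
# placed by the backbone scaffold.
base_template <- function(code, nucleic_type) {
  hex_c <- c(-(.WC_DIST / 2 + .RING6_BOND), 0)
  is_pu <- code %in% PURINES
  if (is_pu) {
    ring_names <- c("N1", "C6", "C5", "C4", "N3", "C2")
    xy <- .polygon_xy(hex_c, .RING6_BOND, seq(0, 300, by = 60))
    # pentagon fused on the C4-C5 edge, pointing away from the hexagon center
    c4 <- xy[4, ]; c5 <- xy[3, ]
    mid <- (c4 + c5) / 2
    out <- (mid - hex_c) / vec_norm(mid - hex_c)
    r5 <- .RING5_BOND / (2 * sin(pi / 5))
    p5c <- mid + (r5 * cos(pi / 5)) * out
    th_c4 <- atan2(c4[2] - p5c[2], c4[1] - p5c[1])
    th_c5 <- atan2(c5[2] - p5c[2], c5[1] - p5c[1])
    # step direction that walks C4 -> N9 -> C8 -> N7 -> C5
    dd <- ((th_c5 - th_c4) %% (2 * pi))
    stp <- if (dd < pi) -2 * pi / 5 else 2 * pi / 5
    th <- th_c4 + stp * (1:3)
    penta <- cbind(p5c[1] + r5 * cos(th), p5c[2] + r5 * sin(th))
    rownames(penta) <- c("N9", "C8", "N7")
    glyco <- "N9"
    c1p <- penta["N9", ] + .GLYCO_BOND * (penta["N9", ] - p5c) / r5
    exo <- switch(code,
      A = rbind(N6 = hex_c + (.RING6_BOND + .EXO_BOND) * c(cos(pi / 3), sin(pi / 3))),
      G = rbind(
        O6 = hex_c + (.RING6_BOND + .EXO_BOND) * c(cos(pi / 3), sin(pi / 3)),
        N2 = hex_c + (.RING6_BOND + .EXO_BOND) * c(cos(5 * pi / 3), sin(5 * pi / 3))
      )
    )
    ring_xy <- rbind(xy, penta)
    rownames(ring_xy) <- c(ring_names, rownames(penta))
    wc_atom <- "N1"
  } else {
    ring_names <- c("N3", "C2", "N1", "C6", "C5", "C4")
    xy <- .polygon_xy(hex_c, .RING6_BOND, seq(0, 300, by = 60))
    rownames(xy) <- ring_names
    glyco <- "N1"
    c1p <- hex_c + (.RING6_BOND + .GLYCO_BOND) * c(cos(2 * pi / 3), sin(2 * pi / 3))
    rad <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
    exo_at <- function(deg) hex_c + (.RING6_BOND + .EXO_BOND) * rad(deg)
    exo <- switch(code,
      C = rbind(O2 = exo_at(60), N4 = exo_at(300)),
      U = rbind(O2 = exo_at(60), O4 = exo_at(300)),
      T = rbind(O2 = exo_at(60), O4 = exo_at(300), C7 = exo_at(240))
    )
    ring_xy <- xy
    wc_atom <- "N3"
  }
  xy_all <- rbind(ring_xy, exo, `C1'` = c1p)
  atoms <- data.frame(
    name = rownames(xy_all),
    x = xy_all[, 1], y = xy_all[, 2], z = 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    code = code,
    atoms = atoms,
    wc_atom = wc_atom,
    glyco_atom = glyco,
    ring_atoms = rownames(ring_xy),
    base_atoms = setdiff(rownames(xy_all), "C1'")
  )
}

# Backbone scaffold in the strand-I pair frame.  Atoms follow the helical
# path; `frac` is the fraction of one base-pair step (twist, rise) advanced
# along the chain, anchored so that C4' lies exactly at (−R, 0, 0): the
# midpoint of the two strands' C4' atoms then sits exactly on the helix
# axis, which is what the base-pair centroid invariant checks.
.BACKBONE_FRAC <- c(P = 0.00, `O5'` = 0.14, `C5'` = 0.30, `C4'` = 0.45,
                    `C3'` = 0.70, `O3'` = 0.85)
# Radii alternate so that consecutive backbone atoms zigzag about the mean
# backbone cylinder instead of tracing a near-straight helical arc (bonded
# angle terms need well-defined, non-collinear native angles).
.BACKBONE_RAD <- c(P = 9.6, `O5'` = 10.0, `C5'` = 9.5, `C4'` = 8.6,
                   `C3'` = 9.5, `O3'` = 8.8)

backbone_template <- function(params) {
  fr <- .BACKBONE_FRAC
  al <- pi + (fr - fr[["C4'"]]) * params$twist * pi / 180
  z <- (fr - fr[["C4'"]]) * params$rise
  r <- .BACKBONE_RAD
  data.frame(
    name = names(fr),
    x = r * cos(al), y = r * sin(al), z = z,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Dyad operation mapping strand-I template coordinates into the antiparallel
# strand-II position: rotation by pi about the in-plane y axis.
.dyad <- function(xyz) {
  xyz[, 1] <- -xyz[, 1]
  xyz[, 3] <- -xyz[, 3]
  xyz
}

# chain-B O2' placement (e3, z, radial components), tuned clash-free
.O2P_B_PAR <- c(-1.4, -0.3, 0.9)

element_of <- function(name) substr(gsub("[^A-Za-z].*$", "", name), 1, 1)

#' Build an idealized duplex native structure from sequence
#'
#' Constructs a two-chain all-heavy-atom duplex: chain A is `sequence`
#' (5'->3') and chain B its reverse complement.  Chain A's 5' terminus is the
#' end that carries the pulling attachment (its terminal 5'-hydroxyl oxygen,
#' together with the 3'-hydroxyl oxygen of chain B's last residue, defines
#' the end-to-end pulling pair).  Residue 1 of each chain lacks the phosphate
#' (5'-OH terminus).  Deterministic; no randomness.
#'
#' @param sequence Chain A sequence, 5'->3'.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param form Helix form, `"A"` or `"B"`; defaults to A for RNA, B for DNA.
#' @param params Helix parameters, see [helix_parameters()].
#' @return An object of class `native_structure`: list with `atoms`
#'   (data.frame: name, element, resno, chain, resid, code, x, y, z),
#'   `seq1`, `seq2`, `nucleic_type`, `form`, `params`.
#' @examples
#' s <- build_duplex("GCGCGC", "RNA")
#' nrow(wc_pair_distances(s))
#' @export
build_duplex <- function(sequence, nucleic_type = c("DNA", "RNA"),
                         form = NULL, params = NULL) {
  nucleic_type <- match.arg(nucleic_type)
  bases <- validate_sequence(sequence, nucleic_type)
  n <- length(bases)
  if (n < 2L) stop("sequence must have length >= 2")
  if (is.null(form)) form <- if (nucleic_type == "RNA") "A" else "B"
  if (is.null(params)) params <- helix_parameters(form)
  validate_helix_parameters(params)
  comp <- WC_COMP[[nucleic_type]]
  seq2 <- reverse_complement(sequence, nucleic_type)

  bb <- backbone_template(params)
  bb_xyz <- as.matrix(bb[, c("x", "y", "z")])
  rownames(bb_xyz) <- bb$name
  Rincl <- rot_x(params$inclination)
  disp <- c(0, params$displacement, 0)

  res_list <- vector("list", 2L * n)
  for (p in seq_len(n)) {
    Rg <- rot_z((p - 1) * params$twist)
    shift <- c(0, 0, (p - 1) * params$rise)
    t1 <- base_template(bases[p], nucleic_type)
    t2 <- base_template(comp[[bases[p]]], nucleic_type)
    b1 <- as.matrix(t1$atoms[, c("x", "y", "z")])
    rownames(b1) <- t1$atoms$name
    b2 <- .dyad(as.matrix(t2$atoms[, c("x", "y", "z")]))
    rownames(b2) <- t2$atoms$name
    # in-plane displacement + inclination of the assembled pair (bases + C1')
    pose <- function(m) sweep(rot_apply(Rincl, m), 2, -disp)
    b1 <- pose(b1); b2 <- pose(b2)
    place <- function(m) sweep(rot_apply(Rg, m), 2, -shift)

    mk_res <- function(base_m, tmpl, bb_m, chain, resno) {
      # bridge sugar atoms from placed C1'/C4'/C3', offset out of the local
      # sugar plane so bonded angles stay well-defined for any base/form
      c1p <- base_m["C1'", ]
      c4p <- bb_m["C4'", ]; c3p <- bb_m["C3'", ]
      e1 <- (c1p - c4p) / vec_norm(c1p - c4p)
      aux <- c3p - c4p
      e2 <- aux - sum(aux * e1) * e1
      e2 <- e2 / vec_norm(e2)
      e3 <- c(
        e1[2] * e2[3] - e1[3] * e2[2],
        e1[3] * e2[1] - e1[1] * e2[3],
        e1[1] * e2[2] - e1[2] * e2[1]
      )
      # The B-form construction is exactly covariant under the base-pair
      # dyad, so both chains use the same rule.  Inclination breaks that
      # covariance (rot_x does not commute with the dyad): in inclined
      # (A-form) helices chain B descends the shared pair frame and its
      # sugar-pucker normal must flip to keep O4'/C2' clear of the
      # neighbouring base.
      incl_b <- chain == "B" && params$inclination != 0
      if (incl_b) e3 <- -e3
      o4p <- c4p + 0.55 * (c1p - c4p) + 0.9 * e3
      if (incl_b) o4p <- o4p + c(0, 0, 0.6)
      c2p <- c3p + 0.52 * (c1p - c3p) - 1.15 * e3
      sug <- rbind(`O4'` = o4p, `C2'` = c2p)
      if (nucleic_type == "RNA") {
        if (!incl_b) {
          o2p <- c2p - 1.4 * e3
        } else {
          pb <- .O2P_B_PAR
          rhat <- c(c2p[1], c2p[2], 0) / vec_norm(c(c2p[1], c2p[2], 0))
          o2p <- c2p + pb[1] * e3 + c(0, 0, pb[2]) + pb[3] * rhat
        }
        sug <- rbind(sug, `O2'` = o2p)
      }
      m <- rbind(bb_m, sug, base_m)
      first <- resno == 1L
      if (first) m <- m[setdiff(rownames(m), "P"), , drop = FALSE]
      m <- place(m)
      data.frame(
        name = rownames(m), element = element_of(rownames(m)),
        resno = resno, chain = chain, code = tmpl$code,
        x = m[, 1], y = m[, 2], z = m[, 3],
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    res_list[[p]] <- mk_res(b1, t1, bb_xyz, "A", p)
    res_list[[n + p]] <- mk_res(b2, t2, .dyad(bb_xyz), "B", n + 1L - p)
  }
  atoms <- do.call(rbind, res_list)
  atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$resno), ]
  rownames(atoms) <- NULL
  atoms$resid <- resid_name(atoms$code, nucleic_type)

  s <- list(
    atoms = atoms, seq1 = paste(bases, collapse = ""), seq2 = seq2,
    nucleic_type = nucleic_type, form = params$form, params = params
  )
  class(s) <- "native_structure"
  s
}

resid_name <- function(code, nucleic_type) {
  if (nucleic_type == "DNA") paste0("D", code) else code
}

code_from_resid <- function(resid) {
  code <- sub("^D", "", resid)
  ok <- code %in% c("A", "C", "G", "T", "U")
  if (!all(ok)) stop("non-nucleic residue(s): ", paste(unique(resid[!ok]), collapse = ", "))
  code
}

#' @export
print.native_structure <- function(x, ...) {
  cat(sprintf(
    "<native_structure> %s %s-form duplex, %d bp, %d atoms\n  chain A 5'-%s-3'\n  chain B 5'-%s-3'\n",
    x$nucleic_type, x$form, nchar(x$seq1), nrow(x$atoms), x$seq1, x$seq2
  ))
  invisible(x)
}

#' Number of base pairs in a duplex
#' @param structure A `native_structure`.
#' @return Integer base-pair count.
#' @export
n_pairs <- function(structure) nchar(structure$seq1)

# Index of one atom in the atoms table; errors if absent.
atom_index <- function(structure, chain, resno, name) {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resno == resno & a$name == name)
  if (length(i) != 1L) {
    stop(sprintf("atom %s/%d/%s not found", chain, resno, name))
  }
  i
}

# The two pulling-attachment atoms: chain A residue 1 5'-hydroxyl oxygen and
# chain B last residue 3'-hydroxyl oxygen (both at the pulled terminal pair).
pulling_pair <- function(structure) {
  n <- n_pairs(structure)
  c(
    atom_index(structure, "A", 1L, "O5'"),
    atom_index(structure, "B", n, "O3'")
  )
}

#' Coordinate matrix of a structure
#' @param structure A `native_structure`.
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Watson-Crick donor/acceptor atom indices for base pair p (chain A residue p
# pairs chain B residue n+1-p); purine N1 vs pyrimidine N3.
wc_atoms_of_pair <- function(structure, p) {
  n <- n_pairs(structure)
  b1 <- substr(structure$seq1, p, p)
  nm1 <- if (b1 %in% PURINES) "N1" else "N3"
  nm2 <- if (b1 %in% PURINES) "N3" else "N1"
  c(
    atom_index(structure, "A", p, nm1),
    atom_index(structure, "B", n + 1L - p, nm2)
  )
}

#' Watson-Crick donor-acceptor distances of all base pairs
#'
#' @param structure A `native_structure`.
#' @param xyz Optional n_atoms x 3 coordinate matrix (defaults to the native
#'   coordinates), so the same measure applies to trajectory frames.
#' @return data.frame with `pair` and `distance` (Angstrom).
#' @export
wc_pair_distances <- function(structure, xyz = NULL) {
  if (is.null(xyz)) xyz <- atom_xyz(structure)
  n <- n_pairs(structure)
  d <- vapply(seq_len(n), function(p) {
    ij <- wc_atoms_of_pair(structure, p)
    dist3(xyz[ij[1], ], xyz[ij[2], ])
  }, numeric(1))
  data.frame(pair = seq_len(n), distance = d)
}

#' Base heavy-atom centroid of a residue
#'
#' Mean position of the base ring and exocyclic atoms (no sugar).
#' @param structure A `native_structure`.
#' @param chain `"A"` or `"B"`.
#' @param resno Residue number within the chain.
#' @param xyz Optional coordinate frame (defaults to native coordinates).
#' @return Length-3 numeric vector (Angstrom).
#' @export
base_centroid <- function(structure, chain, resno, xyz = NULL) {
  if (is.null(xyz)) xyz <- atom_xyz(structure)
  idx <- base_atom_indices(structure, chain, resno)
  colMeans(xyz[idx, , drop = FALSE])
}

#' Atom indices of a residue's base (ring + exocyclic)
#' @inheritParams base_centroid
#' @return Integer atom indices into the structure's atom table.
#' @export
base_atom_indices <- function(structure, chain, resno) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno
  code <- a$code[sel][1]
  tmpl <- base_template(code, structure$nucleic_type)
  which(sel & a$name %in% tmpl$base_atoms)
}

#' Base-pair centroids
#'
#' Midpoint of the two strands' C4' atoms per pair: the base-pair centroid
#' used for the rise invariant (it lies exactly on the helix axis in the
#' ideal construction).
#' @param structure A `native_structure`.
#' @param xyz Optional coordinate frame.
#' @return n_pairs x 3 matrix.
#' @export
pair_centroids <- function(structure, xyz = NULL) {
  if (is.null(xyz)) xyz <- atom_xyz(structure)
  n <- n_pairs(structure)
  t(vapply(seq_len(n), function(p) {
    i <- atom_index(structure, "A", p, "C4'")
    j <- atom_index(structure, "B", n + 1L - p, "C4'")
    (xyz[i, ] + xyz[j, ]) / 2
  }, numeric(3)))
}

#' Validate native-structure invariants
#'
#' Checks the duplex-level invariants: two equal-length complementary chains,
#' consecutive base-pair centroid separation equal to the configured rise
#' (ideal construction), and Watson-Crick donor/acceptor distances within
#' 2.6-3.2 A.
#'
#' @param structure A `native_structure`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_native_structure <- function(structure) {
  a <- structure$atoms
  stopifnot(identical(sort(unique(a$chain)), c("A", "B")))
  n <- n_pairs(structure)
  stopifnot(
    length(unique(a$resno[a$chain == "A"])) == n,
    length(unique(a$resno[a$chain == "B"])) == n
  )
  if (reverse_complement(structure$seq1, structure$nucleic_type) != structure$seq2) {
    stop("chain B is not the reverse complement of chain A")
  }
  pc <- pair_centroids(structure)
  if (n >= 2) {
    sep <- sqrt(rowSums(diff(pc)^2))
    if (any(abs(sep - structure$params$rise) > 1e-6)) {
      stop("base-pair centroid separation deviates from the configured rise")
    }
  }
  wc <- wc_pair_distances(structure)
  if (any(wc$distance < 2.6 | wc$distance > 3.2)) {
    stop("Watson-Crick donor/acceptor distance outside [2.6, 3.2] A")
  }
  invisible(TRUE)
}

#' Write a native structure as PDB
#'
#' Standard ATOM/TER/END records via bio3d, preceded by a REMARK line
#' carrying the helix form and nucleic type so that [read_pdb()] round-trips
#' them.
#'
#' @param structure A `native_structure`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, chain = a$chain,
    eleno = seq_len(nrow(a)), elety = a$name, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), chainter = TRUE
  )
  lines <- readLines(file)
  hdr <- sprintf(
    "REMARK 300 UNWINDR FORM %s TYPE %s", structure$form, structure$nucleic_type
  )
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' Read a duplex native structure from PDB
#'
#' Accepts two-chain nucleic-acid PDB files; chain lengths must be equal and
#' the second chain must be the reverse complement of the first.  Helix form
#' is recovered from the REMARK written by [write_pdb()] when present.
#'
#' @param file PDB path.
#' @return A `native_structure`.
#' @export
read_pdb <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  if (length(readLines(file, n = 1L)) == 0L) stop("empty PDB file")
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records")
  chains <- unique(at$chain)
  if (length(chains) != 2L) {
    stop("not a duplex: expected exactly 2 chains, found ", length(chains))
  }
  code <- code_from_resid(at$resid)
  nucleic_type <- if (any(grepl("^D", at$resid)) || "T" %in% code) "DNA" else "RNA"

  hdr <- grep("^REMARK 300 UNWINDR", readLines(file), value = TRUE)
  form <- if (length(hdr) == 1L) sub(".*FORM (\\S+) TYPE.*", "\\1", hdr) else NA_character_
  if (length(hdr) == 1L) nucleic_type <- sub(".*TYPE (\\S+)\\s*$", "\\1", hdr)

  seq_of <- function(ch) {
    sel <- at$chain == ch
    r <- at$resno[sel]
    code[sel][match(sort(unique(r)), r)]
  }
  s1 <- seq_of(chains[1]); s2 <- seq_of(chains[2])
  if (length(s1) != length(s2)) stop("not a duplex: unequal chain lengths")
  # renumber residues 1..n per chain in file order
  atoms <- data.frame(
    name = at$elety, element = element_of(at$elety),
    resno = at$resno, chain = ifelse(at$chain == chains[1], "A", "B"),
    code = code, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  for (ch in c("A", "B")) {
    sel <- atoms$chain == ch
    atoms$resno[sel] <- match(atoms$resno[sel], sort(unique(atoms$resno[sel])))
  }
  atoms$resid <- at$resid
  s <- list(
    atoms = atoms,
    seq1 = paste(s1, collapse = ""), seq2 = paste(s2, collapse = ""),
    nucleic_type = nucleic_type,
    form = if (is.na(form)) "B" else form,
    params = if (is.na(form)) NULL else helix_parameters(form)
  )
  class(s) <- "native_structure"
  if (reverse_complement(s$seq1, nucleic_type) != s$seq2) {
    stop("not a duplex: chains are not reverse complements")
  }
  s
}
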