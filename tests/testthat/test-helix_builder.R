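# Duplex construction: sequence handling, geometric invariants, PDB I/O.

test_that("reverse complement follows Watson-Crick rules", {
  expect_equal(reverse_complement("GCGCGC", "RNA"), "GCGCGC")
  expect_equal(reverse_complement("AAAAAA", "DNA"), "TTTTTT")
  expect_equal(
    reverse_complement("AGAGAGAGAGAGAGAGAGAGA", "DNA"),
    "TCTCTCTCTCTCTCTCTCTCT"
  )
  expect_equal(reverse_complement("AUGC", "RNA"), "GCAU")
  expect_error(reverse_complement("AUG", "DNA"), "invalid")
  expect_error(reverse_complement("ATG", "RNA"), "invalid")
  expect_error(reverse_complement("", "DNA"), "nonempty")
})

test_that("built duplexes satisfy the native-structure invariants", {
  for (case in list(c("GCGCGC", "RNA"), c("ACCGGT", "DNA"),
                    c("AGAGAG", "DNA"), c("AUAUAU", "RNA"))) {
    s <- build_duplex(case[1], case[2])
    expect_true(validate_native_structure(s))
    wc <- wc_pair_distances(s)
    expect_true(all(wc$distance >= 2.6 & wc$distance <= 3.2))
    # residue counts: two chains of equal length
    expect_equal(sort(unique(s$atoms$chain)), c("A", "B"))
    expect_equal(nchar(s$seq1), nchar(case[1]))
  }
})

test_that("duplex construction is deterministic and respects counts", {
  s1 <- build_duplex("GCGCGC", "RNA")
  s2 <- build_duplex("GCGCGC", "RNA")
  expect_identical(s1$atoms, s2$atoms)
  expect_equal(length(unique(paste(s1$atoms$chain, s1$atoms$resno))), 12)
})

test_that("configured twist and rise are realized exactly", {
  p <- helix_parameters("B")
  s <- build_duplex("GC", "DNA", params = p)
  pc <- pair_centroids(s)
  expect_equal(unname(sqrt(sum(diff(pc)^2))), p$rise, tolerance = 1e-9)
  # twist: angle between successive C4'-C4' in-plane vectors
  a <- atom_xyz(s)
  v <- function(pair) {
    i <- unwindr:::atom_index(s, "A", pair, "C4'")
    j <- unwindr:::atom_index(s, "B", 2 + 1 - pair, "C4'")
    (a[i, 1:2] - a[j, 1:2])
  }
  ang <- function(u, w) {
    acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
  }
  expect_equal(ang(v(1), v(2)), p$twist, tolerance = 1e-6)
})

test_that("end-to-end distance grows monotonically with the rise", {
  xs <- vapply(c(0.9, 1.0, 1.1), function(sc) {
    p <- helix_parameters("B")
    p$rise <- p$rise * sc
    s <- build_duplex("ACCGGT", "DNA", params = p)
    pp <- unwindr:::pulling_pair(s)
    end_to_end(atom_xyz(s), pp)
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("A-form leaves the 5'-terminal base less stacked than B-form", {
  # lateral (in-plane) centroid offset of the 5'-terminal base from its
  # inward neighbour, A vs B on the same sequence
  lateral_offset <- function(form) {
    s <- build_duplex("GCGCGC", "DNA", form = form)
    c1 <- base_centroid(s, "A", 1L)
    c2 <- base_centroid(s, "A", 2L)
    sqrt(sum((c1[1:2] - c2[1:2])^2))
  }
  expect_gt(lateral_offset("A"), lateral_offset("B"))
})

test_that("strand pairing convention is self-consistent", {
  s <- build_duplex("ACCGGT", "DNA")
  n <- nchar(s$seq1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(n)) {
    b1 <- substr(s$seq1, p, p)
    b2 <- s$atoms$code[s$atoms$chain == "B" & s$atoms$resno == n + 1 - p][1]
    expect_equal(b2, unname(comp[b1]))
  }
})

test_that("PDB round-trip preserves sequence and coordinates to 1e-3 A", {
  s <- build_duplex("GCGCGC", "RNA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(s2$seq1, s$seq1)
  expect_equal(s2$seq2, s$seq2)
  expect_equal(s2$nucleic_type, "RNA")
  expect_equal(s2$form, "A")
  expect_lt(max(abs(atom_xyz(s2) - atom_xyz(s))), 1e-3 + 1e-9)
})

test_that("malformed PDB inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "empty")
  # single chain -> not a duplex
  s <- build_duplex("GCGC", "DNA")
  write_pdb(s, f)
  lines <- readLines(f)
  keep <- !grepl("^ATOM", lines) |
    substr(lines, 22, 22) == "A"
  writeLines(lines[keep], f)
  expect_error(read_pdb(f), "duplex")
  expect_error(read_pdb(file.path(tempdir(), "nope-missing.pdb")), "no such")
})
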