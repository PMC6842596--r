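# Far-end tether for reversible unzipping.
#
# A duplex pulled at one end fully dissociates once the last base pair
# breaks, and bimolecular re-association is far too slow to sample
# reversible hopping.  Optical-tweezer constructs avoid this by covalently
# linking the two strands away from the pulled end (hairpin loops,
# handles); the simulation mimics that with a single harmonic bond between
# the Watson-Crick donor/acceptor atoms of the far-end pair.  The tethered
# pair is excluded from junction statistics (it can still unstack but not
# leave).

#' Tether the far-end base pair
#'
#' Adds a harmonic bond between the Watson-Crick atoms of the base pair
#' farthest from the pulled end, keeping the two strands linked after full
#' unzipping so that folded/unfolded hopping is reversible.
#'
#' @param topology An `sbm_topology`.
#' @param k Tether stiffness (energy / A^2).
#' @return The modified topology (flag `tethered_pair` records the pair).
#' @export
tether_far_pair <- function(topology, k = 10) {
  n_bp <- topology$n_bp
  ij <- topology$wc_pairs[n_bp, ]
  xyz <- topology$native_xyz
  r0 <- dist3(xyz[ij[1], ], xyz[ij[2], ])
  topology$bond_atoms <- rbind(topology$bond_atoms, as.integer(ij))
  topology$bond_params <- rbind(topology$bond_params, c(r0, k))
  topology$tethered_pair <- n_bp
  topology
}

#' Clamp the duplex stem for junction-dynamics sampling
#'
#' Adds harmonic Watson-Crick tethers to every base pair from `from_pair`
#' inward, so the outer pairs fray and re-form rapidly at the
#' single-strand/double-strand junction while the stem never melts.  This
#' is the production setup for estimating dangling-intermediate
#' populations: the junction opens and closes thousands of times per run,
#' the end-to-end distance stays small (so the constant-force reweighting
#' keeps a large effective sample size), and the clamped pairs are
#' excluded from junction statistics by construction (they never open).
#'
#' @param topology An `sbm_topology`.
#' @param from_pair First clamped pair (counted from the pulled end);
#'   pairs `from_pair..n` are tethered.
#' @param k Tether stiffness (energy / A^2).
#' @return The modified topology (`clamped_pairs` records them).
#' @export
tether_stem <- function(topology, from_pair = 3, k = 10) {
  n_bp <- topology$n_bp
  stopifnot(from_pair >= 2, from_pair <= n_bp)
  xyz <- topology$native_xyz
  for (p in seq(from_pair, n_bp)) {
    ij <- topology$wc_pairs[p, ]
    r0 <- dist3(xyz[ij[1], ], xyz[ij[2], ])
    topology$bond_atoms <- rbind(topology$bond_atoms, as.integer(ij))
    topology$bond_params <- rbind(topology$bond_params, c(r0, k))
  }
  topology$clamped_pairs <- seq(from_pair, n_bp)
  topology
}
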