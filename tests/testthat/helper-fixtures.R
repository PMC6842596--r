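# Shared fixtures.  Heavy simulation products (calibrated hopping runs and
# their junction analyses) are computed once per test session and cached in
# a package-level environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

dna_hexamer <- function() fixture("dna_hexamer", function() build_duplex("ACCGGT", "DNA"))
rna_hexamer <- function() fixture("rna_hexamer", function() build_duplex("GGCGCC", "RNA"))

dna_topology <- function() fixture("dna_topology", function() build_topology(dna_hexamer()))

# A minimal hand-built topology for integrator physics tests: atoms and an
# optional single bond, no other terms.
toy_topology <- function(n_atoms, bond = NULL, k_bond = 50, r0 = 1.5,
                         masses = rep(1, n_atoms)) {
  empty_i <- function(k) matrix(integer(0), 0, k)
  topo <- list(
    n_atoms = as.integer(n_atoms), masses = masses,
    bond_atoms = if (is.null(bond)) empty_i(2) else
      matrix(as.integer(bond), 1, 2),
    bond_params = if (is.null(bond)) matrix(0, 0, 2) else
      matrix(c(r0, k_bond), 1, 2),
    angle_atoms = empty_i(3), angle_params = matrix(0, 0, 2),
    dihedral_atoms = empty_i(4), dihedral_params = matrix(0, 0, 2),
    contact_atoms = empty_i(2), contact_params = matrix(0, 0, 2),
    excluded_pairs = {
      cmb <- utils::combn(seq_len(n_atoms), 2)
      m <- t(cmb)
      storage.mode(m) <- "integer"
      m
    },
    r_ex = 2.5, eps_ex = 1, pull_pair = c(1L, min(2L, n_atoms)),
    n_bp = 0L
  )
  class(topo) <- "sbm_topology"
  topo
}

# Shared physics runs (used by both the engine unit tests and the
# acceptance suite, cached to keep the run budget down).
nve_run <- function() fixture("nve_run", function() {
  top <- dna_topology()
  s <- dna_hexamer()
  set.seed(2)
  x0 <- atom_xyz(s) + matrix(rnorm(3 * nrow(atom_xyz(s)), 0, 0.03), ncol = 3)
  cfg <- sim_config(gamma = 0, temperature = 0, n_steps = 1e5,
                    save_stride = 50, f_pn = 0, record_channels = FALSE)
  run_dynamics(top, cfg, xyz0 = x0, f_reduced = 0)
})

nve_drift <- function() {
  tr <- nve_run()
  E <- tr$epot + tr$ekin
  n <- length(E)
  abs(mean(E[seq(0.9 * n, n)]) - mean(E[seq(0.1 * n, 0.2 * n)])) /
    abs(mean(E))
}

oscillator_run <- function() fixture("osc_run", function() {
  toy <- toy_topology(2, bond = c(1, 2), k_bond = 20, r0 = 10,
                      masses = c(1, 1e9))
  cfg <- sim_config(timestep = 0.002, gamma = 1, temperature = 1.3,
                    n_steps = 6e5, save_stride = 5, f_pn = 0, seed = 1,
                    record_channels = FALSE)
  run_dynamics(toy, cfg, xyz0 = rbind(c(0, 0, 0), c(10, 0, 0)),
               f_reduced = 0)
})

equipartition_run <- function() fixture("equi_run", function() {
  cfg <- sim_config(temperature = 1.2, n_steps = 1.2e5, save_stride = 10,
                    f_pn = 0, record_channels = FALSE, seed = 6)
  run_dynamics(dna_topology(), cfg)
})
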