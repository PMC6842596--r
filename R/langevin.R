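# Langevin dynamics under the structure-based Hamiltonian plus a constant
# end-to-end force, mimicking constant-force optical-tweezer unzipping.
#
# Integrator: BAOAB splitting (exactly velocity Verlet when gamma = 0).
# Reduced units throughout: energy in contact well depths (epsilon), length
# in Angstrom internally (end-to-end distances are reported in nm), masses 1,
# k_B = 1.  The physical force label in pN is converted through
# k_B T(296 K) = 4.09 pN nm, i.e. f[reduced, energy/A] = f[pN] * T / 40.9
# at simulation temperature T: the calibrated hopping temperature plays the
# role of room temperature.

.KBT_296K_PN_NM <- 4.09

#' Convert a pulling force from pN to reduced units
#'
#' @param f_pn Force in pN.
#' @param temperature Simulation temperature in reduced energy units.
#' @return Force in reduced units (energy / Angstrom).
#' @export
force_pn_to_reduced <- function(f_pn, temperature) {
  f_pn * temperature / (.KBT_296K_PN_NM * 10)
}

#' Simulation configuration
#'
#' @param timestep Integration step (reduced time units).
#' @param gamma Langevin friction (1/time).
#' @param temperature Temperature in reduced energy units (k_B = 1).
#' @param n_steps Number of integration steps.
#' @param save_stride Record the end-to-end distance, energies and junction
#'   distance channels every this many steps.
#' @param frame_stride Store full coordinate frames every this many steps
#'   (0 = none).
#' @param f_pn Constant pulling force in pN (converted internally).
#' @param seed Integer RNG seed; the trajectory is bit-reproducible for a
#'   fixed seed and configuration.
#' @param wall_x,wall_k Half-harmonic confining wall on the end-to-end
#'   distance (Angstrom; energy/A^2), which keeps the unzipped strands from
#'   drifting apart irreversibly -- the role played by the trap and tethers
#'   in the mimicked optical-tweezer setup.
#' @param record_channels Record per-pair Watson-Crick pairing and 5'/3'
#'   stacking distance channels used by the junction-state analysis.
#' @return A `sim_config` list.
#' @export
sim_config <- function(timestep = 0.002, gamma = 1.0, temperature = 1.0,
                       n_steps = 1e5, save_stride = 10, frame_stride = 0,
                       f_pn = 14, seed = 1, wall_x = 33, wall_k = 2,
                       record_channels = TRUE) {
  stopifnot(timestep > 0, gamma >= 0, temperature >= 0, n_steps >= 1,
            save_stride >= 1)
  cfg <- list(
    timestep = timestep, gamma = gamma, temperature = temperature,
    n_steps = n_steps, save_stride = as.integer(save_stride),
    frame_stride = as.integer(frame_stride), f_pn = f_pn,
    seed = as.integer(seed), wall_x = wall_x, wall_k = wall_k,
    record_channels = isTRUE(record_channels)
  )
  class(cfg) <- "sim_config"
  cfg
}

.channel_spec <- function(topology) {
  groups <- topology$base_groups
  lens <- vapply(groups, length, integer(1))
  list(
    wc_pairs = topology$wc_pairs,
    group_ptr = as.integer(c(0, cumsum(lens))),
    group_idx = as.integer(unlist(groups))
  )
}

channel_names <- function(n_bp) {
  c(
    paste0("pairing_", seq_len(n_bp)),
    paste0("stack5_", seq_len(n_bp - 1)),
    paste0("stack3_", seq_len(n_bp - 1))
  )
}

#' Run Langevin dynamics
#'
#' @param topology An `sbm_topology`.
#' @param config A [sim_config()].
#' @param xyz0 Starting coordinates (defaults to the native structure).
#' @param v0 Starting velocities (default: Maxwell-Boltzmann draw at the
#'   configured temperature, or zero at T = 0).
#' @param f_reduced Pulling force directly in reduced units, overriding the
#'   pN conversion (used by low-level physics tests).
#' @return An `unzip_trajectory`: `x_series` (end-to-end distance, nm),
#'   `epot`, `ekin`, `channels` (pairing/stacking distances, Angstrom),
#'   `frames` (array n_frames x n_atoms x 3, if requested), `xyz_final`,
#'   `v_final`, `config`, and the force actually applied (`f_reduced`).
#' @export
run_dynamics <- function(topology, config, xyz0 = NULL, v0 = NULL,
                         f_reduced = NULL) {
  stopifnot(inherits(topology, "sbm_topology"), inherits(config, "sim_config"))
  if (is.null(xyz0)) xyz0 <- topology$native_xyz
  xyz0 <- as.matrix(xyz0)
  stopifnot(nrow(xyz0) == topology$n_atoms)
  if (is.null(f_reduced)) {
    f_reduced <- force_pn_to_reduced(config$f_pn, config$temperature)
  }
  res <- cpp_run(
    topology, xyz0, v0,
    config$timestep, config$gamma, config$temperature,
    config$n_steps, config$save_stride, config$frame_stride,
    config$seed, f_reduced, config$wall_x, config$wall_k,
    config$record_channels && !is.null(topology$wc_pairs),
    .channel_spec(topology)
  )
  out <- list(
    x_series = res$x_series / 10, # nm
    epot = res$epot,
    ekin = res$ekin,
    channels = res$channels,
    xyz_final = res$xyz_final,
    v_final = res$v_final,
    config = config,
    f_reduced = f_reduced,
    n_bp = topology$n_bp,
    seq1 = topology$seq1,
    nucleic_type = topology$nucleic_type,
    form = topology$form
  )
  if (!is.null(out$channels) && ncol(out$channels) > 0) {
    colnames(out$channels) <- channel_names(topology$n_bp)
  }
  if (config$frame_stride > 0) {
    nf <- length(res$frames) / (3 * topology$n_atoms)
    out$frames <- aperm(
      array(res$frames, c(3, topology$n_atoms, nf)), c(3, 2, 1)
    )
  }
  class(out) <- "unzip_trajectory"
  out
}

#' @export
print.unzip_trajectory <- function(x, ...) {
  cat(sprintf(
    "<unzip_trajectory> %s %s-form %s | %d saved frames | x: %.2f-%.2f nm\n",
    x$nucleic_type, x$form, x$seq1, length(x$x_series),
    min(x$x_series), max(x$x_series)
  ))
  invisible(x)
}

#' End-to-end distance of one coordinate frame
#'
#' Euclidean distance between the two pulling-attachment hydroxyl oxygens.
#'
#' @param xyz n_atoms x 3 coordinates (Angstrom).
#' @param pull_pair Length-2 atom indices.
#' @return Distance in nm.
#' @export
end_to_end <- function(xyz, pull_pair) {
  stopifnot(length(pull_pair) == 2, all(pull_pair <= nrow(xyz)))
  dist3(xyz[pull_pair[1], ], xyz[pull_pair[2], ]) / 10
}

#' Two-state occupancy and transition count of an x series
#'
#' Frames below `x_folded` count as folded, above `x_unfolded` as unfolded;
#' transitions are complete crossings from one threshold to the other
#' (hysteresis counting, robust to in-between chatter).
#'
#' @param x End-to-end distance series (nm).
#' @param x_folded,x_unfolded Thresholds in nm.
#' @return List with `p_folded`, `p_unfolded`, `n_transitions`.
#' @export
hopping_stats <- function(x, x_folded, x_unfolded) {
  stopifnot(x_folded < x_unfolded)
  lab <- ifelse(x < x_folded, 1L, ifelse(x > x_unfolded, 2L, NA_integer_))
  known <- lab[!is.na(lab)]
  n_trans <- if (length(known) > 1) sum(diff(known) != 0L) else 0L
  list(
    p_folded = mean(x < x_folded),
    p_unfolded = mean(x > x_unfolded),
    n_transitions = n_trans
  )
}

#' Calibrate the hopping temperature
#'
#' Runs a trajectory at each grid temperature (with the pulling force given
#' in pN, converted at each temperature) and returns the grid point whose
#' folded/unfolded occupancy product is largest, i.e. the most balanced
#' two-state hopping, requiring at least `min_transitions` complete
#' folded-unfolded crossings.  Ties break deterministically to the first
#' grid entry.
#'
#' @param topology An `sbm_topology`.
#' @param f_pn Pulling force (pN).
#' @param t_grid Candidate temperatures (reduced units).
#' @param n_steps Steps per candidate run.
#' @param x_folded,x_unfolded Occupancy thresholds (nm).
#' @param min_transitions Minimum transitions for an admissible candidate.
#' @param burn_in Fraction of each calibration trajectory discarded before
#'   occupancies are measured (runs start from the native state, which
#'   otherwise biases the folded occupancy upward).
#' @param seed RNG seed (one run per grid point, seeds offset by index).
#' @param ... Further arguments to [sim_config()] (timestep, gamma, wall).
#' @return List: `temperature` (chosen), `report` (data.frame per grid
#'   point: temperature, p_folded, p_unfolded, product, n_transitions).
#' @export
calibrate_hopping <- function(topology, f_pn, t_grid, n_steps = 4e5,
                              x_folded = 2.4, x_unfolded = 3.4,
                              min_transitions = 5, burn_in = 0.3,
                              seed = 1, ...) {
  if (length(t_grid) == 0) stop("empty temperature grid")
  rows <- lapply(seq_along(t_grid), function(i) {
    cfg <- sim_config(
      temperature = t_grid[i], n_steps = n_steps, f_pn = f_pn,
      seed = seed + i - 1L, record_channels = FALSE, ...
    )
    tr <- run_dynamics(topology, cfg)
    x <- tr$x_series
    x <- x[-seq_len(floor(burn_in * length(x)))]
    st <- hopping_stats(x, x_folded, x_unfolded)
    data.frame(
      temperature = t_grid[i], p_folded = st$p_folded,
      p_unfolded = st$p_unfolded, product = st$p_folded * st$p_unfolded,
      n_transitions = st$n_transitions
    )
  })
  report <- do.call(rbind, rows)
  ok <- report$product > 0 & report$n_transitions >= min_transitions
  if (!any(ok)) {
    stop(
      "no grid temperature produced both folded and unfolded states; ",
      "widen the temperature grid or lengthen the runs"
    )
  }
  best <- which(ok)[which.max(report$product[ok])]
  list(temperature = report$temperature[best], report = report)
}
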