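# End-to-end unzipping study for one duplex: build, parameterize, simulate
# under constant force, classify junction states and estimate the
# nearest-neighbour dangling-intermediate free energies.

#' Run a constant-force unzipping study for one sequence
#'
#' Builds the idealized duplex, constructs the structure-based topology
#' (with the far-end tether that keeps unzipping reversible), runs Langevin
#' dynamics at the given temperature under a 14 pN end-to-end force,
#' assigns junction states and returns the reweighted nearest-neighbour
#' free-energy table together with hopping diagnostics.
#'
#' @param sequence Chain A sequence (5'->3'; the pulled end is its 5'
#'   terminus).
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param temperature Simulation temperature (reduced units), e.g. from
#'   [calibrate_hopping()].
#' @param n_steps Production steps.
#' @param seed RNG seed.
#' @param f_pn Pulling force in pN.
#' @param timestep,gamma,wall_x Integration and confinement settings; the
#'   defaults are the production settings used throughout the analysis.
#' @param n_boot Bootstrap resamples for the table's standard errors.
#' @param x_folded,x_unfolded Occupancy thresholds (nm) for hopping
#'   diagnostics.
#' @return List with `traj`, `series`, `weights`, `table`, `hopping`,
#'   `events`, `structure`, `topology`, `config`.
#' @export
unzip_study <- function(sequence, nucleic_type, temperature,
                        n_steps = 1e6, seed = 7, f_pn = 14,
                        timestep = 0.002, gamma = 0.3, wall_x = 33,
                        n_boot = 150, x_folded = 2.6, x_unfolded = 3.1,
                        clamp_from = NULL) {
  s <- build_duplex(sequence, nucleic_type)
  top <- tether_far_pair(build_topology(s))
  if (!is.null(clamp_from)) top <- tether_stem(top, from_pair = clamp_from)
  cfg <- sim_config(
    timestep = timestep, gamma = gamma, temperature = temperature,
    n_steps = n_steps, save_stride = 20, f_pn = f_pn, seed = seed,
    wall_x = wall_x
  )
  tr <- run_dynamics(top, cfg)
  ser <- assign_states(tr)
  if (!is.null(clamp_from)) {
    # clamped pairs cannot unpair but can transiently unstack; junction
    # labels at or beyond the clamp are artifacts and carry no context
    ser$context[ser$junction >= clamp_from] <- NA
  }
  w <- reweight(tr$x_series, tr$f_reduced * 10, temperature)
  tab <- dangling_dg(ser, w, n_boot = n_boot, seed = seed + 1L)
  ev <- extract_events(ser, min_dwell = 15)
  list(
    traj = tr, series = ser, weights = w, table = tab,
    hopping = hopping_stats(tr$x_series, x_folded, x_unfolded),
    events = ev, structure = s, topology = top, config = cfg
  )
}

#' Pooled nearest-neighbour table over several independent runs
#'
#' Runs [unzip_study()] for each seed and pools the weighted frames before
#' estimating the table: junction-state dwells are long-lived, so several
#' shorter independent runs give a far better-conditioned estimate than
#' one long run.
#'
#' @inheritParams unzip_study
#' @param seeds Integer vector of run seeds.
#' @param ... Passed on to [unzip_study()].
#' @return List with `table` (pooled `nn_dg_table`), `studies`.
#' @export
pooled_nn_table <- function(sequence, nucleic_type, temperature, seeds,
                            n_steps = 4e5, n_boot = 150, ...) {
  studies <- lapply(seeds, function(sd) {
    unzip_study(sequence, nucleic_type, temperature, n_steps = n_steps,
                seed = sd, n_boot = 0, ...)
  })
  pooled <- pool_runs(lapply(studies, `[[`, "series"),
                      lapply(studies, `[[`, "weights"))
  tab <- dangling_dg(pooled$series, pooled$weights, n_boot = n_boot,
                     seed = seeds[1])
  list(table = tab, studies = studies)
}

#' Calibrate the junction-sampling temperature
#'
#' For junction-statistics runs on the clamped-stem construct, pick the
#' grid temperature that maximizes the number of dangling-intermediate
#' frames at the junction (too cold and the junction never frays, too hot
#' and it sits fully open: intermediate sampling peaks in between).
#'
#' @param sequence,nucleic_type Duplex definition as in [unzip_study()].
#' @param t_grid Candidate temperatures.
#' @param n_steps Steps per candidate run.
#' @param seed RNG seed.
#' @param clamp_from First clamped pair.
#' @param f_pn Pulling force during sampling (default 0: direct unbiased
#'   sampling).
#' @return List: `temperature`, `report` (temperature, n_intermediate).
#' @export
calibrate_junction <- function(sequence, nucleic_type, t_grid,
                               n_steps = 1e5, seed = 1, clamp_from = 3,
                               f_pn = 0) {
  rows <- lapply(seq_along(t_grid), function(i) {
    st <- unzip_study(sequence, nucleic_type, t_grid[i], n_steps = n_steps,
                      seed = seed + i - 1L, f_pn = f_pn,
                      clamp_from = clamp_from, n_boot = 0)
    ser <- st$series
    n_int <- sum(as.character(ser$state) %in% c("FLIP5", "FLIP3") &
                   !is.na(ser$context))
    data.frame(temperature = t_grid[i], n_intermediate = n_int)
  })
  report <- do.call(rbind, rows)
  list(temperature = report$temperature[which.max(report$n_intermediate)],
       report = report)
}

#' Contexts considered adequately sampled in a free-energy table
#'
#' A context counts as sampled when both dangling intermediates were
#' observed at least `min_frames` times; g estimates outside this set are
#' reported but carry too little data for sign-level statements.
#'
#' @param table An `nn_dg_table`.
#' @param min_frames Minimum frames per intermediate.
#' @return Logical vector over the table rows.
#' @export
well_sampled <- function(table, min_frames = 100) {
  is.finite(table$g) & table$n5 >= min_frames & table$n3 >= min_frames
}
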